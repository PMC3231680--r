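#' Band sets
#'
#' A band set is a tibble with one row per spectral band: `band_id` (unique
#' label), `center_nm`, `width_nm` and optional `resolution_m` (ground sample
#' distance, metadata only). Band centers must be strictly increasing and
#' supports strictly positive.
#'
#' `s2_bandset()` returns the 13-band Sentinel-2 MSI configuration
#' (band centers and widths of the mission's spectral specification). Its
#' bands B4 (665 nm), B5 (705 nm), B6 (740 nm) and B7 (783 nm) are the ones
#' whose centers fall inside the default NAOC integration window
#' \[643, 795\] nm.
#'
#' @param band_id Character vector of unique band labels.
#' @param center_nm,width_nm Numeric vectors, nm.
#' @param resolution_m Optional numeric vector, metres.
#' @return A band-set tibble.
#' @examples
#' s2 <- s2_bandset()
#' subset_bands(s2, c("B4", "B7"))
#' @export
band_set <- function(band_id, center_nm, width_nm, resolution_m = NA_real_) {
  bands <- tibble::tibble(
    band_id = as.character(band_id),
    center_nm = as.numeric(center_nm),
    width_nm = as.numeric(width_nm),
    resolution_m = as.numeric(resolution_m)
  )
  if (anyDuplicated(bands$band_id)) {
    abort("band_id values must be unique", class = "rededge_format_error")
  }
  if (is.unsorted(bands$center_nm, strictly = TRUE)) {
    abort("band centers must be strictly increasing",
          class = "rededge_format_error")
  }
  if (any(bands$width_nm <= 0)) {
    abort("band widths must be positive", class = "rededge_format_error")
  }
  if (any(bands$center_nm - bands$width_nm / 2 <= 0)) {
    abort("band support must lie at positive wavelengths",
          class = "rededge_format_error")
  }
  bands
}

#' @rdname band_set
#' @export
s2_bandset <- function() {
  band_set(
    band_id = c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8a",
                "B9", "B10", "B11", "B12"),
    center_nm = c(443, 490, 560, 665, 705, 740, 783, 842, 865,
                  945, 1375, 1610, 2190),
    width_nm = c(20, 65, 35, 30, 15, 15, 20, 115, 20, 20, 30, 90, 180),
    resolution_m = c(60, 10, 10, 10, 20, 20, 20, 10, 20, 60, 60, 20, 20)
  )
}

#' Restrict a band set to selected bands
#'
#' Used for band-ablation experiments, e.g. dropping the red-edge bands B5
#' and B6 from the Sentinel-2 set.
#'
#' @param bandset A band-set tibble.
#' @param band_ids Character vector of band ids to keep; all must exist.
#' @return The band set restricted to `band_ids`, original order preserved.
#' @export
subset_bands <- function(bandset, band_ids) {
  unknown <- setdiff(band_ids, bandset$band_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown band id(s): ", paste(unknown, collapse = ", ")),
          class = "rededge_lookup_error")
  }
  dplyr::filter(bandset, .data$band_id %in% band_ids)
}

#' Read a band set (and SRF choice) from a YAML or JSON config
#'
#' The config schema is
#' `bands: [{id, center_nm, width_nm, resolution_m?}, ...]` with an optional
#' top-level `srf: boxcar|gaussian`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A band-set tibble; the SRF choice, if present, is attached as the
#'   `"srf"` attribute.
#' @export
read_bandset <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$bands)) {
    abort("config must contain a 'bands' list", class = "rededge_format_error")
  }
  bands <- purrr::map_dfr(cfg$bands, function(b) {
    tibble::tibble(
      band_id = as.character(b$id),
      center_nm = as.numeric(b$center_nm),
      width_nm = as.numeric(b$width_nm),
      resolution_m = if (is.null(b$resolution_m)) NA_real_ else as.numeric(b$resolution_m)
    )
  })
  out <- band_set(bands$band_id, bands$center_nm, bands$width_nm,
                  bands$resolution_m)
  if (!is.null(cfg$srf)) {
    attr(out, "srf") <- match.arg(cfg$srf, c("boxcar", "gaussian"))
  }
  out
}
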