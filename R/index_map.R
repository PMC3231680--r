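# Index maps: per-pixel values of one spectral index (or a biophysical
# parameter derived from one), as a tibble with provenance metadata.

new_index_map <- function(pixels, value, meta) {
  out <- tibble::tibble(
    pixel_row = pixels$pixel_row,
    pixel_col = pixels$pixel_col,
    value = value
  )
  attr(out, "meta") <- meta
  class(out) <- c("index_map", class(out))
  out
}

#' Index-map metadata
#'
#' Every index or parameter map carries a `meta` attribute recording how it
#' was computed (index name, wavelengths or bands used, integration limits,
#' calibration coefficients) — enough provenance to recompute it.
#'
#' @param map An index-map tibble.
#' @return A named list.
#' @export
map_meta <- function(map) {
  attr(map, "meta")
}

#' Write an index map to CSV or single-band TIFF
#'
#' @param map An index-map tibble.
#' @param path Output path.
#' @param format `"csv"` (columns `pixel_row,pixel_col,value`) or `"geotiff"`
#'   (single-page float32 TIFF; metadata JSON in the ImageDescription tag).
#' @return `path`, invisibly.
#' @export
write_index_map <- function(map, path, format = c("csv", "geotiff")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(map[c("pixel_row", "pixel_col", "value")], path,
                     row.names = FALSE)
  } else {
    lines <- max(map$pixel_row) + 1L
    samples <- max(map$pixel_col) + 1L
    m <- matrix(NaN, nrow = lines, ncol = samples)
    v <- map$value
    v[is.na(v)] <- NaN
    m[cbind(map$pixel_row + 1L, map$pixel_col + 1L)] <- v
    desc <- jsonlite::toJSON(map_meta(map), auto_unbox = TRUE, digits = NA)
    write_tiff_f32(list(m), list(as.character(desc)), path)
  }
  invisible(path)
}

#' Plot an index map as a raster heat map
#'
#' @param object An index-map tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.index_map <- function(object, ...) {
  meta <- map_meta(object)
  lab <- if (!is.null(meta$index)) meta$index else "value"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pixel_col,
                                       y = .data$pixel_row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = lab)
}

#' Plot spectra from a cube
#'
#' Draws up to `n` pixel spectra as reflectance-vs-wavelength lines.
#'
#' @param spectra A cube tibble.
#' @param n Maximum number of pixels to draw.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, n = 25) {
  px <- dplyr::distinct(spectra, .data$pixel_row, .data$pixel_col)
  if (nrow(px) > n) {
    px <- px[unique(round(seq(1, nrow(px), length.out = n))), ]
  }
  dat <- dplyr::inner_join(spectra, px, by = c("pixel_row", "pixel_col"))
  dat$pixel <- paste0(dat$pixel_row, ",", dat$pixel_col)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$wavelength_nm,
                                    y = .data$reflectance,
                                    group = .data$pixel)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance")
}
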