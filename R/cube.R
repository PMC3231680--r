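#' Reflectance cubes as long tibbles
#'
#' A reflectance cube is an ordinary tibble in long format with one row per
#' pixel and wavelength: columns `pixel_row`, `pixel_col` (0-based integer
#' grid indices), `wavelength_nm` (band-center wavelength in nanometres) and
#' `reflectance` (unitless, nominally in \[0, 1\]). Every unmasked pixel
#' carries a full-length spectrum on the shared wavelength axis; a masked
#' pixel is represented by `NA` reflectance across all wavelengths.
#'
#' `as_cube()` validates a data frame against this contract and returns it as
#' a tibble. Reflectance values outside \[0, 1\] are retained (atmospheric
#' correction routinely produces slight negatives) but their count is
#' reported; only non-finite values mask a pixel.
#'
#' @param x A data frame with columns `pixel_row`, `pixel_col`,
#'   `wavelength_nm`, `reflectance`.
#' @param quiet Suppress the out-of-range report.
#' @return A validated cube tibble.
#' @examples
#' cube <- as_cube(data.frame(
#'   pixel_row = 0L, pixel_col = 0L,
#'   wavelength_nm = c(665, 705), reflectance = c(0.05, 0.35)
#' ))
#' @export
as_cube <- function(x, quiet = FALSE) {
  required <- c("pixel_row", "pixel_col", "wavelength_nm", "reflectance")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cube is missing column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "rededge_format_error")
  }
  x <- tibble::as_tibble(x)[required]
  if (nrow(x) == 0) {
    return(x)
  }
  check_axis(sort(unique(x$wavelength_nm)))
  cm <- cube_matrix(x) # validates full-length spectra per pixel
  n_oob <- sum(cm$values < 0 | cm$values > 1, na.rm = TRUE)
  if (n_oob > 0 && !quiet) {
    inform(
      paste0(n_oob, " reflectance value(s) outside [0, 1] retained"),
      class = "rededge_oob"
    )
  }
  x
}

# Shared axis checks: strictly increasing, positive, finite.
check_axis <- function(wl, min_len = 1) {
  if (length(wl) < min_len) {
    abort(paste0("wavelength axis needs at least ", min_len, " band(s)"),
          class = "rededge_metadata_error")
  }
  if (anyNA(wl) || any(!is.finite(wl))) {
    abort("wavelength axis contains non-finite values",
          class = "rededge_metadata_error")
  }
  if (any(wl <= 0)) {
    abort("wavelengths must be positive (nm)", class = "rededge_metadata_error")
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("wavelength axis must be strictly increasing",
          class = "rededge_metadata_error")
  }
  invisible(wl)
}

# Pivot a long cube to a dense pixel x wavelength matrix.
# Returns list(axis, values, pixels); pixel order is (pixel_row, pixel_col)
# ascending, which every function in the package relies on.
cube_matrix <- function(spectra) {
  wl <- sort(unique(spectra$wavelength_nm))
  sp <- dplyr::arrange(spectra, .data$pixel_row, .data$pixel_col,
                       .data$wavelength_nm)
  px <- dplyr::distinct(sp, .data$pixel_row, .data$pixel_col)
  n <- nrow(px)
  nw <- length(wl)
  if (nrow(sp) != n * nw) {
    abort(
      "every pixel must carry a full-length spectrum on the shared axis",
      class = "rededge_format_error"
    )
  }
  values <- matrix(sp$reflectance, nrow = n, ncol = nw, byrow = TRUE)
  # a pixel with any non-finite reflectance is masked outright
  bad <- !is.finite(values)
  if (any(bad)) {
    values[rowSums(bad) > 0, ] <- NA_real_
  }
  list(axis = wl, values = values, pixels = px)
}

# Inverse of cube_matrix().
cube_from_matrix <- function(axis, values, pixels) {
  n <- nrow(pixels)
  nw <- length(axis)
  tibble::tibble(
    pixel_row = rep(pixels$pixel_row, each = nw),
    pixel_col = rep(pixels$pixel_col, each = nw),
    wavelength_nm = rep(axis, times = n),
    reflectance = as.vector(t(values))
  )
}

# Accept either a cube or a bare spectrum (no pixel columns); a bare spectrum
# is promoted to a single-pixel cube and flagged so callers can return a
# scalar.
normalize_spectra <- function(x) {
  if (all(c("wavelength_nm", "reflectance") %in% names(x)) &&
      !("pixel_row" %in% names(x))) {
    x <- tibble::tibble(
      pixel_row = 0L, pixel_col = 0L,
      wavelength_nm = x$wavelength_nm, reflectance = x$reflectance
    )
    list(cube = x, scalar = TRUE)
  } else {
    list(cube = x, scalar = FALSE)
  }
}
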