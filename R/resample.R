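#' Spectrally resample a cube to a target band set
#'
#' Convolves each pixel's spectrum with a spectral response function (SRF)
#' for every band in `bandset`, producing a cube whose wavelength axis is the
#' band centers. The SRF is evaluated at the discrete source samples and the
#' band value is the normalized weighted mean of source reflectance, so a
#' spectrum that is constant within a band's support resamples to exactly
#' that constant.
#'
#' Two SRF shapes are available:
#' \describe{
#'   \item{`boxcar`}{Uniform weight on `[center - width/2, center + width/2]`.
#'     The conventional stand-in when a sensor's official response curves are
#'     not used.}
#'   \item{`gaussian`}{Gaussian with FWHM equal to the band width, truncated
#'     at +/- 2 FWHM.}
#' }
#'
#' @param spectra A cube tibble.
#' @param bandset A band-set tibble, e.g. [s2_bandset()].
#' @param srf SRF shape, `"boxcar"` (default) or `"gaussian"`.
#' @return A cube tibble on the band-center axis; masked pixels stay masked.
#' @examples
#' scene <- simulate_scene(scene_params(n_rows = 4, n_cols = 5, n_fields = 2))
#' s2 <- resample_cube(scene$spectra, s2_bandset())
#' @export
resample_cube <- function(spectra, bandset, srf = c("boxcar", "gaussian")) {
  srf <- match.arg(srf)
  cm <- cube_matrix(spectra)
  check_axis(cm$axis, min_len = 2)
  W <- srf_weights(cm$axis, bandset, srf)
  values <- cm$values %*% W
  cube_from_matrix(bandset$center_nm, values, cm$pixels)
}

#' Drop bands not covered by a source axis
#'
#' Returns the subset of `bandset` whose SRF support contains at least two
#' samples of `axis` (the precondition of [resample_cube()]). Handy before
#' resampling a cube of limited spectral range to a full sensor band set.
#'
#' @param bandset A band-set tibble.
#' @param axis Numeric source wavelength axis, nm.
#' @param srf SRF shape.
#' @param quiet Suppress the message listing dropped bands.
#' @return The covered subset of `bandset`.
#' @export
covered_bands <- function(bandset, axis, srf = c("boxcar", "gaussian"),
                          quiet = FALSE) {
  srf <- match.arg(srf)
  half <- if (srf == "boxcar") bandset$width_nm / 2 else 2 * bandset$width_nm
  n_in <- vapply(seq_len(nrow(bandset)), function(i) {
    sum(axis >= bandset$center_nm[i] - half[i] &
          axis <= bandset$center_nm[i] + half[i])
  }, integer(1))
  dropped <- bandset$band_id[n_in < 2]
  if (length(dropped) > 0 && !quiet) {
    inform(paste0("band(s) outside source coverage dropped: ",
                  paste(dropped, collapse = ", ")),
           class = "rededge_dropped_bands")
  }
  bandset[n_in >= 2, ]
}

# Weight matrix [n_source x n_bands]; each column sums to 1.
srf_weights <- function(axis, bandset, srf) {
  n <- length(axis)
  W <- matrix(0, nrow = n, ncol = nrow(bandset))
  for (i in seq_len(nrow(bandset))) {
    center <- bandset$center_nm[i]
    width <- bandset$width_nm[i]
    if (srf == "boxcar") {
      inside <- axis >= center - width / 2 & axis <= center + width / 2
      wts <- as.numeric(inside)
    } else {
      sigma <- width / (2 * sqrt(2 * log(2))) # FWHM -> sigma
      inside <- abs(axis - center) <= 2 * width
      wts <- ifelse(inside, exp(-(axis - center)^2 / (2 * sigma^2)), 0)
    }
    if (sum(inside) < 2) {
      abort(paste0(
        "band ", bandset$band_id[i], " (", center, " nm): fewer than 2 source",
        " samples fall inside its SRF support"
      ), class = "rededge_coverage_error")
    }
    W[, i] <- wts / sum(wts)
  }
  W
}
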