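#' Normalized difference index (NDI)
#'
#' Computes the generic two-band normalized difference
#' `(R_b - R_a) / (R_b + R_a)` per pixel, with `R_a` taken from the band
#' nearest `wl_a` and `R_b` from the band nearest `wl_b` (each within
#' `tolerance`). NDVI is the (670, 800) nm special case; the red-edge LAI
#' index used throughout this package is NDI(674, 712) on hyperspectral data
#' and NDI(665, 705) (Sentinel-2 B4/B5) on resampled data.
#'
#' Pixels whose two reflectances sum to zero are masked (0/0 carries no
#' information); the count is reported.
#'
#' @param spectra A cube tibble, or a bare spectrum tibble
#'   (`wavelength_nm`, `reflectance`), in which case a single value is
#'   returned.
#' @param wl_a,wl_b Requested band-center wavelengths, nm; must differ.
#' @param tolerance Maximum allowed |requested - nearest band|, nm. The 5 nm
#'   default absorbs small grid offsets such as 664 vs 665 nm.
#' @return An index-map tibble (`pixel_row`, `pixel_col`, `value`) with
#'   provenance in `attr(, "meta")`, or a single numeric for a bare spectrum.
#' @examples
#' sp <- tibble::tibble(wavelength_nm = c(674, 712), reflectance = c(0.05, 0.35))
#' ndi(sp, 674, 712) # 0.75
#' @export
ndi <- function(spectra, wl_a, wl_b, tolerance = 5) {
  if (wl_a == wl_b) {
    abort("wl_a and wl_b must differ", class = "rededge_usage_error")
  }
  ns <- normalize_spectra(spectra)
  cm <- cube_matrix(ns$cube)
  ia <- nearest_band(cm$axis, wl_a, tolerance)
  ib <- nearest_band(cm$axis, wl_b, tolerance)
  ra <- cm$values[, ia]
  rb <- cm$values[, ib]
  denom <- ra + rb
  value <- (rb - ra) / denom
  zero_den <- !is.na(denom) & denom == 0
  if (any(zero_den)) {
    value[zero_den] <- NA_real_
    inform(paste0(sum(zero_den), " pixel(s) masked: zero NDI denominator"),
           class = "rededge_masked")
  }
  meta <- list(
    index = "ndi",
    wl_a_requested = wl_a, wl_a_used = cm$axis[ia],
    wl_b_requested = wl_b, wl_b_used = cm$axis[ib]
  )
  if (ns$scalar) {
    return(value[[1]])
  }
  new_index_map(cm$pixels, value, meta)
}

nearest_band <- function(axis, wl, tolerance) {
  i <- which.min(abs(axis - wl))
  if (abs(axis[i] - wl) > tolerance) {
    abort(paste0("no band within ", tolerance, " nm of ", wl, " nm"),
          class = "rededge_lookup_error")
  }
  i
}

#' Normalized Area Over the reflectance Curve (NAOC)
#'
#' NAOC measures the depth of the chlorophyll absorption feature relative to
#' the far-red shoulder:
#' \deqn{NAOC = 1 - \frac{\int_a^b R\, d\lambda}{R_b (b - a)}}
#' with default limits a = 643 nm, b = 795 nm (normalization 152 x R(795)).
#' The reflectance curve is reconstructed per pixel by linear interpolation
#' between band-center values, extended as a constant beyond the outermost
#' centers (relevant for coarse band sets whose extreme centers, e.g.
#' Sentinel-2's 665 and 783 nm, lie inside the integration window), and
#' integrated by the composite trapezoid rule on a uniform grid of spacing
#' `sample_step`. `R_b` is the reconstructed reflectance at wavelength `b`.
#'
#' NAOC is invariant under rescaling of the spectrum, is always <= 1, and is
#' 0 for a flat spectrum. Pixels with `R_b <= 0` are masked and counted.
#'
#' @param spectra A cube tibble, or a bare spectrum tibble for a single value.
#' @param a,b Integration limits, nm (`a < b`).
#' @param sample_step Integration grid spacing, nm; must be positive and at
#'   most `(b - a) / 10`.
#' @return An index-map tibble, or a single numeric for a bare spectrum.
#' @examples
#' sp <- tibble::tibble(wavelength_nm = c(643, 795), reflectance = c(0, 0.4))
#' naoc(sp) # 0.5
#' @export
naoc <- function(spectra, a = 643, b = 795, sample_step = 1) {
  if (!(a < b)) {
    abort("integration limits must satisfy a < b",
          class = "rededge_usage_error")
  }
  if (sample_step <= 0 || sample_step > (b - a) / 10) {
    abort("sample_step must be in (0, (b - a)/10]",
          class = "rededge_usage_error")
  }
  ns <- normalize_spectra(spectra)
  cm <- cube_matrix(ns$cube)
  check_naoc_coverage(cm$axis, a, b)
  grid <- seq(a, b, by = sample_step)
  if (grid[length(grid)] < b) grid <- c(grid, b)
  A <- interp_weights(cm$axis, grid) # [n_bands x n_grid]
  curve <- cm$values %*% A
  tw <- trapezoid_weights(grid)
  integral <- as.vector(curve %*% tw)
  r_b <- curve[, length(grid)]
  value <- 1 - integral / (r_b * (b - a))
  bad_rb <- !is.na(r_b) & r_b <= 0
  if (any(bad_rb)) {
    value[bad_rb] <- NA_real_
    inform(paste0(sum(bad_rb), " pixel(s) masked: non-positive R(b)"),
           class = "rededge_masked")
  }
  meta <- list(index = "naoc", a = a, b = b, sample_step = sample_step,
               bands_used = cm$axis)
  if (ns$scalar) {
    return(value[[1]])
  }
  new_index_map(cm$pixels, value, meta)
}

check_naoc_coverage <- function(axis, a, b) {
  n_inside <- sum(axis >= a & axis <= b)
  straddles <- any(axis <= a) && any(axis >= b)
  if (n_inside < 2 && !straddles) {
    abort(paste0(
      "need at least 2 bands inside or straddling [", a, ", ", b, "] nm"
    ), class = "rededge_coverage_error")
  }
  invisible(axis)
}

# Linear-interpolation operator: R(grid) = values %*% A, with constant
# extrapolation beyond the outermost nodes (approx rule = 2).
interp_weights <- function(axis, grid) {
  n <- length(axis)
  A <- matrix(0, nrow = n, ncol = length(grid))
  for (j in seq_along(grid)) {
    g <- grid[j]
    if (g <= axis[1]) {
      A[1, j] <- 1
    } else if (g >= axis[n]) {
      A[n, j] <- 1
    } else {
      hi <- findInterval(g, axis, rightmost.closed = TRUE) + 1L
      lo <- hi - 1L
      t <- (g - axis[lo]) / (axis[hi] - axis[lo])
      A[lo, j] <- 1 - t
      A[hi, j] <- t
    }
  }
  A
}

# Composite trapezoid quadrature weights for an arbitrary sorted grid.
trapezoid_weights <- function(grid) {
  h <- diff(grid)
  w <- numeric(length(grid))
  w[1] <- h[1] / 2
  w[length(grid)] <- h[length(h)] / 2
  if (length(grid) > 2) {
    w[2:(length(grid) - 1)] <- (h[-length(h)] + h[-1]) / 2
  }
  w
}

#' NAOC with and without the red-edge bands
#'
#' For a cube on the Sentinel-2 axis, computes NAOC twice: once with all four
#' bands whose centers fall inside the integration window (B4 665, B5 705,
#' B6 740, B7 783 nm) as curve nodes, and once with the red-edge bands
#' ablated, i.e. only B4 and B7. Both use the same integration limits and
#' extrapolation rule, so the difference isolates what the red-edge bands
#' contribute to the reconstructed reflectance curve.
#'
#' @param spectra A cube tibble whose axis contains bands near 665, 705, 740
#'   and 783 nm.
#' @inheritParams naoc
#' @param tolerance Band-matching tolerance, nm.
#' @return A list with index maps `with_red_edge` and `without_red_edge`.
#' @export
naoc_bandset_variants <- function(spectra, a = 643, b = 795, sample_step = 1,
                                  tolerance = 5) {
  cm <- cube_matrix(spectra)
  centers <- c(665, 705, 740, 783)
  idx <- vapply(centers, function(w) {
    i <- which.min(abs(cm$axis - w))
    if (abs(cm$axis[i] - w) > tolerance) {
      abort(paste0("cube lacks a band within ", tolerance, " nm of ", w,
                   " nm (required for the red-edge variants)"),
            class = "rededge_coverage_error")
    }
    i
  }, integer(1))
  sub_cube <- function(keep) {
    cube_from_matrix(cm$axis[keep], cm$values[, keep, drop = FALSE], cm$pixels)
  }
  list(
    with_red_edge = naoc(sub_cube(idx), a = a, b = b,
                         sample_step = sample_step),
    without_red_edge = naoc(sub_cube(idx[c(1, 4)]), a = a, b = b,
                            sample_step = sample_step)
  )
}
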