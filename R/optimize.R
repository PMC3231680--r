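#' Exhaustive NDI band-pair optimization
#'
#' Searches every ordered pair (a, b) of candidate bands in
#' `[wl_min, wl_max]` for the pair whose NDI correlates best (Pearson r, in
#' absolute value) with a target biophysical parameter across pixels. On
#' hyperspectral campaign data over agricultural sites this style of search
#' selects an absorption band near 674 nm paired with a red-edge band near
#' 712 nm for green LAI.
#'
#' The full correlation surface is returned so the argmax can be audited: it
#' is antisymmetric, `r(a, b) = -r(b, a)`, because swapping the bands flips
#' the sign of NDI. The best pair is reported in the orientation giving
#' `r > 0`; exact ties are broken by smallest `a`, then smallest `b`. Pairs
#' whose NDI has zero variance across pixels are undefined (NA) and excluded
#' from the argmax.
#'
#' @param spectra A cube tibble (one spectrum per pixel).
#' @param target Numeric vector of the parameter (e.g. LAI), one value per
#'   pixel in `(pixel_row, pixel_col)` ascending order; must not be constant.
#' @param wl_min,wl_max Search window, nm; needs >= 2 candidate bands.
#' @return An object of class `ndi_surface`: list with `wavelengths`,
#'   `r_matrix` (rows = a, cols = b), `best_pair`, `best_r`, `n`. `tidy()`
#'   returns the surface in long form; `autoplot()` draws it.
#' @export
optimize_ndi <- function(spectra, target, wl_min, wl_max) {
  cm <- cube_matrix(spectra)
  n_px <- nrow(cm$pixels)
  if (n_px < 3) {
    abort("need at least 3 spectra", class = "rededge_usage_error")
  }
  if (length(target) != n_px) {
    abort("target length must equal the number of pixels",
          class = "rededge_usage_error")
  }
  if (stats::var(target, na.rm = TRUE) == 0 || all(is.na(target))) {
    abort("target is constant; correlation is undefined",
          class = "rededge_degenerate_target_error")
  }
  keep <- cm$axis >= wl_min & cm$axis <= wl_max
  wl <- cm$axis[keep]
  if (length(wl) < 2) {
    abort("fewer than 2 candidate bands in the search window",
          class = "rededge_coverage_error")
  }
  M <- cm$values[, keep, drop = FALSE]
  nw <- length(wl)
  r_mat <- matrix(NA_real_, nw, nw, dimnames = list(a = wl, b = wl))
  for (i in seq_len(nw - 1)) {
    ra <- M[, i]
    js <- (i + 1):nw
    nd <- (M[, js, drop = FALSE] - ra) / (M[, js, drop = FALSE] + ra)
    r_row <- suppressWarnings(as.vector(cor(nd, target,
                                            use = "pairwise.complete.obs")))
    sds <- apply(nd, 2, stats::sd, na.rm = TRUE)
    r_row[!is.finite(sds) | sds == 0] <- NA_real_
    r_mat[i, js] <- r_row
    r_mat[js, i] <- -r_row # NDI antisymmetry
  }
  finite <- which(is.finite(r_mat), arr.ind = TRUE)
  if (nrow(finite) == 0) {
    abort("all candidate pairs have undefined correlation",
          class = "rededge_degenerate_target_error")
  }
  vals <- abs(r_mat[finite])
  best_abs <- max(vals)
  cand <- finite[vals >= best_abs - 1e-15, , drop = FALSE]
  # orient each candidate so r > 0, then tie-break: smallest a, then b
  oriented <- t(apply(cand, 1, function(ij) {
    if (r_mat[ij[1], ij[2]] >= 0) c(ij[1], ij[2]) else c(ij[2], ij[1])
  }))
  a_wl <- wl[oriented[, 1]]
  b_wl <- wl[oriented[, 2]]
  ord <- order(a_wl, b_wl)
  best <- oriented[ord[1], ]
  structure(
    list(
      wavelengths = wl,
      r_matrix = r_mat,
      best_pair = c(a = wl[best[1]], b = wl[best[2]]),
      best_r = r_mat[best[1], best[2]],
      n = n_px
    ),
    class = "ndi_surface"
  )
}

#' @export
print.ndi_surface <- function(x, ...) {
  cat("NDI band-pair optimization surface\n")
  cat("  candidate bands:", length(x$wavelengths), "in [",
      min(x$wavelengths), ",", max(x$wavelengths), "] nm\n")
  cat(sprintf("  best pair: a = %g nm, b = %g nm (r = %.4f, n = %d)\n",
              x$best_pair[["a"]], x$best_pair[["b"]], x$best_r, x$n))
  invisible(x)
}

#' @export
tidy.ndi_surface <- function(x, ...) {
  grid <- expand.grid(a = x$wavelengths, b = x$wavelengths)
  tibble::tibble(
    wl_a = grid$a,
    wl_b = grid$b,
    r = as.vector(x$r_matrix)
  )
}

#' @export
glance.ndi_surface <- function(x, ...) {
  tibble::tibble(
    best_a = x$best_pair[["a"]],
    best_b = x$best_pair[["b"]],
    best_r = x$best_r,
    n_bands = length(x$wavelengths),
    n = x$n
  )
}

#' @export
autoplot.ndi_surface <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$wl_a, y = .data$wl_b,
                                    fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::annotate("point", x = object$best_pair[["a"]],
                      y = object$best_pair[["b"]], shape = 4, size = 3) +
    ggplot2::labs(x = "band a (nm)", y = "band b (nm)", fill = "r")
}
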