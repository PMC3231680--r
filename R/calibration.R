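#' Index-to-parameter calibration models
#'
#' Three empirical calibration forms link a spectral index to a biophysical
#' parameter:
#' \describe{
#'   \item{proportional}{`y = slope * x`, least squares through the origin
#'     (`slope = sum(xy) / sum(x^2)`). Used for the NDI-to-green-LAI
#'     relationship, whose printed forms carry no intercept: a bare-soil NDI
#'     near zero anchors the origin.}
#'   \item{linear}{`y = intercept + slope * x`, ordinary least squares. Used
#'     for the NAOC-to-leaf-chlorophyll relationship.}
#'   \item{exponential}{`y = A * exp(k * x)`, fitted in the log domain by OLS
#'     on `ln y` (deterministic and closed-form). Used for the
#'     NAOC-to-canopy-chlorophyll (Ch x LAI, g/m^2) relationship.}
#' }
#'
#' The stored `r` is the Pearson correlation between the index and the
#' response (log response for the exponential form); `NA` when the response
#' has zero variance.
#'
#' @param x Numeric index values (e.g. NDI or NAOC).
#' @param y Numeric response values (LAI, Ch, or Ch x LAI). For
#'   `fit_exponential()` all must be strictly positive.
#' @return A `calibration_model`: list with `kind`, `coefficients` (named),
#'   `r`, `n`, and the training `data`. Supports `predict()`, `tidy()`,
#'   `glance()`, `autoplot()`.
#' @examples
#' m <- fit_proportional(c(0.1, 0.3, 0.5), c(0.9, 2.4, 4.4))
#' predict(m, 0.4)
#' @export
fit_proportional <- function(x, y) {
  check_xy(x, y, min_n = 2)
  if (all(x == 0)) {
    abort("all index values are zero; proportional slope undefined",
          class = "rededge_degenerate_predictor_error")
  }
  slope <- sum(x * y) / sum(x^2)
  new_calibration(
    kind = "proportional",
    coefficients = c(slope = slope),
    r = safe_cor(x, y),
    n = length(x),
    data = tibble::tibble(x = x, y = y)
  )
}

#' @rdname fit_proportional
#' @export
fit_linear <- function(x, y) {
  check_xy(x, y, min_n = 2)
  if (stats::var(x) == 0) {
    abort("index values are constant; linear fit undefined",
          class = "rededge_degenerate_predictor_error")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  new_calibration(
    kind = "linear",
    coefficients = c(intercept = unname(fit$coefficients[1]),
                     slope = unname(fit$coefficients[2])),
    r = safe_cor(x, y),
    n = length(x),
    data = tibble::tibble(x = x, y = y)
  )
}

#' @rdname fit_proportional
#' @export
fit_exponential <- function(x, y) {
  check_xy(x, y, min_n = 3)
  bad <- which(y <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      "exponential fit requires y > 0; offending indices: ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) ", ..." else ""
    ), class = "rededge_domain_error")
  }
  if (stats::var(x) == 0) {
    abort("index values are constant; exponential fit undefined",
          class = "rededge_degenerate_predictor_error")
  }
  fit <- stats::lm.fit(cbind(1, x), log(y))
  new_calibration(
    kind = "exponential",
    coefficients = c(A = exp(unname(fit$coefficients[1])),
                     k = unname(fit$coefficients[2])),
    r = safe_cor(x, log(y)),
    n = length(x),
    data = tibble::tibble(x = x, y = y)
  )
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) {
    abort("x and y must have the same length", class = "rededge_usage_error")
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    abort("x and y must be finite", class = "rededge_usage_error")
  }
  if (length(x) < min_n) {
    abort(paste0("need at least ", min_n, " points"),
          class = "rededge_usage_error")
  }
  invisible(TRUE)
}

safe_cor <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  cor(x, y)
}

new_calibration <- function(kind, coefficients, r, n, data = NULL,
                            source = "fitted") {
  structure(
    list(kind = kind, coefficients = coefficients, r = r, n = n,
         data = data, source = source),
    class = "calibration_model"
  )
}

#' Fit a calibration from a data frame
#'
#' Tidy front door to [fit_proportional()], [fit_linear()] and
#' [fit_exponential()]: selects the index and target columns from `data`.
#'
#' @param data A data frame.
#' @param index,target Column names (tidy-eval) of the index and the
#'   response.
#' @param kind Calibration form.
#' @return A `calibration_model`.
#' @export
fit_calibration <- function(data, index, target,
                            kind = c("proportional", "linear", "exponential")) {
  kind <- match.arg(kind)
  x <- dplyr::pull(data, {{ index }})
  y <- dplyr::pull(data, {{ target }})
  ok <- is.finite(x) & is.finite(y)
  switch(kind,
    proportional = fit_proportional(x[ok], y[ok]),
    linear = fit_linear(x[ok], y[ok]),
    exponential = fit_exponential(x[ok], y[ok])
  )
}

#' Built-in empirical calibration presets
#'
#' Published calibration coefficients from airborne/spaceborne campaigns over
#' European agricultural sites, shipped so the calibration equations can be
#' applied without refitting:
#' \describe{
#'   \item{`ndi_lai_hyperspectral`}{Green LAI = 6.753 x NDI(674, 712)
#'     (r = 0.908), from spaceborne hyperspectral nadir spectra.}
#'   \item{`ndi_lai_s2`}{Green LAI = 8.452 x NDI at the Sentinel-2 B4/B5
#'     positions (r = 0.903).}
#'   \item{`naoc_ch`}{Leaf chlorophyll (ug/cm^2) = -3.8868 + 101.94 x NAOC
#'     (r = 0.909).}
#'   \item{`naoc_chlai`}{Canopy chlorophyll (g/m^2) =
#'     0.0219 x exp(10.02 x NAOC) (r = 0.795).}
#' }
#'
#' @param name Preset name.
#' @return A `calibration_model` with `source = "preset"` (no training data).
#' @examples
#' predict(calibration_preset("naoc_chlai"), 0) # 0.0219
#' @export
calibration_preset <- function(name = c("ndi_lai_hyperspectral", "ndi_lai_s2",
                                        "naoc_ch", "naoc_chlai")) {
  name <- match.arg(name)
  switch(name,
    ndi_lai_hyperspectral = new_calibration(
      "proportional", c(slope = 6.753), r = 0.908, n = NA_integer_,
      source = "preset"
    ),
    ndi_lai_s2 = new_calibration(
      "proportional", c(slope = 8.452), r = 0.903, n = NA_integer_,
      source = "preset"
    ),
    naoc_ch = new_calibration(
      "linear", c(intercept = -3.8868, slope = 101.94), r = 0.909,
      n = NA_integer_, source = "preset"
    ),
    naoc_chlai = new_calibration(
      "exponential", c(A = 0.0219, k = 10.02), r = 0.795, n = NA_integer_,
      source = "preset"
    )
  )
}

#' Apply a calibration model
#'
#' Elementwise application of the model's functional form to a numeric vector
#' or an index map; masked pixels propagate as `NA`.
#'
#' @param object A `calibration_model`.
#' @param newdata Numeric vector, or an index-map tibble with a `value`
#'   column.
#' @param ... Ignored.
#' @return Same shape as `newdata`; for an index map the returned map's
#'   metadata records the calibration applied.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  f <- switch(object$kind,
    proportional = function(x) object$coefficients[["slope"]] * x,
    linear = function(x) {
      object$coefficients[["intercept"]] + object$coefficients[["slope"]] * x
    },
    exponential = function(x) {
      object$coefficients[["A"]] * exp(object$coefficients[["k"]] * x)
    }
  )
  if (is.numeric(newdata)) {
    return(f(newdata))
  }
  if (!is.data.frame(newdata) || !("value" %in% names(newdata))) {
    abort("newdata must be numeric or an index map with a 'value' column",
          class = "rededge_usage_error")
  }
  meta <- c(map_meta(newdata),
            list(calibration = list(kind = object$kind,
                                    coefficients = as.list(object$coefficients))))
  new_index_map(newdata, f(newdata$value), meta)
}

#' @export
print.calibration_model <- function(x, ...) {
  eqn <- switch(x$kind,
    proportional = sprintf("y = %.6g x", x$coefficients[["slope"]]),
    linear = sprintf("y = %.6g + %.6g x", x$coefficients[["intercept"]],
                     x$coefficients[["slope"]]),
    exponential = sprintf("y = %.6g exp(%.6g x)", x$coefficients[["A"]],
                          x$coefficients[["k"]])
  )
  cat(sprintf("%s calibration (%s): %s  [r = %s, n = %s]\n",
              x$kind, x$source, eqn, format(x$r), format(x$n)))
  invisible(x)
}

#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, r = x$r, n = x$n, source = x$source)
}

#' @export
autoplot.calibration_model <- function(object, ...) {
  if (is.null(object$data)) {
    abort("preset calibrations carry no training data to plot",
          class = "rededge_usage_error")
  }
  rng <- range(object$data$x)
  grid <- tibble::tibble(x = seq(rng[1], rng[2], length.out = 200))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "index", y = "parameter",
                  title = sprintf("%s calibration (r = %.3f)", object$kind,
                                  object$r))
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `read_calibration()` returns a `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(kind = model$kind, coefficients = as.list(model$coefficients),
         r = model$r, n = model$n, source = model$source),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::fromJSON(path)
  new_calibration(
    kind = x$kind,
    coefficients = unlist(x$coefficients),
    r = if (is.null(x$r)) NA_real_ else x$r,
    n = if (is.null(x$n)) NA_integer_ else x$n,
    source = x$source
  )
}
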