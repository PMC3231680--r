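#' Validate a parameter map against ground truth
#'
#' Compares per-pixel predictions with a table of ground-truth points and
#' reports RMSE (units of the target variable), Pearson r (when n >= 3),
#' bias (`mean(pred - obs)`) and an optional per-class breakdown.
#'
#' @param pred An index-map tibble of predicted values.
#' @param truth A data frame with columns `pixel_row`, `pixel_col`, `value`
#'   and optionally `class_label` (e.g. crop type or field id).
#' @param aggregate `"point"` compares point-wise; `"class_mean"` first
#'   averages predictions and observations within each `class_label`,
#'   mirroring validation against per-plot averaged field measurements.
#' @return A `validation_report`: list with `rmse`, `r`, `bias`, `n` and
#'   `per_class` (tibble or `NULL`). Supports `tidy()` and `glance()`.
#' @export
validate_map <- function(pred, truth, aggregate = c("point", "class_mean")) {
  aggregate <- match.arg(aggregate)
  required <- c("pixel_row", "pixel_col", "value")
  if (!all(required %in% names(truth))) {
    abort("truth needs columns pixel_row, pixel_col, value",
          class = "rededge_usage_error")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(truth), obs = "value"),
    dplyr::rename(pred[c("pixel_row", "pixel_col", "value")], pred = "value"),
    by = c("pixel_row", "pixel_col")
  )
  joined <- dplyr::filter(joined, is.finite(.data$pred), is.finite(.data$obs))
  if (nrow(joined) == 0) {
    abort("no truth point falls on an unmasked pixel",
          class = "rededge_empty_overlap_error")
  }
  has_class <- "class_label" %in% names(joined)
  if (aggregate == "class_mean") {
    if (!has_class) {
      abort("class_mean aggregation needs a class_label column",
            class = "rededge_usage_error")
    }
    joined <- dplyr::summarise(
      dplyr::group_by(joined, .data$class_label),
      obs = mean(.data$obs), pred = mean(.data$pred), .groups = "drop"
    )
  }
  per_class <- NULL
  if (has_class && aggregate == "point") {
    per_class <- dplyr::summarise(
      dplyr::group_by(joined, .data$class_label),
      rmse = sqrt(mean((.data$pred - .data$obs)^2)),
      bias = mean(.data$pred - .data$obs),
      r = if (dplyr::n() >= 3) safe_cor(.data$pred, .data$obs) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  }
  new_validation_report(joined$pred, joined$obs, per_class = per_class)
}

new_validation_report <- function(pred, obs, per_class = NULL,
                                  pairs = NULL) {
  n <- length(pred)
  structure(
    list(
      rmse = sqrt(mean((pred - obs)^2)),
      bias = mean(pred - obs),
      r = if (n >= 3) safe_cor(pred, obs) else NA_real_,
      n = n,
      per_class = per_class,
      pairs = pairs
    ),
    class = "validation_report"
  )
}

#' Agreement between two maps on the same grid
#'
#' Map-versus-map comparison over jointly unmasked pixels (e.g. an index map
#' from resampled multispectral bands against the same index from the source
#' hyperspectral cube). Returns the same statistics as [validate_map()] plus
#' the paired values for scatter plotting.
#'
#' @param map_a,map_b Index-map tibbles on the same pixel grid (at least 3
#'   jointly unmasked pixels).
#' @return A `validation_report` whose `pairs` element is a tibble
#'   (`pixel_row`, `pixel_col`, `a`, `b`); `autoplot()` draws the scatter
#'   against the 1:1 line.
#' @export
map_agreement <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b))) {
    abort("maps must have the same shape", class = "rededge_usage_error")
  }
  pairs <- dplyr::inner_join(
    dplyr::rename(map_a[c("pixel_row", "pixel_col", "value")], a = "value"),
    dplyr::rename(map_b[c("pixel_row", "pixel_col", "value")], b = "value"),
    by = c("pixel_row", "pixel_col")
  )
  if (nrow(pairs) != nrow(map_a)) {
    abort("maps must cover the same pixel grid", class = "rededge_usage_error")
  }
  pairs <- dplyr::filter(pairs, is.finite(.data$a), is.finite(.data$b))
  if (nrow(pairs) < 3) {
    abort("need at least 3 jointly unmasked pixels",
          class = "rededge_usage_error")
  }
  rep <- new_validation_report(pairs$a, pairs$b, pairs = pairs)
  class(rep) <- c("map_agreement", class(rep))
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: rmse = %.4g, bias = %.4g, r = %s, n = %d\n",
              x$rmse, x$bias, format(x$r, digits = 4), x$n))
  if (!is.null(x$per_class)) {
    print(x$per_class)
  }
  invisible(x)
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, bias = x$bias, r = x$r, n = x$n)
}

#' @export
tidy.validation_report <- function(x, ...) {
  if (!is.null(x$per_class)) {
    x$per_class
  } else {
    glance(x)
  }
}

#' @export
autoplot.map_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "map a", y = "map b",
      title = sprintf("r = %.3f, rmse = %.3g, n = %d", object$r, object$rmse,
                      object$n)
    )
}

#' Write a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(rmse = report$rmse, bias = report$bias, r = report$r,
              n = report$n)
  if (!is.null(report$per_class)) {
    out$per_class <- report$per_class
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
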