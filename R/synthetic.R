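#' Synthetic canopy scene simulator
#'
#' Forward-simulates a reflectance cube with known per-pixel ground truth, so
#' the whole retrieval pipeline can be exercised without campaign data. The
#' model is deliberately minimal but reproduces the spectral features the
#' indices exploit:
#'
#' * **Leaf reflectance.** An exponential-absorption model,
#'   `R_leaf = R_inf + (R_max - R_inf) * exp(-ch * eps(lambda))` with
#'   `R_max = 0.5`, `R_inf = 0.05`, and specific absorption
#'   `eps = 0.06 G(670, 40) + 0.03 G(500, 30)` (unit-height Gaussians,
#'   center/sigma in nm). This yields a chlorophyll-driven absorption feature
#'   near 670 nm, a red-edge transition whose position deepens with `ch`, and
#'   a chlorophyll-insensitive NIR plateau above ~780 nm.
#' * **Soil.** A spectrally bland brightness ramp
#'   `R_soil = 0.10 + 0.00025 (lambda - 400)`, clipped to \[0, 0.45\].
#' * **Canopy mixing.** Gap-fraction weighting with extinction coefficient
#'   0.5: fractional cover `f = 1 - exp(-0.5 LAI)`, canopy reflectance
#'   `f R_leaf + (1 - f) R_soil`.
#'
#' `simulate_scene()` partitions the pixel grid into contiguous rectangular
#' fields, draws field-level LAI and chlorophyll uniformly from the
#' configured ranges (a fraction of fields is bare soil, LAI = 0), applies
#' +/-10% per-pixel jitter, builds spectra, and adds i.i.d. additive Gaussian
#' sensor noise per band. All draws flow from `params$seed` in one fixed
#' order (field LAI, field Ch, soil-field selection, LAI jitter, Ch jitter,
#' noise), so scenes are bit-for-bit reproducible.
#'
#' @param ch Leaf chlorophyll content, ug/cm^2 (>= 0).
#' @param axis Numeric wavelength axis, nm.
#' @return `leaf_reflectance()` and `soil_spectrum()` return spectrum tibbles
#'   (`wavelength_nm`, `reflectance`).
#' @examples
#' head(leaf_reflectance(30, 400:450))
#' @export
leaf_reflectance <- function(ch, axis) {
  if (ch < 0) {
    abort("chlorophyll content must be non-negative",
          class = "rededge_domain_error")
  }
  check_axis(axis)
  tibble::tibble(
    wavelength_nm = as.numeric(axis),
    reflectance = as.vector(0.05 + 0.45 * exp(-ch * specific_absorption(axis)))
  )
}

specific_absorption <- function(axis) {
  gauss <- function(l, center, sigma) exp(-(l - center)^2 / (2 * sigma^2))
  0.06 * gauss(axis, 670, 40) + 0.03 * gauss(axis, 500, 30)
}

#' @rdname leaf_reflectance
#' @export
soil_spectrum <- function(axis) {
  check_axis(axis)
  tibble::tibble(
    wavelength_nm = as.numeric(axis),
    reflectance = pmin(pmax(0.10 + 0.00025 * (axis - 400), 0), 0.45)
  )
}

#' @rdname leaf_reflectance
#' @param leaf,soil Spectrum tibbles on the same axis.
#' @param lai Leaf area index, m^2/m^2 (>= 0).
#' @export
canopy_reflectance <- function(leaf, soil, lai) {
  if (lai < 0) {
    abort("LAI must be non-negative", class = "rededge_domain_error")
  }
  if (!isTRUE(all.equal(leaf$wavelength_nm, soil$wavelength_nm))) {
    abort("leaf and soil spectra must share the same wavelength axis",
          class = "rededge_usage_error")
  }
  f <- 1 - exp(-0.5 * lai)
  tibble::tibble(
    wavelength_nm = leaf$wavelength_nm,
    reflectance = f * leaf$reflectance + (1 - f) * soil$reflectance
  )
}

#' Scene simulation parameters
#'
#' Defaults emulate the structure of the agricultural validation campaigns:
#' crop fields spanning green LAI 0-6 m^2/m^2 and leaf chlorophyll
#' 10-60 ug/cm^2, 15% bare-soil fields, and additive sensor noise of
#' 0.005 reflectance units per band on a 1 nm axis over 400-1000 nm.
#'
#' @param n_rows,n_cols Pixel grid size.
#' @param n_fields Number of contiguous rectangular fields.
#' @param lai_range,ch_range Field-level uniform sampling ranges.
#' @param soil_fraction Fraction of fields set to bare soil (LAI = 0).
#' @param noise_sd_additive Gaussian noise standard deviation, reflectance
#'   units.
#' @param axis Output wavelength axis, nm.
#' @param seed Integer RNG seed; every stochastic draw derives from it.
#' @return A `scene_params` list.
#' @export
scene_params <- function(n_rows = 40, n_cols = 50, n_fields = 40,
                         lai_range = c(0, 6), ch_range = c(10, 60),
                         soil_fraction = 0.15, noise_sd_additive = 0.005,
                         axis = 400:1000, seed = 1L) {
  p <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_fields = as.integer(n_fields),
    lai_range = as.numeric(lai_range), ch_range = as.numeric(ch_range),
    soil_fraction = as.numeric(soil_fraction),
    noise_sd_additive = as.numeric(noise_sd_additive),
    axis = as.numeric(axis), seed = as.integer(seed)
  )
  stopifnot(
    p$n_rows >= 1, p$n_cols >= 1, p$n_fields >= 1,
    length(p$lai_range) == 2, diff(p$lai_range) >= 0, p$lai_range[1] >= 0,
    length(p$ch_range) == 2, diff(p$ch_range) >= 0, p$ch_range[1] >= 0,
    p$soil_fraction >= 0, p$soil_fraction <= 1,
    p$noise_sd_additive >= 0
  )
  check_axis(p$axis, min_len = 2)
  structure(p, class = "scene_params")
}

#' Simulate a scene
#'
#' @param params A [scene_params()] object.
#' @return A list with `spectra` (cube tibble) and `truth` (tibble with
#'   `pixel_row`, `pixel_col`, `lai` m^2/m^2, `ch` ug/cm^2, `ch_lai` g/m^2 =
#'   `ch * lai * 0.01`, `class_label`).
#' @examples
#' scene <- simulate_scene(scene_params(n_rows = 6, n_cols = 6, n_fields = 4,
#'                                      seed = 7))
#' @rdname leaf_reflectance
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  layout <- field_layout(params$n_rows, params$n_cols, params$n_fields)
  n_px <- params$n_rows * params$n_cols
  nf <- params$n_fields
  withr::with_seed(params$seed, {
    field_lai <- runif(nf, params$lai_range[1], params$lai_range[2])
    field_ch <- runif(nf, params$ch_range[1], params$ch_range[2])
    n_soil <- round(params$soil_fraction * nf)
    soil_fields <- if (n_soil > 0) sample(nf, n_soil) else integer(0)
    field_lai[soil_fields] <- 0
    lai <- pmax(field_lai[layout$field] * (1 + runif(n_px, -0.1, 0.1)), 0)
    ch <- field_ch[layout$field] * (1 + runif(n_px, -0.1, 0.1))
    eps <- specific_absorption(params$axis)
    soil_r <- soil_spectrum(params$axis)$reflectance
    leaf_m <- 0.05 + 0.45 * exp(-outer(ch, eps)) # [n_px x n_wl]
    f <- 1 - exp(-0.5 * lai)
    values <- f * leaf_m + outer(1 - f, soil_r)
    if (params$noise_sd_additive > 0) {
      values <- values + matrix(rnorm(length(values), 0,
                                      params$noise_sd_additive),
                                nrow = n_px)
    }
  })
  is_soil <- layout$field %in% soil_fields
  truth <- tibble::tibble(
    pixel_row = layout$pixel_row,
    pixel_col = layout$pixel_col,
    lai = lai,
    ch = ch,
    ch_lai = ch * lai * 0.01, # ug/cm^2 x m^2/m^2 -> g/m^2
    class_label = ifelse(is_soil, sprintf("soil_%02d", layout$field),
                         sprintf("field_%02d", layout$field))
  )
  spectra <- cube_from_matrix(params$axis, values,
                              layout[c("pixel_row", "pixel_col")])
  list(spectra = spectra, truth = truth, params = params)
}

# Partition the grid into n_fields contiguous rectangles: the field count is
# factored into the most nearly square (rows x cols) arrangement and the grid
# split into near-equal blocks.
field_layout <- function(n_rows, n_cols, n_fields) {
  divs <- which(n_fields %% seq_len(n_fields) == 0)
  fr <- max(divs[divs <= sqrt(n_fields)])
  fc <- n_fields %/% fr
  if (n_rows < fr || n_cols < fc) {
    abort(paste0("grid too small for ", n_fields, " fields (needs at least ",
                 fr, " x ", fc, " pixels)"),
          class = "rededge_usage_error")
  }
  row_block <- ceiling(seq_len(n_rows) / (n_rows / fr))
  col_block <- ceiling(seq_len(n_cols) / (n_cols / fc))
  px <- expand.grid(pixel_col = seq_len(n_cols) - 1L,
                    pixel_row = seq_len(n_rows) - 1L)
  px <- tibble::as_tibble(px[c("pixel_row", "pixel_col")])
  px$field <- (row_block[px$pixel_row + 1L] - 1L) * fc +
    col_block[px$pixel_col + 1L]
  px
}
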