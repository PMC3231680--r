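# Bare spectra (no pixel columns) make index functions return scalars.
bare_spectrum <- function(wavelength_nm, reflectance) {
  tibble::tibble(wavelength_nm = wavelength_nm, reflectance = reflectance)
}

test_that("ndi reproduces hand-computed values and boundary cases", {
  expect_equal(ndi(bare_spectrum(c(674, 712), c(0.2, 0.2)), 674, 712), 0)
  expect_equal(ndi(bare_spectrum(c(674, 712), c(0, 0.4)), 674, 712), 1)
  expect_equal(ndi(bare_spectrum(c(674, 712), c(0.05, 0.35)), 674, 712),
               (0.35 - 0.05) / (0.35 + 0.05))
})

test_that("ndi picks the nearest band within tolerance and errors beyond it", {
  sp <- bare_spectrum(c(664, 706), c(0.1, 0.3))
  expect_equal(ndi(sp, 665, 705), 0.5)
  expect_error(ndi(sp, 600, 706), regexp = "600",
               class = "rededge_lookup_error")
  expect_error(ndi(sp, 664, 664), class = "rededge_usage_error")
})

test_that("zero-denominator pixels are masked with a reported count", {
  cube <- matrix_cube(c(674, 712), rbind(c(0.1, 0.3), c(0.2, -0.2)))
  expect_message(m <- ndi(cube, 674, 712), class = "rededge_masked")
  expect_equal(m$value[1], 0.5)
  expect_true(is.na(m$value[2]))
})

test_that("ndi is antisymmetric and bounded by 1 for non-negative reflectance", {
  scene <- tiny_scene(seed = 4)
  ab <- ndi(scene$spectra, 674, 712)
  ba <- ndi(scene$spectra, 712, 674)
  expect_equal(ab$value, -ba$value)
  noiseless <- tiny_scene(seed = 4, noise = 0)
  m <- ndi(noiseless$spectra, 674, 712)
  expect_true(all(abs(m$value) <= 1))
})

test_that("ndi map metadata records the wavelengths actually used", {
  m <- ndi(pixel_cube(c(664, 706), c(0.1, 0.3)), 665, 705)
  meta <- map_meta(m)
  expect_equal(meta$wl_a_used, 664)
  expect_equal(meta$wl_b_used, 706)
  expect_equal(meta$wl_a_requested, 665)
})

test_that("naoc is zero for flat spectra and 0.5 for the closed-form triangle", {
  expect_equal(naoc(bare_spectrum(seq(643, 795, by = 2), rep(0.3, 77))), 0)
  expect_equal(naoc(bare_spectrum(c(643, 795), c(0, 0.4))), 0.5)
})

test_that("naoc is scale-invariant and never exceeds 1", {
  scene <- tiny_scene(seed = 6, noise = 0)
  cube <- scene$spectra
  m1 <- naoc(cube)
  scaled <- dplyr::mutate(cube, reflectance = 7.3 * reflectance)
  m2 <- naoc(scaled)
  expect_equal(m1$value, m2$value, tolerance = 1e-12)
  expect_true(all(m1$value <= 1, na.rm = TRUE))
})

test_that("trapezoid naoc at 1 nm agrees with 0.1 nm within 1e-3 on scene spectra", {
  scene <- tiny_scene(seed = 8, n_rows = 5, n_cols = 8, n_fields = 4)
  coarse <- naoc(scene$spectra, sample_step = 1)
  fine <- naoc(scene$spectra, sample_step = 0.1)
  expect_lt(max(abs(coarse$value - fine$value), na.rm = TRUE), 1e-3)
})

test_that("naoc matches an independent dense-grid trapezoid oracle", {
  axis <- 400:1000
  canopy <- canopy_reflectance(leaf_reflectance(35, axis),
                               soil_spectrum(axis), 3)
  expect_equal(
    naoc(canopy),
    naoc_oracle(canopy$wavelength_nm, canopy$reflectance),
    tolerance = 1e-10
  )
})

test_that("naoc masks pixels with non-positive shoulder reflectance", {
  cube <- matrix_cube(c(643, 795), rbind(c(0.1, 0.4), c(0.1, -0.01)))
  expect_message(m <- naoc(cube), class = "rededge_masked")
  expect_true(is.na(m$value[2]))
  expect_false(is.na(m$value[1]))
})

test_that("naoc demands spectral coverage of the integration window", {
  expect_error(naoc(bare_spectrum(c(850, 900), c(0.4, 0.4))),
               class = "rededge_coverage_error")
  expect_error(naoc(bare_spectrum(c(643, 795), c(0.1, 0.4)), sample_step = 50),
               class = "rededge_usage_error")
  # a straddling pair of bands is enough
  expect_equal(naoc(bare_spectrum(c(600, 850), c(0.2, 0.2))), 0)
})

test_that("red-edge band ablation variants behave per the curve geometry", {
  s2_axis <- c(665, 705, 740, 783)
  v <- naoc_bandset_variants(pixel_cube(s2_axis, rep(0.25, 4)))
  expect_equal(v$with_red_edge$value, 0)
  expect_equal(v$without_red_edge$value, 0)

  linear <- pixel_cube(s2_axis, 0.1 + 0.001 * (s2_axis - 665))
  v <- naoc_bandset_variants(linear)
  expect_equal(v$with_red_edge$value, v$without_red_edge$value,
               tolerance = 1e-10)

  # convex red edge: the 4-node curve tracks the fine-grid truth better
  axis <- 400:1000
  canopy <- canopy_reflectance(leaf_reflectance(40, axis),
                               soil_spectrum(axis), 4)
  fine_truth <- naoc_oracle(canopy$wavelength_nm, canopy$reflectance)
  cube <- pixel_cube(canopy$wavelength_nm, canopy$reflectance)
  s2 <- resample_cube(cube, subset_bands(s2_bandset(),
                                         c("B4", "B5", "B6", "B7")))
  v <- naoc_bandset_variants(s2)
  err_with <- abs(v$with_red_edge$value - fine_truth)
  err_without <- abs(v$without_red_edge$value - fine_truth)
  expect_false(isTRUE(all.equal(v$with_red_edge$value,
                                v$without_red_edge$value)))
  expect_lt(err_with, err_without)

  expect_error(naoc_bandset_variants(pixel_cube(c(665, 783), c(0.1, 0.4))),
               class = "rededge_coverage_error")
})

test_that("optimize_ndi recovers a pair whose NDI is the target exactly", {
  scene <- tiny_scene(seed = 1, n_rows = 5, n_cols = 8, n_fields = 4,
                      axis = seq(650, 730, by = 4))
  target_map <- ndi(scene$spectra, 674, 710)
  surf <- optimize_ndi(scene$spectra, target_map$value, 650, 730)
  expect_equal(unname(surf$best_pair), c(674, 710))
  expect_equal(surf$best_r, 1, tolerance = 1e-12)
})

test_that("optimize_ndi's best pair matches an independent brute-force scan", {
  scene <- tiny_scene(seed = 12, n_rows = 5, n_cols = 8, n_fields = 4,
                      axis = seq(600, 800, by = 10))
  truth <- scene$truth$lai
  surf <- optimize_ndi(scene$spectra, truth, 600, 800)
  cm_axis <- sort(unique(scene$spectra$wavelength_nm))
  best_abs <- 0
  for (a in cm_axis) {
    for (b in cm_axis) {
      if (a == b) next
      nd <- ndi(scene$spectra, a, b)$value
      if (stats::sd(nd) == 0) next
      best_abs <- max(best_abs, abs(cor(nd, truth)))
    }
  }
  expect_equal(abs(surf$best_r), best_abs, tolerance = 1e-12)
  expect_true(all(abs(surf$r_matrix) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(surf$r_matrix, -t(surf$r_matrix), ignore_attr = TRUE)
})

test_that("optimize_ndi pairs the absorption core with a shoulder band for LAI", {
  # the simulator's absorption feature is symmetric about 670 nm, so the
  # short-wavelength shoulder is as informative as the red edge: require one
  # band in the absorption core and its partner on a shoulder
  scene <- simulate_scene(scene_params(n_rows = 10, n_cols = 20,
                                       n_fields = 10, seed = 1))
  surf <- optimize_ndi(scene$spectra, scene$truth$lai, 600, 800)
  expect_gte(surf$best_pair[["a"]], 650)
  expect_lte(surf$best_pair[["a"]], 690)
  expect_gte(abs(surf$best_pair[["b"]] - 670), 30)
  expect_gte(abs(surf$best_r), max(abs(surf$r_matrix), na.rm = TRUE))
  # without sensor noise the optimum sits at absorption core vs red edge
  noiseless <- simulate_scene(scene_params(n_rows = 10, n_cols = 20,
                                           n_fields = 10, seed = 1,
                                           noise_sd_additive = 0))
  surf0 <- optimize_ndi(noiseless$spectra, noiseless$truth$lai, 600, 800)
  expect_gte(surf0$best_pair[["a"]], 650)
  expect_lte(surf0$best_pair[["a"]], 690)
  expect_gte(surf0$best_pair[["b"]], 700)
  expect_lte(surf0$best_pair[["b"]], 750)
})

test_that("optimize_ndi rejects degenerate targets", {
  scene <- tiny_scene(seed = 3, n_rows = 4, n_cols = 5, n_fields = 2)
  expect_error(
    optimize_ndi(scene$spectra, rep(1, 20), 600, 800),
    class = "rededge_degenerate_target_error"
  )
})
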