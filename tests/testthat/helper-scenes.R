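# Shared fixture builders: everything is generated in code at test time.

tiny_scene <- function(seed = 1, noise = 0.005, n_rows = 10, n_cols = 20,
                       n_fields = 8, axis = 400:1000) {
  simulate_scene(scene_params(
    n_rows = n_rows, n_cols = n_cols, n_fields = n_fields,
    noise_sd_additive = noise, axis = axis, seed = seed
  ))
}

# A single-pixel cube with given wavelengths and reflectances.
pixel_cube <- function(wavelength_nm, reflectance) {
  as_cube(tibble::tibble(
    pixel_row = 0L, pixel_col = 0L,
    wavelength_nm = wavelength_nm, reflectance = reflectance
  ), quiet = TRUE)
}

# A multi-pixel cube from a pixel x wavelength matrix.
matrix_cube <- function(axis, values) {
  n <- nrow(values)
  as_cube(tibble::tibble(
    pixel_row = rep(seq_len(n) - 1L, each = length(axis)),
    pixel_col = 0L,
    wavelength_nm = rep(axis, times = n),
    reflectance = as.vector(t(values))
  ), quiet = TRUE)
}

# A bare parameter map (column layout of an index map) for validation tests.
new_map_for_test <- function(values) {
  tibble::tibble(pixel_row = seq_along(values) - 1L, pixel_col = 0L,
                 value = values)
}

# Brute-force NAOC oracle: trapezoid over [a, b] on an axis that already
# samples the interval densely (no interpolation machinery shared with the
# implementation).
naoc_oracle <- function(wavelength_nm, reflectance, a = 643, b = 795) {
  sel <- wavelength_nm >= a & wavelength_nm <= b
  l <- wavelength_nm[sel]
  r <- reflectance[sel]
  integral <- sum(diff(l) * (r[-1] + r[-length(r)]) / 2)
  1 - integral / (r[length(r)] * (b - a))
}
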