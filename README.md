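# rededge

Empirical retrieval of **green leaf area index (LAI)** and **canopy
chlorophyll** from hyperspectral and Sentinel-2-like multispectral
reflectance, built around the red-edge spectral region (~690–750 nm) where
chlorophyll absorption gives way to the NIR plateau.

The package is aimed at vegetation remote-sensing practitioners who want to
compute red-edge indices, calibrate them against field measurements, and
quantify what the Sentinel-2 red-edge bands (B5 at 705 nm, B6 at 740 nm)
contribute — all on tidyverse-style tabular data (cubes are long tibbles,
results are tibbles or broom-friendly model objects).

## Methods

**Normalized difference index (NDI).** For bands at wavelengths *a* and *b*,

    NDI(a, b) = (R_b − R_a) / (R_b + R_a)

NDVI is the (670, 800) nm special case. `optimize_ndi()` exhaustively scans
all band pairs in a window for the pair whose NDI correlates best with a
target parameter and returns the full Pearson-r surface. Green LAI follows
from a proportional (through-origin) calibration `LAI = s · NDI`; shipped
presets are `s = 6.753` for the hyperspectral pair (674, 712 nm) and
`s = 8.452` for the Sentinel-2 B4/B5 pair.

**Normalized Area Over the reflectance Curve (NAOC).**

    NAOC = 1 − ∫[a,b] R dλ / (R_b · (b − a)),   a = 643 nm, b = 795 nm

computed by trapezoidal integration of the piecewise-linear reflectance
curve through the band centers (constant extension beyond the outermost
centers). Leaf chlorophyll (µg/cm²) follows from the linear preset
`Ch = −3.8868 + 101.94 · NAOC`; canopy chlorophyll (g/m²) from the
exponential preset `Ch·LAI = 0.0219 · exp(10.02 · NAOC)`.

A seeded forward simulator (`simulate_scene()`) provides field-structured
scenes with known per-pixel LAI, Ch and Ch·LAI spanning LAI 0–6 and
Ch 10–60 µg/cm², so every stage is testable without campaign data.

## Worked example

```r
library(rededge)

scene <- simulate_scene(scene_params(n_rows = 20, n_cols = 30,
                                     n_fields = 12, seed = 101))
abl <- run_naoc_ablation(scene$spectra, truth = scene$truth,
                         calibration = "fit")
abl
#> NAOC red-edge ablation
#> exponential calibration (fitted): y = 0.0365927 exp(7.87591 x)  [r = 0.9805372, n = 502]
#>   naoc_with_red_edge           r = 0.9965  rmse = 0.01759
#>   naoc_without_red_edge        r = 0.9914  rmse = 0.05577
#>   ch_lai_with_red_edge         r = 0.9966  rmse = 0.1288
#>   ch_lai_without_red_edge      r = 0.9738  rmse = 0.546
```

The exponential Ch·LAI calibration is fitted on the reference (fine-band)
NAOC map against the scene's true canopy chlorophyll (502 vegetated pixels).
Each resampled NAOC variant is then compared against the reference map:
with the red-edge bands B5/B6 included the Ch·LAI map tracks the reference
almost perfectly (r = 0.997, RMSE 0.13 g/m²); with only B4 and B7 the
reconstructed reflectance curve misses the red-edge convexity and the
exponential calibration amplifies the error four-fold (RMSE 0.55 g/m²),
which is the quantitative case for the red-edge bands.

The LAI branch works the same way:

```r
lai <- run_lai_experiment(scene$spectra, truth = scene$truth,
                          calibration = "fit")
glance(lai$agreement)   # S2-band vs hyperspectral-band LAI map
#> # A tibble: 1 × 4
#>    rmse   bias     r     n
#>   <dbl>  <dbl> <dbl> <int>
#> 1 0.416 0.0852 0.957   600
```

`autoplot()` methods draw index maps, optimization surfaces, calibration
curves and agreement scatters; `tidy()`/`glance()` give tabular summaries.

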