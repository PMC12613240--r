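# cestr

Quantitative CEST-MRI Z-spectrum analysis in R: multi-pool Lorentzian
fitting, field-inhomogeneity correction, relaxation-compensated contrasts,
and atlas-ROI statistics — with a synthetic multi-subject brain phantom for
end-to-end validation.

## What this package is for

Chemical exchange saturation transfer (CEST) MRI saturates dilute
exchangeable protons off-resonance and reads their signature out of the
water signal. The normalized Z-spectrum, Z(Δω) = M_sat/M0, carries
overlapping contributions from direct water saturation (DS), amide protons
(+3.5 ppm), relayed NOEs (−3.5 ppm) and semi-solid magnetization transfer
(ssMT, modeled at −2.5 ppm). Quantifying the individual pools at 3 T
requires a processing chain whose pieces this package implements and tests:

* **Normalization** against two drifting M0 frames (linear interpolation by
  acquisition index);
* **B0 correction** by spectral resampling along the offset axis
  (shape-preserving monotone-cubic interpolation);
* **Field mapping**: WASABI fitting for B0 and relative B1
  (multi-start least squares of
  `|c − d·sin²(atan(γB1/(Δω−δω)))·sin²(½ t_p √((γB1)²+(Δω−δω)²))|`),
  and saturation-recovery T1 fitting of `S(t) = A(1 − e^(−t/T1))`;
* **PCA denoising** of the Z-stack (noise-edge component selection by
  default, Malinowski indicator optional);
* **Four-pool Lorentzian fitting**,
  `Z(Δω) = z0 − c − Σ A_i (Γ_i/2)² / ((Γ_i/2)² + (Δω − δ_i)²)`,
  by bounded nonlinear least squares with a compiled objective;
* **Contrasts**: `MTR_Rex = 1/Z_lab − 1/Z_ref`, `LD = Z_ref − Z_lab`,
  `AREX = MTR_Rex/T1`, the APTw asymmetry
  `[Z(−3.5) − Z(+3.5)]·100%` with per-side quadratic, B0-corrected
  evaluation, and fluid-suppressed APTw `APTw·(0.35/Z(−3.5))²`;
* **Two-point B1 correction**: the contrast measured at relB1·(0.6, 0.9) uT
  defines a per-voxel line evaluated at 0.7 uT;
* **ROI statistics**: per-region/tissue summaries, exact and approximate
  two-sided Mann-Whitney U tests, Shapiro-Wilk screening, coefficients of
  variation, and a voxel-wise contrast-vs-B1 regression check.

Because no volunteer data are redistributable, the package ships a
**synthetic phantom** (`make_subject()`, `simulate_cohort()`): an
ellipsoidal GM/WM slab partitioned into frontal (FL), parietotemporal
(ParTem), occipital (OC) and calcarine (Ccs) ROIs, whose regional contrast
truths are published 3-T group reference values with the published
between-subject SDs as jitter, forward-modeled through the same acquisition
geometry (two low-power whole-Z-spectrum series at 0.6/0.9 uT with 57
offsets in ±250 ppm, a 16-offset 2 uT APTw series, WASABI, saturation
recovery), under noise, M0 drift, and smooth B0/B1 field inhomogeneity.

## Worked example

```r
library(cestr)

# one synthetic subject under the default stated world
config  <- phantom_config(seed = 42)          # 48x40x8 slab, 0.7% noise
subject <- make_subject(config, subject_index = 1)

# full processing: field maps, preprocessing, fitting, contrasts
result <- process_subject(subject)
tab <- summarize_subject(result)
subset(tab, contrast == "MTRRex_amide" & tissue == "GM",
       select = c(region, n, mean, sd, median))
#>     region    n   mean       sd median
#> 1       FL  848 0.1735 0.012686 0.1733
#> 2   ParTem  756 0.2155 0.012288 0.2149
#> 3       OC  800 0.2099 0.009727 0.2096
#> 4      Ccs  284 0.2296 0.009568 0.2286
#> 9 Combined 2688 0.2021 0.023178 0.2070
```

The medians track this subject's jittered regional truths (0.1736, 0.2154,
0.2101, 0.2295 after jittering the presets 0.19, 0.205, 0.21, 0.23) to
within about 1e-3: the anterior B1 drop (relative B1 ~ 0.74 frontally) and
the B0 field have been removed by the WASABI-based two-point correction and
spectral shifting, and the remaining spread is voxel noise.

A whole cohort with group statistics (the group table holds the mean ± SD
of per-subject ROI medians, the group-reference analog):

```r
run <- run_pipeline(phantom_config(seed = 42), out_dir = "out/")
subset(run$group_table, tissue == "GM" & region == "Combined" &
                        contrast %in% c("MTRRex_amide", "MTRRex_ssMT", "T1"))
#>   tissue   region     contrast n_subjects mean_median sd_median
#>       GM Combined MTRRex_amide         10      0.2072    0.0061
#>       GM Combined  MTRRex_ssMT         10      0.3728    0.0082
#>       GM Combined           T1         10      1.4526    0.0161
```

`out/` then contains `table1_subjects.csv`, `table2_group.csv`,
`tests.csv` (pairwise Mann-Whitney results), `cv.csv`, the serialized run
configuration and an md5 manifest.

There is also a command-line interface:

```sh
Rscript inst/cli/cest.R run-all --out out --seed 42
Rscript inst/cli/cest.R simulate --out phantoms --subjects 10 --seed 42
Rscript inst/cli/cest.R report --run out --out out/report.md
```

## Layout

```
R/                  implementation (geometry/NIfTI IO, phantom, field maps,
                    preprocessing, Lorentzian fitting, contrasts, ROI stats,
                    pipeline, CLI)
src/                compiled four-pool objective (Rcpp)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/cest-quantification.Rmd   methods and design rationale
inst/cli/cest.R     command-line launcher
```
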