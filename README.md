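# gliogrow

Diffuse gliomas infiltrate far beyond their outline on MRI, which makes
both therapy planning and growth forecasting ill-posed: the clinician sees
two threshold-like contours (the contrast-enhancing core, the T2-FLAIR
edema), not the underlying tumor cell density or the growth parameters.
`gliogrow` is an R toolkit for studying this problem end to end with the
anisotropic Fisher–KPP reaction–diffusion model:

* **Forward model.** Normalized tumor cell density `c(x, t)` evolves as
  `dc/dt = div(D(x) grad c) + rho c (1 - c)` over a voxelized brain domain
  with no-flux boundaries, solved by a conservative flux-form forward-Euler
  scheme (Rcpp). The tumor tensor `D(x)` is built from a DTI-style water
  tensor by sharpening its anisotropy (Westin shape measures, anisotropy
  factor `a = 10`) and rescaling so white matter has mean diffusivity
  `dwhite` and gray matter `0.1 dwhite`.
* **Wave parameters.** Tumors are characterized by the infiltration length
  `lambda = sqrt(d / rho)` (mm) and front speed `v = 2 sqrt(d rho)`
  (mm/year); `derive_rates()` maps them to `dwhite = lambda v / 2` and
  `rho = v / (2 lambda)`.
* **Synthetic data.** Brain phantoms with fiber-like white-matter tensors,
  uniform parameter sampling (`lambda` in [0.5, 2] mm, `v` in
  [28.28, 48.99] mm/year, imaging intervals 90–180 d), threshold imaging at
  `c1 = 0.80` / `c2 = 0.16`, subject-wise train/test splits.
* **Inverse estimation.** A brute-force grid-search oracle and small
  convolutional networks (a U-Net density reconstructor and an encoder
  regressor for `(lambda, v)`), with their own Rcpp convolution engine and
  Adam training loop.
* **Evaluation and forecasting.** Masked MAE, Hausdorff and average
  symmetric surface distances, Lin's concordance, density post-processing,
  forecasting 90/180 days ahead, and a ±10% threshold sensitivity harness.

NIfTI volumes are read and written via `RNifti`.

## Worked example

Grow a synthetic tumor on a phantom brain and recover its parameters from
the three imaging contours alone:

```r
library(gliogrow)

ph   <- generate_brain_phantom(c(48, 48, 1), spacing = 2,
                               style = "folded", seed = 106)
unit <- build_tumor_tensor(ph$water, ph$map)   # trace-3 unit tumor tensor

rec <- synthesize_tumor(ph$map, unit, seed = 1007,
                        config = simulation_config(dt = 2))
rec$parameters
#> Growth parameters: lambda = 1.548 mm, v = 34.95 mm/yr (d = 27.05 mm^2/yr, rho = 11.29 /yr)
#>   imaging times t1-t4: 94, 264, 354, 444 d

est <- gridsearch_estimate(
  threshold_region(rec$snapshots[[2]], 0.80),   # core at t2
  threshold_region(rec$snapshots[[2]], 0.16),   # edema at t2
  threshold_region(rec$snapshots[[1]], 0.16),   # edema at t1
  t1 = rec$times[["t1"]], dt2 = rec$times[["t2"]] - rec$times[["t1"]],
  brain = ph$map, unit_tensor = unit, seed_center = rec$seed_center,
  lambda_grid = seq(0.5, 2.0, length.out = 12),
  v_grid = seq(28.28, 48.99, length.out = 12),
  config = simulation_config(dt = 2))
est
#> Glioma growth estimate (gridsearch):
#>   lambda = 1.591 mm, v = 35.81 mm/yr
#>   dwhite = 28.49 mm^2/yr, rho = 11.25 /yr
```

The estimate lands within one candidate cell of the truth (under 3% error
on both wave parameters here). `predict(est, rec$snapshots[[2]], unit,
ph$map, config = simulation_config(dt = 2))` then forecasts the density 90
and 180 days ahead, and `evaluate_forecast()` scores the forecasts with the
masked MAE and surface distances at both imaging thresholds.

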