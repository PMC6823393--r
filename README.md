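# minwave

Quantitative analysis of self-organized Min-protein dynamics in cell-free
systems.

The MinC/MinD/MinE proteins of *E. coli* position the division site by
oscillating between the cell poles. Reconstituted in vitro — on supported
lipid bilayers (SLBs) or inside liposomes, with the proteins either
purified or synthesized by a cell-free expression system — they form
traveling and standing surface waves, and pulsing, pole-to-pole or
circling oscillations that can visibly deform the vesicle membrane.
`minwave` is for researchers running such experiments: it turns
fluorescence time-lapse movies and LC-MS quantification tables into the
numbers these studies report.

## What it computes

**Liposome pipeline** — seeded-watershed segmentation and tracking of a
vesicle cross-section through the membrane-dye channel (white top-hat
background correction, rotated elongated Laplacian-of-Gaussian ridge
filters, marker-controlled watershed, temporal seed propagation by
size-dependent erosion), perimeter kymographs resampled to the longest
circumference, membrane vs. lumen reporter traces, moment-ellipse
elongation and normalized perimeter π·√(4A/π), the phase lag between
elongation and lumen signal, and oscillation-mode classification from the
per-position phase of the dominant temporal frequency.

**Wave metrics** — standing-wave period as the median over pixels of the
first prominent peak of the temporal autocorrelation; traveling-wave
wavelength and velocity from line kymographs by Sobel edge detection and
a linear Hough transform (stripe slope → velocity, stripe spacing →
wavelength), with an optional 8-px Gaussian preblur to suppress
small-scale cytoskeletal texture.

**Expression kinetics** — the sigmoid model
`y(t) = k' + k·tⁿ/(tⁿ + Kⁿ)` fitted by bounded Levenberg–Marquardt, with
the expression lifespan `T_plateau = 2K/n + K` and apparent translation
rate `v = k·n/(4K)`; variance-weighted calibration curves
(`wᵢ = 1/σᵢ²`) for targeted LC-MS quantification with internal-standard
normalization and the most-C-terminal-peptide rule for protein
concentration.

**Synthetic data** — `render_liposome_movie()`, `render_slb_movie()` and
`simulate_kinetics()` generate ground-truth-annotated movies (pulsing /
pole-to-pole / circling scenes with optional area-preserving elongation;
traveling / standing plane waves with PSF blur and mixed Poisson/Gaussian
noise) and noisy kinetic time courses, so every estimator in the package
is validated by parameter recovery.

## Worked example

```r
library(minwave)

## 1. a synthetic pulsing liposome, analyzed end to end
scene <- render_liposome_movie(liposome_scene_spec(
  mode = "pulsing", period = 50, n_frames = 75L, gaussian_sd = 5, seed = 12L))
seed0 <- EBImage::erode(scene$truth$masks[, , 1] * 1, matrix(1, 17, 17)) > 0
cfg <- pipeline_config(pixel_size = 0.13, frame_interval = 2)
res <- run_pipeline(scene$stack, seed0, cfg)

res$mode$label
#> [1] "pulsing"
res$mode$period_s
#> [1] 50
cor(res$traces$membrane_mean, res$traces$lumen_mean)
#> [1] -0.999986
head(res$shape[, c("time_s", "area_um2", "elongation", "norm_perimeter_um")], 3)
#>   time_s area_um2 elongation norm_perimeter_um
#> 1      0  31.8396          1          20.00271
#> 2      2  31.8396          1          20.00271
#> 3      4  31.8396          1          20.00271
```

The classifier recovers the generating mode and its 50-s period; the
membrane and lumen traces are anticorrelated because reporter leaving the
membrane accumulates in the lumen; the shape series shows a non-deforming
vesicle of 31.8 µm² cross-section (equal-area-circle circumference
20.0 µm).

```r
## 2. wavelength and velocity of a traveling surface wave
mov <- render_slb_movie(slb_wave_spec(
  image_size = c(256L, 256L), pixel_size = 1, frame_interval = 2,
  n_frames = 150L, kind = "traveling", wavelength = 43, velocity = 0.49,
  amplitude = 100, baseline = 50, gaussian_sd = 20, seed = 7L))
kymo <- line_kymograph(mov, c(128, 1), c(128, 256))
est <- estimate_traveling_wave(kymo)
unlist(est[c("wavelength_um", "velocity_um_s", "period_s", "n_lines")])
#> wavelength_um velocity_um_s      period_s       n_lines
#>    43.3066810     0.4877449    88.7896180     5.0000000
```

Five crest lines are detected in the kymograph; the generating 43 µm /
0.49 µm s⁻¹ wave is recovered to within ~1%.

```r
## 3. expression kinetics: fit and derived quantities
truth <- kinetic_model(k_prime = 0, k = 19, K = 120, n = 3)
sim <- simulate_kinetics(truth, c(0, 20, 40, 60, 120, 180, 300),
                         noise_sd = 1, n_replicates = 3, seed = 11L)
fit <- fit_sigmoid(sim$time_min, sim$conc_uM)
fit$model
#> kinetic_model: k' = -0.471 uM, k = 19.66 uM, K = 122.7 min, n = 2.824
#>   T_plateau = 209.6 min, v_translation = 0.1132 uM/min
```

A single noisy 7-time-point, 3-replicate course recovers the 19 µM yield
within ~3%; lifespan and rate estimates from single courses scatter more,
which is why recovery studies summarize medians over many simulations.

## Layout

- `R/` — synthetic-data generators, segmentation/tracking, kymographs and
  traces, wave metrics, kinetics/calibration, pipeline orchestration
- `src/` — marker-controlled watershed (Rcpp)
- `tests/testthat/` — unit, property and recovery tests with brute-force
  oracles
- `vignettes/minwave-methods.Rmd` — models, assumptions, parameter
  choices and limitations
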