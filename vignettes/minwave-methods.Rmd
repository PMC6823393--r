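---
title: "Quantifying Min-protein waves, liposome oscillations and cell-free expression kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Min-protein waves, liposome oscillations and cell-free expression kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minwave)
```

## The system and the measurements

The MinC/MinD/MinE proteins of *E. coli* position the division site by
oscillating between the cell poles. Reconstituted in cell-free systems,
MinD and MinE self-organize on supported lipid bilayers (SLBs) into planar
traveling waves, rotating spirals and standing waves, and inside liposomes
into pulsing, pole-to-pole or circling oscillations of the membrane-bound
fraction, which can visibly deform the vesicle. When the proteins are
produced by in vitro transcription–translation (the PURE system), the same
phenomenology appears, and three kinds of quantities characterize it:

1. **Wave metrics** on SLBs — wavelength and velocity of traveling waves,
   oscillation period of standing waves.
2. **Per-liposome dynamics** — segmentation and tracking of the vesicle
   cross-section, perimeter kymographs, membrane vs. lumen reporter
   traces, oscillation-mode classification, and shape metrics (elongation,
   normalized perimeter) with their phase relation to the protein cycle.
3. **Expression kinetics** — a phenomenological sigmoid fitted to
   concentration time courses quantified by targeted LC-MS against
   variance-weighted calibration curves.

`minwave` implements all three, plus a synthetic-data generator that
renders ground-truth-annotated movies and time courses so every estimator
can be validated end to end without microscope data.

## Synthetic scenes: what they emulate and what they do not

`render_liposome_movie()` renders a single equatorial liposome
cross-section: channel 1 carries a membrane-dye ring with a radial
Gaussian profile (SD = half the nominal ring width, a PSF-like,
differentiable choice), channel 2 a reporter partitioned between that ring
and the uniform lumen. The membrane-bound fraction follows the oscillation
mode: spatially uniform and sinusoidal for *pulsing*; two smoothly
antiphase polar domains (angular weight $1 + \cos(\omega t)\cos\varphi$)
for *pole-to-pole*; a rotating hotspot ($1 + \cos(\varphi - \omega t)$)
advancing one full turn per period for *circling*. Shape coupling uses an
area-preserving ellipse with semi-axes $r\sqrt{e}$ and $r/\sqrt{e}$ whose
axis ratio $e(t)$ oscillates with the scene period, shifted by a
configurable lag — matching the observation that vesicles elongate at
nearly constant cross-section. In noiseless scenes the total reporter
signal is conserved exactly across frames, which the tests verify to
$10^{-9}$ relative.

`render_slb_movie()` renders plane waves,
$I = b + a\,[1 + \cos(2\pi(u - vt)/\lambda)]/2$ along a propagation
direction $u$, or standing waves with a separable spatial × temporal
cosine. An optional *speckle* component — a Gaussian-correlated texture
drawn once per movie and added to every frame — emulates a stable
cytoskeletal network coexisting with the wave, the situation encountered
when FtsZ filaments cover the bilayer. Both generators apply Gaussian PSF
blur, then optional Poisson shot noise, then Gaussian read noise, all from
a single per-call generator seeded by `seed`; identical specs and seeds
give bit-identical stacks.

Scene defaults follow the reported experiments: 0.13 µm/px and 2 s/frame
at the liposome scale, vesicle radius 3.2 µm (glass-bead-swelling
preparations center near 4 µm diameter), oscillation periods of tens of
seconds, and SLB fields at 1 µm/px. Where the studies report no value —
reporter partition amplitudes, ring width, noise levels — the defaults are
plausible for spinning-disk imaging of eGFP at this magnification, and are
stated parameters, not claims about any dataset. Throughout, signal-to-noise
is quantified as peak-to-peak signal amplitude divided by the Gaussian
read-noise SD. The generator renders 2-D cross-sections only (no 3-D
vesicle, no photobleaching, no mechanistic reaction–diffusion model), so
passing tests demonstrate correctness of the *measurement* chain, not
realism of Min biochemistry.

## Segmentation and tracking

Per frame, the membrane-dye channel passes through three stages:

* **White top-hat** (`background_correct()`): the grayscale opening with a
  4-px disk is subtracted. The membrane ring is thinner than the disk, so
  it survives, while smooth background and broad structures are removed
  and the result is guaranteed non-negative. "Opening-based background
  correction" could also be read as *replacing* the image by its opening;
  that reading would erase the thin ring — the feature segmentation needs —
  so the top-hat reading is used. Grayscale morphology is computed
  in-package as a running min/max over disk offsets with out-of-bounds
  neighbors ignored, so the opening never exceeds the image at borders.
* **Ridge enhancement** (`membrane_enhance()`): a bank of rotated
  elongated Laplacian-of-Gaussian kernels (nominal support 10 px, realized
  as 11×11 so kernels center on a pixel; SDs 3 px along and 0.1 px across
  the axis), sign-flipped so bright ridges score positive and
  mean-subtracted so flat regions score zero; the per-pixel maximum over
  12 orientations (15° steps, worst-case angular mismatch 7.5°, small
  against the 3-px axial SD) is the response.
* **Seeded watershed** (`watershed_segment()`): Meyer's marker-controlled
  flooding (implemented in C++; ties broken FIFO for determinism) with two
  markers — the seed and the image border — on the ridge response, so the
  membrane is the high barrier and the two fronts meet on the ring crest.
  The seed's basin is hole-filled and reduced to the component containing
  the seed; a basin touching the border is a flagged failure.

Tracking (`track_liposome()`) uses a user seed on frame 1 and, for every
later frame, the previous mask eroded by a disk of radius
$\max(1, \mathrm{round}(0.15\,D_{eq}))$ with $D_{eq} = 2\sqrt{A/\pi}$ —
scale-free in vesicle size — falling back to a 3×3 square at the centroid
if erosion empties the mask, so the propagated seed is never empty.
Tracking is declared lost when consecutive masks stop overlapping. On
synthetic fixtures this chain reaches IoU ≥ 0.9 against ground truth
(≥ 0.85 while deforming at axis ratio 1.2) with area drift below 5%.

## Kymographs, traces and shape metrics

Reporter frames are smoothed with a normalized Gaussian (nominal support
10 px → 11×11, SD 1.2 px). The perimeter path is a closed clockwise
Moore-neighbor trace starting at the topmost-then-leftmost boundary pixel
— this start anchor fixes the kymograph column origin, and the sign
convention for circling direction follows from it. Because the
circumference changes as the vesicle deforms, each kymograph row is
linearly resampled to the longest circumference in the movie; linear
interpolation is range-bounded, so no overshoot is introduced.

Membrane and lumen traces use regions that published trace figures
typically leave undefined:
the membrane is the band within 3 px inside the mask boundary (about the
ring width at this magnification), the lumen is the mask eroded by
`band_width + 2` px, leaving a buffer ring between the two; both are
configurable. Elongation is the axis ratio of the moment-equivalent
ellipse, computed from the pixel-coordinate covariance with a +1/12 px²
diagonal correction for finite pixel area (which also keeps the minor
eigenvalue positive for 1-px-thick masks). The normalized perimeter is
$\pi\sqrt{4A/\pi}$, the circumference of the equal-area circle — a lower
bound on the true perimeter by the isoperimetric inequality. The phase
lag between elongation and lumen signal is the shift maximizing their
circular cross-correlation; positive values mean elongation leads, and
the result is only defined modulo the oscillation period.

## Wave metrics

**Standing waves.** Every pixel's mean-subtracted temporal
autocorrelation is computed by FFT with the *unbiased* normalization
(dividing lag $\ell$ by $n - \ell$): the biased estimator's triangular
taper pulls every first peak systematically toward smaller lags. Peaks
are searched up to lag $n/2$. The reported period is the median over
pixels of the first local maximum whose prominence — height above the
lowest earlier autocorrelation value — reaches `min_prominence`; an even
count takes the midpoint. The default prominence is 0.3: a pure-noise
pixel's autocorrelation fluctuates with SD ≈ $1/\sqrt{n}$ and its
running-min prominence reaches ≈ 0.25 for typical movie lengths, so 0.1
would admit noise pixels whose small first-peak lags drag the median
down, while 0.3 rejects them yet keeps any pixel whose oscillation
carries ≥ ~15% of its temporal variance.

**Traveling waves.** A line kymograph (1-px bilinear sampling along a
user-chosen segment in the propagation direction) shows crests as
parallel stripes whose slope is the velocity and whose spacing is the
wavelength. The estimator follows the Sobel + linear-Hough scheme with
several internals chosen deliberately:

* the kymograph is pre-smoothed (Gaussian SD 2 px) before Sobel, since at
  SNR 5 raw pixel noise otherwise dominates the gradient;
* the Otsu-thresholded gradient magnitude is thinned to per-row local
  maxima along space, keeping rising crossings only — un-thinned edge maps
  are thick bands containing both rising and falling crossings, which
  would halve the measured spacing;
* the stripe angle is *seeded from the kymograph's 2-D power spectrum*: a
  plane wave is a single $(\omega, k_x)$ peak whose ratio gives the
  stripe slope, a static texture lives in the $\omega = 0$ row (dropped
  when `exclude_stationary = TRUE`), and uniform flicker in the
  $k_x = 0$ column. The ±half-bin spectral quantization is propagated
  into the angle window that the Hough refinement may search;
* within that window the angle is refined by maximizing the sharpness
  (sum of squares) of the Gaussian-smoothed 1-px edge projection, on a
  0.5° grid and then two zoom levels down to 0.005° — for steep stripes a
  residual error of a few hundredths of a degree still drifts the
  projection across several bins over the height of the kymograph, and
  any angle error is amplified by $1/\cos\theta$ in the spacing
  conversion;
* the projection-smoothing SD adapts to the expected stripe spacing from
  the spectral seed (capped at `rho_sep` = 3 px, floored at 0.8 px), so
  jittered edges of one stripe aggregate without merging closely spaced
  stripes; lines are local maxima of the smoothed projection with ≥ 50%
  of the strongest line's mass, non-maximum suppressed at 3 px, and pairs
  far closer than the median spacing are vote-weight merged.

Velocity is the median $|dx/dt|$ over accepted lines times
pixel size / frame interval; wavelength is the median difference of the
lines' mid-row crossing positions times pixel size — the spacing along
the space axis at fixed time. On noiseless synthetic kymographs the
estimate is exact to within the 1-px ρ resolution; across a
λ ∈ {20, 40, 80} µm × v ∈ {0.25, 0.5, 1.0} µm/s grid at SNR 5 both
quantities recover within 10%.

**Mode classification.** The perimeter kymograph's columns share a
dominant temporal frequency (the largest non-DC spectral peak, required
to carry ≥ 20% of non-DC power, else *undetermined*). The per-column
phase profile then separates the modes: circular SD < 30° → *pulsing*;
strong doubled-angle concentration ($|E e^{2i\varphi}| > 0.7$) with weak
first-order concentration → *pole-to-pole* (two antiphase poles);
unwrapped phase advancing monotonically through 2π around the perimeter
(Spearman |ρ| > 0.9) → *circling*, with the rotation sign referred to the
clockwise path convention. On synthetic fixtures classification is exact
without noise (30/30) and ≥ 90% at SNR 5.

## Expression kinetics and LC-MS calibration

Protein accumulation is modeled by the phenomenological sigmoid
$$y(t) = k' + k\,\frac{t^n}{t^n + K^n},$$
with baseline $k'$, final yield $k$ (µM), half-rise time $K$ (min) and
steepness $n$. Two derived quantities summarize a fit: the expression
lifespan $T_{\mathrm{plateau}} = 2K/n + K$ — the time where the tangent
at the half-rise point reaches the plateau — and the apparent translation
rate $v = kn/(4K)$, the slope at $t = K$. These satisfy the tangent
identity $K + (k/2)/v = T_{\mathrm{plateau}}$ exactly, which the test
suite checks for 1000 random models alongside a finite-difference check
of $v$.

`fit_sigmoid()` uses Levenberg–Marquardt with box constraints
($n \in [1, 20]$, $K > 0$, $k \ge 0$), data-driven starts (baseline =
min, amplitude = range, $K$ = time of half rise, $n = 4$) and five
deterministic restarts jittering $(K, n)$ by factors of 2 — the
log-likelihood is flat in $n$, and restarts guard against terraces. Fits
are unweighted by default, with optional per-point SD weighting for
designs where replicate uncertainties are available. A fit whose steepness ends on a box
constraint is flagged (`boundary`); such solutions are not interior
optima and their derived quantities are unreliable — at low
signal-to-noise (yield ≈ 5 µM against 1 µM noise) roughly one fit in
eight pins $n$ at its upper bound, collapsing $T_{\mathrm{plateau}}$
toward $K$, so recovery summaries exclude flagged fits.

Calibration curves for targeted LC-MS quantification are weighted linear
least squares with instrumental variance weighting $w_i = 1/\sigma_i^2$
per concentration level ($\sigma_i$ = replicate SD; non-positive SDs are
replaced by the smallest positive one and flagged). With equal SDs the
fit reduces to ordinary least squares to within $10^{-10}$.
Quantification inverts the curve after optional normalization by a
constitutive internal-standard peptide ratio and dilution correction,
flagging extrapolation beyond the calibrated range. Protein concentration
is reported from the most C-terminal quantified peptide — only ribosomes
that completed translation produce it — with a warning when peptide
coverage stops well short of the C-terminus, in which case the value may
overestimate the full-length concentration.

## Validation design and problem sizes

All quantitative claims in the test suite are parameter-recovery
experiments: the generator is run with ground truth set to the values
measured for the cell-free Min/FtsZ system, and each estimator must
return its generating value within that measurement's reported spread.
The suite uses 256×256 px × 150-frame movies for the traveling-wave case,
128×128 × 200 frames for the standing wave, 48-px-tall strips wide enough
for ≥ 3 wavelengths for the cytoskeletal-pattern cases, 96×96 × 75-frame
liposome scenes, and 100 simulated time courses per kinetic design (7
time points × 3 replicates, 1 µM noise) — sizes at which every estimate
is stable while the whole suite runs in a few minutes. Low-level image
operations (morphology, convolution, erosion, interpolation, moments) are
checked pixelwise against brute-force double-loop oracles on ≤ 64×64
fixtures.

## Known limitations

* Single-liposome tracking only; no multi-instance segmentation, no
  sub-pixel contour refinement, no 3-D geometry.
* The traveling-wave estimator assumes one dominant plane-wave family per
  kymograph; spirals, colliding wavefronts or drifting wavelengths
  violate that assumption and at best raise the non-parallel-lines flag.
* The phase-lag and classification routines need at least ~3 oscillation
  periods of data and a reasonably stationary rhythm.
* The kinetic model is phenomenological: its parameters summarize curve
  shape and carry no mechanistic meaning beyond yield, half-rise time,
  lifespan and apparent rate.
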