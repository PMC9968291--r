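---
title: "cytorelease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytorelease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytorelease)
```

This vignette documents the scientific models behind `cytorelease`, the
assumptions they make, the tunable parameters that matter, and the design
choices taken where the problem was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## 1. The measurement model

### Two-plane acquisition and lipoplex exclusion

Cytosolic siRNA is measured in the lower of two confocal z-planes spaced
4 µm apart. Intact lipoplexes — siRNA/lipid particles orders of magnitude
brighter than dispersed cytosolic siRNA — contaminate the lower plane both
in focus and as out-of-focus haze from particles near the upper plane.
`mask_lipoplexes()` therefore thresholds **both** planes, takes the union
footprint and dilates it by `margin_px` (default 3) before excluding it
from all measurements. The particle threshold defaults to the 99.9th
percentile of the first-frame siRNA channel; both values are configuration
parameters because the original choices were empirical.

All quantities are **median** pixel intensities within segmentation masks,
which suppresses any residual bright puncta, and are background-corrected
by subtracting the per-frame median of object-free pixels. Two masks are
used deliberately: the full cell mask (larger area, better signal-to-noise)
for event *detection*, and the cytosol mask with the nucleus removed
(insensitive to the nucleus' exact z-position) for *quantification*.
Reporter (d1-eGFP) expression is measured in the nucleus mask, because cell
boundaries become hard to segment from the eGFP channel precisely when
knockdown succeeds.

### Segmentation and tracking

No segmentation algorithm is prescribed by the measurement model, so the
package uses the most standard, testable choice: Otsu thresholding of the
denoised nuclear channel, connected components as nuclei, and cells grown
from nucleus seeds into the Otsu foreground of the eGFP channel by seeded
region growing. Tracking is greedy nearest-centroid linking with a maximum
per-frame displacement of twice the median nucleus radius. Denoising
(Gaussian, `denoise_sigma`) is applied **only** to segmentation channels —
measurements always read raw pixels. These primitives are implemented
in-package (`otsu_threshold`, `label_components`, `gaussian_blur`,
`dilate_mask`) because no image-processing library is available in the
supported dependency set; they are exact re-implementations of textbook
algorithms, not approximations.

Pixel indices and frame numbers are 1-based throughout, following R
convention. Image I/O is by in-memory arrays with CSV/JSON serialization;
TIFF reading/writing is out of scope for this build because no TIFF codec
is available as a dependency and hand-rolling one would be poor
engineering.

## 2. Calibration: intensity to nM to molecules

A reference sample of 1 µM labelled siRNA in cytosol-mimicking buffer is
imaged as a z-stack through the fluid column. `build_reference()` selects
the contiguous interval of planes whose mean intensity is at least half the
maximum plane mean (the FWHM interval), mean-projects over it, averages
replicates, and subtracts a blank stack processed identically. The result
keeps the full vignetting pattern of the optics: dividing a measured
intensity by the reference value *at the cell centroid*
(`to_concentration()`) corrects vignetting and converts to absolute
concentration in a single step,

$$C = \frac{I_{\text{corrected}}}{I_{\text{ref}}(x, y)} \times 1000\ \mathrm{nM}.$$

The reference is used raw per pixel (an optional Gaussian smoothing flag
exists); whether the original analysis smoothed it is unknown, and raw
keeps the contract exact. Molecule counts are
$N = C \cdot V \cdot N_A$ with $V$ in litres; the default volume is the
typical HeLa cytosol of 5000 fL, so 1 nM ≈ 3011 molecules. Counts are
conventionally reported at 2 significant figures (`round_2sf = TRUE`).

Two caveats are inherited from the measurement concept: the concentration
is an *apparent* concentration over the whole cytoplasmic space (including
organelle volume), and linearity of the detector is assumed — both hold by
construction for the synthetic data and are documented limitations for
real data.

## 3. Event detection

The detector operates on the median-filtered (5-frame moving median,
shrinking windows at the edges) cell-mask trace. Frame $t$ is called a
release event when the filtered values at $t, \dots, t+5$ are **all**
strictly greater than

$$\max\big(\mu_3 + 3\,\sigma_{10},\ \mu_3 + \delta\big),$$

where $\mu_3$ and $\sigma_{10}$ are the mean and SD of the 3 and 10 frames
immediately preceding $t$ (the shift frame itself excluded — the rule's
wording implies but does not state this; exclusion is adopted), and
$\delta$ is a fixed offset guarding the zero-noise regime. The original
offset value was tuned visually and never published; the default here is
0.15 nM-equivalents, chosen once on synthetic data with the default noise
level and not revisited. After a call, scanning resumes past the
persistence window, so multiple events per cell are supported. The SD uses
the sample (n−1) estimator.

Detection performance is scored per cell against independent ground truth
(synthetic injection times, or membrane-damage-reporter annotations for
real data): a call within ±5 frames of the first true event is a true
positive; manual-QC-rejected calls are removed before scoring, so a
rejected false positive becomes a true negative. Each cell is evaluated
only up to its first event.

## 4. Release-magnitude models

Post-event concentration traces decay approximately exponentially as the
dispersed siRNA redistributes. `fit_release()` fits three nested models
over the frames $t_0 - 3, \dots, t_0 + 14$ (a 15-frame, 75-min window plus
three pre-event frames):

* **exp** — $C(t) = B + A_1 e^{-k (t - t_0)}$ for $t \ge t_0$, $C = B$
  before;
* **step** — the same with $k = 0$, for low-magnitude events where noise
  hides the decay;
* **double** — two events with a shared decay constant, at most 14 frames
  apart, reported as a single release of magnitude $A_1 + A_2$.

Design choices, since the original model's exact parameterization is not
available: the baseline $B$ is a constant fitted jointly, and three
pre-event frames are included in the window — without them the step model
is structurally unidentifiable ($B$ and $A_1$ enter only as a sum). The
event time is refined over ±2 frames around the detection frame because
automated detection can lag the visible release by a few frames. For fixed
event times and decay, all models are linear in $(B, A_1, A_2)$, so
fitting reduces to profiled linear least squares over $k$; the profile is
scanned on a coarse log grid before local refinement because the
amplitude-positivity constraint can split the $k$ axis into disjoint
feasible regions. Model selection is by small-sample-corrected AICc
(counting the discrete event times as parameters); on noiseless data the
RSS is floored at $10^{-7}$ of the TSS so exact fits tie and the smaller
model wins.

Each fit reports $R^2$ over the window — the per-event confidence measure
used downstream at thresholds 0.3 (exclude unreliable) and 0.75 (keep only
high-confidence) — and an uncertainty budget

$$\mathrm{rel\_sd} = \sqrt{\frac{\mathrm{se}(A)^2}{A^2}
  + \epsilon_{\text{calib}}^2 + \epsilon_{\text{bleach}}^2},$$

with defaults $\epsilon_{\text{calib}} = 0.08$ and
$\epsilon_{\text{bleach}} = 0.05$, chosen so the systematic floor at large
magnitudes is $\sqrt{0.08^2 + 0.05^2} \approx 9.4\%$, i.e. the ~10%
systematic-error regime; `se(A)` is the linear-fit standard error
conditional on the profiled decay and event times (a slight
underestimate, absorbed by the systematic terms).

## 5. Knockdown analysis

### Correction and alignment

Reporter traces of event cells are divided by the mean trajectory of
same-well control cells (no detected event, each normalized to its own
first frame), which removes photobleaching, drift and slow well-level
confounders in one operator — the division-by-control-mean form is this
package's choice; the data source (control cells in the same well) is part
of the method. Traces are then shifted so the first event is $t = 0$ and
normalized to the value there, so every corrected trace equals 1 at
$t = 0$ by construction. Masks: everything after a second detected event
(its knockdown would confound the first event's dose-response), 20 frames
before an annotated death, cells entering the field after frame 3 (they
may carry an undetected prior release), and cells starting below a
configurable low-expression threshold. A multiplicative mitosis-correction
hook (factor curve estimated from control-siRNA experiments) is provided;
its exact functional form in the original analysis is unknown.

### Dose-response

Cells passing the $R^2$ filter are ranked by model-based peak
concentration and split into equal quintiles; group curves are means with
t-based 80% pointwise bands (80% for curves, 95% for IC50s, both
configurable, matching common reporting style). Two complementary IC50
estimators are provided:

* `fit_4pl()` / `ic50_timecourse()` — per-timepoint four-parameter
  logistic on $\log_{10}$ dose with top fixed at 1, bottom in $[0, 1]$,
  optional shared hillslope across curves. The *relative* IC50 is the
  midpoint parameter; the *absolute* IC50 is the dose where the fitted
  curve crosses 0.5, absent when it never does. Note that for a decreasing
  curve with bottom > 0 the absolute IC50 lies at a **higher** dose than
  the relative IC50 (the midpoint response is above 0.5); both are
  reported. CIs are percentile bootstrap over cells.
* `fit_kinetic_model()` — an ODE fitted to all timepoints jointly.

### The kinetic model

With $s(t)$ the cytosolic siRNA concentration decaying first-order at
$\lambda_s$, and mRNA/protein written relative to their untreated steady
states ($M = m/m^*$, $P = p/p^*$), transcription and translation rates
cancel and the dynamics reduce to

$$M' = \delta_m (1 - M) - M \, \frac{v_{\max} s^n}{s^n + K^n},
\qquad P' = \delta_p (M - P).$$

Dose 0 keeps $M = P = 1$ exactly, and nadir depth and knockdown duration
are monotone in dose. $\delta_p = \ln 2 / 0.8\,\mathrm{h}^{-1}$ is fixed
by the ~48-min half-life of the destabilized d1-eGFP reporter.
`fit_kinetic_model()` estimates $(\delta_m, v_{\max}, K)$ on the log scale
by least squares against the quintile mean curves, holding $n$ (default 1)
and $\lambda_s$ (default 0.05 h⁻¹) fixed: with only relative-expression
data the 5-parameter family is weakly identifiable, and the shape
exponents and siRNA loss rate are better supplied from separate evidence.
The model-implied absolute IC50 at $t^\*$ (default 10 h, near the nadir)
is found by monotone interpolation over a log-dose grid; CIs come from
bootstrap resampling of cells within groups (default 200 replicates,
seeded), preserving within-cell correlation. Integration is a fixed-step
vectorized RK4 (default 0.2 h; against a 0.01 h reference the error is
~1e-3 in relative expression, far below measurement noise).

This ODE is a reconstruction: the original model's description is not
available, and this is the minimal Hill-type form consistent with
dose-dependent nadir depth, timing and duration. Its contracts (dose-0
identity, monotonicity, IC50 semantics) are what the package tests.

## 6. The synthetic world

The generators emulate the stated acquisition phenomenology, with defaults
fixed once:

* **Traces** (`gen_trace_ensemble`): releases are instantaneous cytosolic
  steps (dispersion takes ~20 s versus the 5-min frame interval) decaying
  at 0.05/frame, with additive Gaussian frame noise of 0.15 nM-equivalents,
  magnitudes log-uniform on [1, 40] nM (spanning the observed greater than
  order-of-magnitude spread; the true distribution family is unreported,
  so log-uniform is an explicit stand-in), Poisson event counts, and
  optional multiplicative exponential bleaching shared by all cells in a
  well (which is what makes control-cell correction work).
* **Scenes** (`gen_image_sequence`): disk cells (12 µm radius, 5.5 µm
  nucleus — with realistic column heights this yields a cytosol volume in
  the 3800–5900 fL interquartile band around the typical 5000 fL), bright
  lipoplex puncta assigned to either z-plane and rendered with a wider
  Gaussian in the other (flux-preserving), a radial quadratic vignette
  field (corner/centre ratio 0.8), and optional Poisson-Gaussian detector
  noise. The detector-noise family is not stated anywhere authoritative;
  Poisson+Gaussian is the standard camera model and is switched off for
  oracle tests.
* **Reference stacks** (`gen_reference_stack`): the synthetic fluid column
  has a plateau axial profile with sub-half-maximum tails, so its FWHM
  projection equals the plateau exactly and the calibration round-trip is
  exact on noiseless renders. (A Gaussian axial profile would attenuate
  the projection by its above-half-max mean — a real effect that would
  equally attenuate in-cell measurements, and which the simulator does not
  model; the plateau keeps reference and scene consistent.) A Gaussian
  profile option exists to exercise the FWHM selection logic.
* **Knockdown cohorts** (`gen_knockdown_dataset`): ODE solutions per dose
  times lognormal cell noise (SD 0.1 on the log scale). The default
  kinetic parameters ($v_{\max} = 1.5$, $K = 1$ nM) place the 10-h
  absolute IC50 near 0.3 nM, the sub-nanomolar scale measured for a potent
  sequence.

What a green test establishes — and what it does not: the synthetic world
has exactly the stated noise structure, no segmentation ambiguity beyond
what the renderer produces, no cell motility, no mitosis-driven intensity
fluctuations, and no model misspecification in the knockdown stage (cells
are generated from the same ODE family that is fitted). Green tests
therefore establish correctness of the *algorithms and their
implementations*, and achievable performance under idealized conditions;
they do not reproduce real-data sensitivity/specificity figures, which
depend on biology and optics outside the simulator.

## 7. Numerical choices and degenerate inputs

* Exact threshold ties in the detector do **not** trigger (the rule says
  strictly larger); a flat zero-noise trace yields no events because the
  fixed offset keeps the threshold positive when the SD collapses to 0.
* Empty traces, blank frames, all-masked cells, monotone-flat dose-response
  data and non-converged fits all return typed empty results or flagged
  rows rather than errors; genuinely invalid parameters (negative doses,
  nucleus larger than cell, zero reference pixels) raise classed errors.
* All randomness flows through explicit seeds; identical spec + seed gives
  bit-identical tables, and the pipeline manifest records the seed and a
  config hash.
* Bootstrap replicates that fail to fit are counted and reported, not
  silently dropped; intervals are returned only when at least 20
  replicates succeeded.

## 8. Known limitations

* No subpixel particle localization and no learned segmentation; crowded
  or motile cells will degrade tracking (greedy nearest-centroid).
* The decay of the post-release signal is modelled empirically
  (exponential); no mechanistic model of siRNA redistribution into foci.
* The kinetic model's $\lambda_s$ and Hill exponent are assumptions, not
  estimates; absolute IC50s from the ODE should be read together with the
  per-timepoint 4PL estimates, which are model-free in time.
* TIFF I/O is not included (no codec in the dependency set); adapters from
  array-based stacks are the integration point.
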