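---
title: "Modelling physiological coupling to the BOLD signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling physiological coupling to the BOLD signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physbold)
```

## The problem

Slow fluctuations of heart rate, breathing depth and arterial CO₂ drive
vascular responses that appear in resting-state BOLD fMRI as structured,
spatially widespread signal. Depending on the question, this component is
either a confound to be regressed out or the object of study — a window on
autonomic–cerebrovascular interaction and its change with age and with
interventions that modulate heart-rate variability. `physbold` implements the
full chain from raw physiological recordings to corrected group maps, plus a
synthetic-cohort generator that makes each stage verifiable by parameter
recovery.

## Physiological preprocessing

**Beat detection.** The PPG waveform is band-pass filtered 0.5–2 Hz with a
second-order Butterworth filter applied forward and backward (zero phase lag),
and local maxima at least 0.25 s apart with height ≥ 5% of the filtered
signal's interquartile range are taken as beats. The refractory separation of
0.25 s corresponds to 240 bpm, safely above physiological heart rates.

**Interval cleaning.** Inter-beat intervals (IBIs) outside 0.33–2.0 s or more
than 3 scaled median absolute deviations from a 15-beat running median are
replaced by linear interpolation between valid neighbours. This automates a
step that is often done by visual inspection; automation makes the pipeline
deterministic and reproducible. If more than half the intervals are flagged,
the series is marked poor-quality.

**TR-locked timecourses.** Heart rate at each volume is 60 over the median
IBI in the 6-s window centred on the acquisition time; respiratory variation
(RV) is the windowed standard deviation of the raw belt trace on the same
grid. Edge windows are clipped to the recorded data rather than padded — we
prefer a slightly noisier edge estimate to fabricating samples. RV is
normalized to approximately [-1, 1] using the 1.45th/98.55th percentile
bounds (exact order statistics with linear interpolation, R type 7, used for
every quantile in the package; a binned-histogram variant would differ
negligibly). Capnograph traces are first advanced by the delay that makes
their correlation with the respiration belt most negative (tubing introduces
a measurement lag; the two signals are physiologically anti-correlated), then
breath-wise peaks are extracted as end-tidal CO₂ and interpolated to the
volume grid. Positive shift means the capnograph lags respiration.

**HRV summaries.** RMSSD is computed directly from the IBIs (ms). LF
(0.04–0.15 Hz) and HF (0.15–0.4 Hz) band powers are integrals of a Welch
spectral estimate — cubic interpolation of the IBI series onto a uniform 4 Hz
grid, 120-s Hann segments with 50% overlap, trapezoidal band integration —
which is standard HRV practice; units are ms². Powers are reported on the
natural-log scale because their sampling distributions are strongly
right-skewed. Spectral estimation requires at least two minutes of beats;
RMSSD is returned regardless. Cohort-level outlier screening uses the
1.5 × IQR fence per metric.

## Response-function regressors

Heart rate couples into BOLD through the canonical cardiac response function
(an early gamma-shaped overshoot and a Gaussian trough near 12 s), RV through
the respiratory response function, and end-tidal CO₂ through a double-gamma
response `A₁·γ(t; n₁, τ₁) − A₂·γ(t; n₂, τ₂)`. The published CO₂
parameterization is not reproduced numerically anywhere we can cite a table
from, so the package ships editable defaults (`co2_rf_params()`: peak near
12 s, shallow undershoot) and the generic double-gamma form accepts any
published values.

Each response family contributes a small basis: the primary function, its
temporal derivative (central finite difference, 0.01-s step — chosen so the
finite-difference error is below 10⁻⁴ of the analytic derivative), and for
CRF/RRF a dispersive derivative `[rf(t/w)/w − rf(t)]/(w−1)` with `w = 1.1`,
which absorbs voxelwise differences in response latency and width. A cited
description of the cardiac basis says "temporal and spatial derivative"; a
spatial derivative of a time-domain kernel is not meaningful, so we read it
as the dispersive form, symmetric with the respiratory basis.

`build_regressors()` linearly detrends and z-scores each physiological
series, upsamples it to a 0.5-s grid (a compromise between convolution
fidelity and cost; configurable), convolves causally, samples at the volume
times and z-scores the columns. Because of the pre/post standardization the
columns are exactly invariant to affine rescaling of the raw input, so units
of the physiological series never matter downstream. Zero-variance columns
(e.g. from a constant input) are dropped with a warning. Legendre polynomials
up to order 4 model drift inside the design matrix rather than being
pre-subtracted, which keeps the variance accounting explicit.

## PVE: definition and numerical choices

Three models are fitted per voxel — joint, cardiac-only, respiratory-only —
with no orthogonalization between families, so variance shared by cardiac and
respiratory fluctuations appears in both single-family models; the joint
model bounds both from above, exactly, at every voxel.

PVE is a partial R²: both the voxel series and the physiological columns are
residualized against the drift block, and PVE = 1 − RSS/TSS of the reduced
regression. The denominator is the *drift-adjusted* voxel variance. The
alternative — raw voxel variance including drift — would let slow scanner
trends arbitrarily deflate the measure; since preprocessing conventionally
removes polynomial trends before modelling, the drift-adjusted denominator is
the faithful reading. The Frisch–Waugh identity makes the resulting
coefficients identical to those of the full joint fit. PVE is clipped to
[0, 1]; voxels with (numerically) zero variance are masked. Under pure noise
the estimator inflates to roughly k/(n − d) (k physiological columns, d drift
terms) — about 0.015 at 404 volumes — which is visible in the null
simulations and is a property of R², not a bug.

## Lagged cross-correlation

Cross-correlations use the *unconvolved* physiological series, so they make
no assumption about the response shape. At lag `L = d·Δ` the physiological
series is shifted forward by `d` samples, the overlapping segments are
linearly detrended, and Pearson r is computed on the overlap (which shrinks
with |lag|; no padding; lags with < 30 overlapping samples are NA). The
convention throughout: positive lag = physiology leads BOLD.

Voxelwise maps stay on the TR grid. Tissue-averaged curves (gray matter,
white matter, ventricles) optionally upsample both series to a 0.2-s step by
linear interpolation (the interpolant is a free choice; linear avoids
overshoot) and refine the lag grid accordingly. The default lag grids are
−2…+15 TRs at TR 1.4 s (−2.8 … 21.0 s) and −1…+9 TRs at TR 2.4 s
(−2.4 … 21.6 s). A printed endpoint of 21.4 s at TR 1.4 s is not an integer
number of TRs; the grid stops at 21.0 s, the nearest multiple, and the
discrepancy is noted here rather than silently corrected elsewhere.

## Group inference

Voxelwise group contrasts use the pooled-variance two-sample t statistic,
computed as the group-indicator coefficient in a per-voxel linear model so
that covariates (sex, average heart rate, …) can be added. Pooled rather
than Welch variance keeps the statistic exchangeable under label
permutation; for scalar cohort summaries, where no permutation is involved,
Welch is the more robust default — an intentional asymmetry.

TFCE integrates cluster extent and height over all thresholds,
`TFCE(v) = Σ_h e(h,v)^E h^H dh`, with the method's standard parameters
E = 0.5, H = 2, 26-connectivity and dh = max/100 (midpoint rule). The
implementation activates voxels in descending height order and merges
components with union-find (compiled code), which matches a brute-force
flood-fill integration to better than 1% and is fast enough to sit inside
the permutation loop. Negative statistics are enhanced on the sign-flipped
map and returned with their sign.

The permutation test shuffles group labels (group sizes preserved exactly,
asserted at run time), records the map-wise maximum of the enhanced statistic
per direction, and reports familywise-corrected
`p(v) = (1 + #{perm max ≥ obs(v)})/(n_perm + 1)` for each direction
separately. The full-fidelity setting for publication-grade maps is 5000
permutations; the package default of 500 gives a p-value granularity of
1/501, sufficient for α = 0.05 decisions at desk scale. Pre/post intervention effects are assessed
on subject-matched post − pre difference maps. Lag-wise tissue comparisons
use t tests per lag with Bonferroni correction over lags (α/n_lags),
reporting both corrected and uncorrected significance, and degenerate
all-equal comparisons count as no evidence (p = 1) rather than an error.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, not a demo. Scenario
defaults describe a plausible resting cohort: mean heart rate 70 (young) /
67 (old) bpm; sinusoidal IBI modulation at 0.1 Hz (LF) and at the breathing
frequency (HF), amplitudes 0.05 s with the old group's HF halved; breathing
16 / 14 bpm; end-tidal CO₂ ≈ 39 / 40 mmHg; capnograph delay 2 s. Coupling
defaults encode the qualitative age contrasts the analysis should recover:
old coupling gain 0.5 versus young 1.0, old latency +2 s. The magnitudes are
free modelling choices — no published generative model exists for these
data — and are deliberately conservative.

PPG pulses are raised cosines (pulse shape is irrelevant downstream beyond
peak detectability); respiration is a quasi-sinusoid with slowly varying
amplitude; the capnograph shows breath-synchronous plateaus with ~1%
height variation, constructed as a monotone decreasing function of the
respiration phase so the inverse correlation used for alignment holds by
construction. BOLD voxels are built from the *TR-locked* timecourses:
convolution with the primary response functions on a 0.1-s grid, a latency
shift applied on that fine grid before TR sampling (how a delayed vascular
response would actually appear), random per-voxel betas, Legendre drift, and
AR(1) noise (coefficient 0.3 — chosen over white noise so cross-correlation
significance behaves realistically). The signal scale at each voxel solves a
quadratic so that var(signal)/var(signal + noise) equals the requested
variance fraction *exactly on the realized series*; drift is excluded from
this accounting because PVE is defined after drift projection. Determinism
is strict: every random draw is seeded from (scenario seed, subject id,
stage, session), so identical inputs give bit-identical outputs, including
the gzipped NIfTI files.

What the generator does **not** emulate: head motion, spatial autocorrelation
of anatomy, multi-echo acquisition, neuronal resting-state networks, and
measurement nonlinearities of real belts and oximeters. Passing recovery
tests on this generator therefore demonstrates correctness of the estimators
under the stated model, not robustness to every artifact of real data.

## Problem sizes and runtime choices

The test-suite and acceptance runs use desk-scale configurations chosen to
make Monte-Carlo properties measurable in minutes on one CPU: PVE recovery
on 800 voxels at 404 volumes (the long-scan configuration); lag recovery
over 150 seeded voxels; permutation calibration over 40 replicate null
cohorts of 15 + 15 subjects on a 6×6×6 grid at 64 volumes with 500
permutations; power at coupling gains 1.0 vs 0.25 in the same geometry; and
a 6-subject end-to-end determinism run. Larger grids and 5000 permutations
change none of the logic, only the runtime.

## Known limitations

- Response functions are population-canonical; no subject- or age-specific
  estimation is attempted.
- The GLM is ordinary least squares; beta inference would require
  prewhitening, which is out of scope because group inference is
  permutation-based on summary maps.
- `iqr_screen` and the HRV summaries assume independent subjects; family or
  repeated-measure structure is the caller's responsibility.
- The capnograph alignment assumes the inverse correlation with the belt
  holds; severe belt failure (the reason end-tidal CO₂ replaces RV in one
  acquisition profile) would degrade it, and the function warns when the
  correlation never goes negative.
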