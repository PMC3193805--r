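---
title: "Brix-model DCE-MRI analysis and the virtual xenograft cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brix-model DCE-MRI analysis and the virtual xenograft cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brixflow)
```

# Scope

`brixflow` implements the full analysis chain of a preclinical
DCE-MRI treatment-monitoring study: per-voxel relative signal
enhancement, Brix two-compartment model fitting with quality-based
exclusion, caliper-based tumor-growth-delay endpoints, and the group
statistics that relate imaging biomarkers to treatment response and
tumor hypoxia. Because studies of this kind rarely deposit raw image
data, the package also contains a first-class synthetic cohort
generator that emulates the statistical structure such an experiment
produces; every downstream stage is developed and tested against it.

# The kinetic model

The measured quantity is the relative signal intensity
$RSI(t) = (SI(t) - SI(0))/SI(0)$, with $SI(0)$ the mean of the
pre-contrast baseline frames. Working in relative enhancement rather
than contrast-agent concentration avoids T1 mapping and
signal-to-concentration conversion entirely; the cost is that the
amplitude parameter is a relative, not absolute, measure of the
extracellular extravascular space (EES).

The Brix model treats plasma and the EES as two well-mixed
compartments: contrast enters the tissue at exchange rate $k_{ep}$
(min$^{-1}$), is cleared from plasma at $k_{el}$ (min$^{-1}$), and the
dimensionless amplitude $A$ scales with the size of the EES:

$$RSI(t) = \frac{A\,k_{ep}}{k_{el}-k_{ep}}
  \left(e^{-k_{ep}t} - e^{-k_{el}t}\right),$$

with the analytic limit $A\,k_{ep}\,t\,e^{-k_{ep}t}$ on the
$k_{ep}=k_{el}$ diagonal (switched at relative rate difference
$10^{-8}$; the general form a hair off the diagonal agrees with the
limit to well under $10^{-6}$ relative error, so the surface the
optimizer sees is smooth). The curve rises to a unique interior
maximum at $t^{ \ast } = \ln(k_{ep}/k_{el})/(k_{ep}-k_{el})$ and decays.

## Identifiability

The functional form is invariant under the swap
$(A, k_{ep}, k_{el}) \mapsto (A\,k_{ep}/k_{el},\, k_{el},\, k_{ep})$:
both branches produce identical curves. All fits (and the grid-search
oracle used to validate them) are therefore reported on the canonical
$k_{ep} \ge k_{el}$ branch — the physiological regime of these highly
permeable tumors, where contrast in-wash is fast relative to plasma
clearance — whenever the swapped amplitude stays inside the fitting
bounds. Without this convention, parameter-level comparisons between
independent optimizers would be ill-defined.

# Fitting

Each voxel curve is fitted by bounded Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`), minimizing the sum of squared
residuals between the measured and modeled $RSI$. Choices that matter:

* **Bounds** $A \in [0, 50]$, $k_{ep} \in [0, 30]$ min$^{-1}$,
  $k_{el} \in [0, 5]$ min$^{-1}$: generous brackets around plausible
  tissue values; the upper bounds double as saturation detectors.
* **Multi-start**: three fixed starts — $(1, 1, 0.1)$, then a
  fast-in-wash start $(0.5, 5, 0.5)$ and a slow-enhancement start
  $(2, 0.5, 0.05)$. All are always run and the lowest objective wins,
  which makes the fit a deterministic function of the curve.
* **Convergence**: objective tolerance $10^{-8}$, at most 500
  iterations per start.
* **Voxel exclusion**, with reason codes: non-positive baseline
  (normalization undefined), no converged start, $A$ or $k_{el}$
  saturated at its upper bound, or $r^2 < 0.5$ (including flat curves
  whose $r^2$ is undefined). The $r^2$ floor and the QC threshold
  below are configurable; the defaults make the qualitative exclusions
  reported in such studies operational.

## When $k_{ep}$ cannot be trusted

$k_{ep}$ is estimated from the initial rise of the curve. With a 12 s
frame interval, a voxel with $k_{ep}$ near or above ~5 min$^{-1}$
peaks within the first two or three post-contrast frames, and the
estimate destabilizes. `qc_kep()` flags a fitted map when more than a
configurable fraction (default 25%) of its voxels either sit at the
$k_{ep}$ bound or leave fewer than 3 samples before the fitted peak
time; flagged maps keep $A$ and $k_{el}$ in ROI summaries but report
$k_{ep}$ as `NA`. This mirrors the common practice of excluding
$k_{ep}$ from tumor-level comparisons in fast-enhancing xenografts.

## Time-axis correction

Contrast is injected over a nominal 3 s. When the realized injection
duration differs, the recorded post-contrast frame times are displaced
relative to the effective bolus midpoint; `correct_time_axis()` shifts
the post-contrast times by $(\text{actual}-\text{nominal})/2$
(converted to minutes), leaving baseline frames untouched. Midpoint
alignment is the least-assumption correction: it needs no bolus-shape
model, only the recorded durations.

# The virtual cohort

`cohort_design()` fixes the study conditions; the defaults encode the
emulated experiment:

* **Arms** (9 tumors each): control, PL-DXR (pegylated liposomal
  doxorubicin), PL-DXR + hypoxic RT, hypoxic RT, RT. The pre→post
  effect multipliers on $(A, k_{el})$ are (0.82, 1.45), (0.74, 1.85),
  (1.04, 1.47), (1.20, 0.73), (1.29, 0.73): amplitude falls in the two
  non-irradiated arms and rises in every irradiated arm, while
  $k_{el}$ falls in the two radiotherapy-only arms. These are
  emulation targets for the generator, not claims of reproducing any
  particular animal experiment.
* **Acquisition**: 5 baseline frames, 12 s interval, 20 min of
  post-contrast imaging (100 frames), injection at the end of the
  baseline block.
* **Parameter fields**: log-normal marginals ($A$: median 1.2,
  $\sigma_{\log} = 0.25$; $k_{ep}$: median 3 min$^{-1}$,
  $\sigma_{\log} = 0.30$; $k_{el}$: median 0.3 min$^{-1}$,
  $\sigma_{\log} = 0.20$) smoothed on the log scale with a Gaussian
  kernel ($\sigma = 2$ voxels), over an elliptical single-slice ROI of
  about 400 voxels. Log-normality guarantees positivity with
  right-skewed heterogeneity; the high $k_{ep}$ median deliberately
  puts part of the field in the under-sampled in-wash regime so the
  QC logic is exercised. The post-treatment session reuses the same
  spatial field and applies the arm's multipliers *exactly*, so the
  generator is calibrated by construction: the in-ROI mean post/pre
  ratio equals the configured multiplier, and measured between-tumor
  variability comes from the random per-tumor fields plus acquisition
  noise propagated through fitting.
* **Noise**: additive Gaussian on signal intensity, default 5% of
  baseline. Rician noise was deliberately deferred: at this SNR the
  Gaussian approximation is excellent and keeps the fitting oracle
  simple. The noise level itself is a free knob — such studies rarely
  state their dynamic-series SNR — chosen once as a realistic
  high-field small-animal value.
* **Growth law**: $V(t) = V_0\exp\{g\,t\,(1-t/(2t_{sat}))\}$ with
  $t_{sat} = 40$ d, control rate $g = 0.14$ d$^{-1}$, per-tumor
  log-rate spread 0.15, day-0 volumes log-normal around 200 mm³, 3%
  multiplicative caliper noise per diameter, aspect ratio 1.2, and
  arm modifiers 1.00 / 0.65 / 0.35 / 0.50 / 0.22. These values were
  set once so that controls reach 3-fold volume in 8–10 days, the
  strongest arm stays below 3-fold within the window (producing the
  censored, "more than"-style delay), and the day-29 ordering of mean
  relative volume is control > PL-DXR > hypoxic RT > PL-DXR+hypoxic
  RT > RT. Measurements run at 4-day intervals with a terminal
  measurement closing the 29-day window.
* **Hypoxia coupling**: hypoxic fraction
  $= 0.17 - 0.21\,\Delta A + \varepsilon$, $\varepsilon \sim
  N(0, 0.02)$, clipped to $[0,1]$, with $\Delta A$ the tumor's
  relative amplitude change as a fraction. Intercept and slope match a
  linear fit through the published group-mean pairs this structure
  emulates.

Determinism is a contract: one master seed fans out through
`derive_seed()` to every tumor, session and stage, so any generator
call is a pure function of (design, indices, seed) and full pipeline
runs are bit-reproducible.

## What the generator does *not* emulate

No pulse-sequence physics, flip-angle effects or
signal-to-concentration conversion (the analysis operates in relative
enhancement, as the emulated protocol does); no 3D multi-slice
anatomy (one central slice per tumor); no arterial input function; no
synthetic stained-section images (hypoxic fractions enter as
scalars); no animal attrition or failed injections — exclusions enter
only through the voxel-level quality rules. Passing tests on this
cohort therefore demonstrate correctness of the estimation and
statistics chain under the stated noise model, not robustness to
motion, coil inhomogeneity or segmentation error in real data.

# Growth endpoints and statistics

Volumes use the caliper formula $V = (\pi/6)\,L^2 W$ with $L \ge W$,
implemented verbatim as printed in the emulated protocol even though
the usual ellipsoid convention squares the *shorter* axis; the
conventional $W^2 L$ variant is available via a config switch. The
3-fold crossing time is found by linear interpolation on the volume
scale between the bracketing 4-day measurements — the simplest
monotone-consistent rule; trajectories that never cross within the
window are censored at the last day. Group growth delay (`tgd_v3()`)
is the difference of group *means* of crossing times, and any censored
treated tumor converts the group value into a lower bound, never a
point estimate.

Group trend comparisons use a two-stage analysis: each tumor's log
relative volume is regressed on orthogonal linear and quadratic
contrasts of day, and the per-animal trend scores are compared between
groups by Student t-tests. A single pooled regression with
group-by-trend interactions was considered and rejected: its residuals
are correlated within animal, which inflates the type-I error of the
interaction test, whereas the animal-level error term of the two-stage
form keeps it calibrated (verified by null simulation at 1000
replicates). Log transformation stabilizes the multiplicative growth
variance; orthogonal contrasts make the linear and quadratic tests
separable.

Within-group pre→post comparisons are paired on tumor identity (the
same tumors are imaged twice); between-group comparisons are unpaired
pooled-variance t-tests. Group relative change is primarily the mean
of per-tumor relative changes, with the change-of-group-means variant
exported alongside. No multiple-testing correction is applied by
default (flat 5% level, matching the emulated analysis); a Holm option
exists. Cross-endpoint correlations are plain Pearson $r$ with the
t-transform p-value, computed across group means for the five
canonical pairings (hypoxic fraction vs $\Delta A$, $\Delta k_{el}$,
$\Delta V$; $\Delta V$ vs $\Delta A$, $\Delta k_{el}$); a pairing is
skipped with a warning if any group lacks the endpoint.

# Numerical and testing choices

* The fitting oracle used in validation is a $40^3$ grid search over
  the fitting bounds (exploiting linearity in $A$ within each rate
  cell) followed by local refinement with the PORT routine `nlminb`
  from the best grid cells *and their swap-symmetric twins* — without
  the twin starts the oracle can converge onto the mirrored branch
  against a bound. Fitter and oracle agree in objective to $10^{-6}$
  and in parameters to $10^{-3}$ relative on noiseless curves.
* Degenerate inputs: flat curves have undefined $r^2$ and are
  excluded; zero-baseline voxels are flagged, not fatal; an all-voxel
  exclusion marks the map non-evaluable; empty ROIs and non-positive
  effect multipliers are errors.
* Problem sizes in the test-suite and acceptance script were chosen to
  keep full runs comfortably interactive: ~400-voxel ROIs for
  recovery checks (the realistic central-slice size), ~50-voxel ROIs
  when 50 whole cohorts are fitted for the sign-pattern check (ROI
  size only shrinks the already-negligible ROI-mean standard error),
  1000 replicates for type-I calibration, 50 curves for oracle
  agreement.

# Known limitations

Gaussian (not Rician) noise; single-slice ROIs; no arterial input
function or Tofts-family models; censored growth delays are reported
as lower bounds rather than analyzed by survival methods; the
pooled-regression formulation of the trend comparison is intentionally
not offered; and because group-level endpoint values of any real
experiment depend on unpublished per-animal data, the package's
cohort-level numbers are structural emulations, not reproductions.
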