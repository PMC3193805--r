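# brixflow

Voxel-wise pharmacokinetic analysis of dynamic contrast-enhanced MRI
(DCE-MRI) of tumor xenografts with the **Brix two-compartment model**,
together with the downstream treatment-response workflow used in
preclinical chemoradiotherapy studies: caliper-based tumor volumes and
growth delay, group-level relative-change statistics, and correlation
of imaging biomarkers with pimonidazole hypoxic fractions.

The package is aimed at preclinical imaging scientists who want the
whole chain — enhancement-curve modeling, quality-based voxel
exclusion, growth-delay endpoints and group statistics — as tested,
scriptable functions, plus a seeded synthetic cohort generator so every
stage can be exercised and validated without any acquired data.

## The model

For each tumor-ROI voxel the time-dependent relative signal intensity
is computed from the dynamic series,

    RSI(t) = (SI(t) − SI(0)) / SI(0),

with SI(0) the mean over the pre-contrast baseline frames. Each RSI
curve is then fitted with the Brix two-compartment model of contrast
exchange between blood plasma and the extracellular extravascular
space (EES),

    RSI(t) = A · k_ep / (k_el − k_ep) · (e^(−k_ep·t) − e^(−k_el·t)),

where `A` (dimensionless) is an amplitude related to the size of the
EES, `k_ep` (min⁻¹) the plasma–EES exchange rate constant, and `k_el`
(min⁻¹) the elimination rate of the agent from plasma. Fitting is
bounded Levenberg–Marquardt least squares with fixed multi-starts.
The curve peaks at `t* = ln(k_ep/k_el)/(k_ep − k_el)`; when the
in-wash is too steep for the temporal resolution to sample the rise,
`k_ep` is flagged unreliable at the ROI level and dropped from tumor
summaries while `A` and `k_el` are retained.

Tumor response is quantified by caliper volumes
`V = (π/6)·length²·width`, relative-volume trajectories, the growth
delay `TGD_V3` (extra days, versus controls, to reach 3-fold baseline
volume, with lower-bound semantics under censoring), linear/quadratic
growth-trend comparisons, Student t-tests on pre→post relative changes,
and Pearson correlations across group means.

## Worked example

A reduced five-arm virtual cohort (4 tumors/arm, ~55-voxel ROIs),
simulated, fitted voxel-wise and summarized end to end:

```r
library(brixflow)
cfg <- pipeline_config(
  design = list(groups = default_groups(n_tumors = 4),
                roi = list(shape = c(12L, 12L), semiaxes = c(4.2, 4.2))),
  seed = 11)
rep <- run_pipeline(cfg)
print(rep)
```

```
<pipeline_report> 20 tumors in 5 groups (seed 11)
group summary (relative changes, %):
             group n dA_pct_mean dkel_pct_mean hypoxic_fraction_pct_mean dvol_pct_mean
           control 4      -17.61          45.9                      20.4         206.2
        hypoxic RT 4       19.70         -27.1                      11.6          96.8
            PL-DXR 4      -23.91          92.1                      21.6          83.9
 PL-DXR+hypoxic RT 4        3.65          47.9                      16.5          44.2
                RT 4       28.22         -27.1                      11.1          17.7
growth delay vs control (days):
  PL-DXR               7.6
  PL-DXR+hypoxic RT    >18.8
  hypoxic RT           9.9
  RT                   >21.1
```

Reading the output: `dA_pct_mean` is each arm's mean pre→post relative
change of the ROI-mean amplitude `A` — it falls in the two
non-irradiated arms and rises in every irradiated arm, while `k_el`
falls only in the two radiotherapy-only arms; hypoxic fractions are
lowest where `A` rose most. The growth-delay column shows `>`
lower bounds where tumors never reached 3-fold volume within the
29-day window. `rep$correlations` holds the five cross-endpoint
Pearson correlations over group means (here, hypoxic fraction versus
amplitude change: r = −0.99).

A shell entry point wrapping the same functions ships in
`inst/cli/brixflow.R` (`simulate`, `fit`, `growth`, `stats`, `run`).

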