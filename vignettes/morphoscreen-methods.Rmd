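---
title: "morphoscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphoscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscreen)
```

`morphoscreen` implements the statistical layer of a high-content drug
evaluation: it starts where the imaging pipeline ends (per-cell tables,
well-level feature matrices, growth time series) and produces disruption,
dependency, uniformity, localization and growth summaries. This vignette
explains the statistical model behind each stage, the tunable parameters,
the numerical choices, and what the synthetic-data module does and does not
emulate.

## Robust statistics throughout

Every spread estimate in the package is the **raw median absolute
deviation**, `mad_raw(x) = median(|x - median(x)|)`, *without* the 1.4826
normal-consistency constant. The package's decision rules — the 2-MAD well
and time-point outlier cuts and the modified Z′ — are all defined on this
raw scale, so introducing the consistency constant would silently rescale
every threshold. High-content intensity and area data are heavy-tailed and
frequently contaminated by segmentation artefacts, which is why
median/raw-MAD replaces mean/SD everywhere.

## Feature curation and normalization

`curate_features()` removes features with variance below `variance_threshold`
(default `1e-8`, i.e. near-constant) and then greedily trims correlated
features until no retained pair exceeds `correlation_threshold` (default
0.9 absolute Pearson). The greedy order is deterministic and seed-free: at
each step the feature with the highest mean absolute correlation to the
remaining features is dropped (ties broken towards the later column) and
correlations are recomputed. Cell Painting exports are massively redundant —
thousands of features arising from a few hundred effective measurements —
and downstream correlation distances would otherwise be dominated by the
largest redundant block. The default thresholds are package choices; typical
Cell Painting tables retain roughly a tenth of their input features under
correlation trimming at this level, and both thresholds are surfaced in the
pipeline manifest.

`normalize_to_control()` robust-standardizes each feature against the
vehicle (DMSO) wells of the control genotype:
`(x - median_control) / MAD_control`. When several plates are present the
statistics are computed per plate from that plate's own vehicle wells, which
contains plate effects without any further batch correction. Features whose
control MAD is zero carry no usable control spread and are dropped with a
report. After normalization every feature is on the same robust scale, so
the PCA stage applies no second scaling pass.

`remove_outlier_wells()` implements the replicate-level cleaning rule:
within a group of biological replicates, wells farther than 2 raw MADs from
the group median are removed. The rule is single-pass (statistics computed
once, no re-trimming) and strict (`>`), so an all-equal group — MAD 0,
deviations 0 — keeps every well. Groups of fewer than 3 wells cannot support
the rule and pass through with a warning.

## Correlation-distance profiling and uniformity

Wells are compared by **correlation distance**, `1 - Pearson r` across the
retained features: 0 for identical profile *shapes*, 1 for unrelated, 2 for
anti-correlated. Pearson (not Spearman) is used because the features are
already robust-normalized continuous scores; this follows standard
image-based profiling practice. Complete-linkage clustering operates on this
distance (merge height = maximum pairwise distance), and
`pca_trajectories()` tracks each (genotype, treatment) centroid across
increasing dose, with the genotype's vehicle centroid as dose 0.

The **morphological uniformity** of a well is `1 - mean correlation
distance to all other like-treated wells` (same genotype, treatment,
concentration). The self-distance (always 0) is excluded by default —
including it only dilutes the statistic by a constant — but
`include_self = TRUE` restores the inclusive reading. Both orientations
(mean like distance and 1 minus it) are reported, since "higher uniformity"
should be numerically higher in plots. Singleton groups have no like-treated
partner and are omitted with a report.

## The modified robust Z′ and dependency adjustment

The classical Z-factor, `1 - 3(SD_t + SD_c)/|mean_t - mean_c|`, certifies
assay windows; here the aim is a *relative, per-feature* measure of whether
treated morphology resolves from vehicle. Removing the scaling constant 3
and replacing mean/SD with median/raw-MAD gives

`z_mod = 1 - (MAD_treat + MAD_control) / |median_treat - median_control|`

with the convention that a tied median difference yields an undefined score
(`NA`) and no disruption call. The absolute value in the denominator is
deliberate: the flattened one-line form of the equation does not show it,
but without it the score's sign would flip with the direction of the feature
shift, which is meaningless for a disruption measure. Key properties, all
tested: `z_mod <= 1` with equality iff both MADs vanish with distinct
medians; invariance under affine transforms `x -> a + bx` (b > 0) applied to
both arms; and the sign characterization `z_mod > 0  <=>  |Δmedian| >
MAD_t + MAD_c`, which is exactly the strict disruption rule. No
multiple-testing layer is added: disruption is a deterministic threshold
rule, not a p-value procedure.

`disruption_table()` scores each treated (genotype, treatment, dose) group
against the *same genotype's* vehicle wells, so each genotype carries its
own morphological baseline. `dependency_adjust()` then subtracts the KO
score from the WT score per (feature, treatment, dose). Scores below
`clamp_floor` (default −10), including the `NA` sentinel, are raised to the
floor before subtraction: near-tie denominators produce arbitrarily negative
scores whose magnitude is noise, and propagating them (or −∞) would poison
the difference. The floor preserves sign information while bounding
influence; it is a config key, and the adjusted scores are antisymmetric in
the two genotypes once clamping is applied. By default only features with
discriminatory potential in WT (`z_wt > 0`) are reported, since dependency
of a feature that is not disrupted anywhere is not interpretable.

## Localization analysis

Per-cell nuclear:cytoplasmic ratios proxy the transcriptional activity of
YAP-like shuttling proteins. Because localization depends strongly on cell
crowding, cells are filtered to a **45–55% cell-contact window** before
aggregation; the window is read as closed (`[45, 55]`) — the boundary cells
are retained — and both bounds are parameters. "Detectable signal in both
compartments" is implemented as strictly positive intensities, the weakest
faithful reading; cells failing it are flagged and counted, never silently
dropped. Wells are summarized by the *median* cell ratio (robust to a
minority of mis-segmented cells), expressed as percent of the same-genotype
vehicle baseline, and cleaned by the 2-MAD rule across biological
replicates. The vehicle baseline pools vehicle-well medians with the *mean*
(percent-of-control convention; switchable to median), computed within each
plate so that plate-wide intensity rescaling cancels exactly.

## Growth quantification

2D proliferation tracks (percent confluency over ~72 h) are fit with a
three-parameter logistic `L / (1 + exp(-k (t - t0)))` by Levenberg–Marquardt
least squares. Initialization is deterministic — `L` from the observed
maximum, `t0` from the time of half-maximum, `k` from a logit-linear
pre-fit — so fits are reproducible without random restarts. The
single-number **slope statistic is `L·k/4`**, the curve's maximal
derivative: unlike `k` alone it is scale-consistent with the confluency
units, and `k` remains available from the fit for users who prefer it.
Slope statistics are normalized to the mean vehicle slope within genotype,
and negative rates are clipped to 0 (a shrinking well is "no growth" for
response purposes). Constant series short-circuit to slope 0; a failed
nonlinear fit falls back to a straight-line slope with `fit_ok = FALSE`.
Noiseless recovery is tested to a median relative slope error below 1e-3
over `k` in 0.02–0.3 per hour.

Spheroid tracks are noisier: per time-point, areas more than 2 raw MADs from
the like-treated group median are masked, and wells with strictly more than
half their time-points masked are excluded. Trimming pools within
like-treated wells of a replicate batch (pooling across treatments would
conflate treatment effects with artefacts; `pool_all_wells = TRUE` restores
the global reading). Spheroid growth is the day-7 area over the 24-h area
within each well, with a ±4 h tolerance for finding the nearest unmasked
anchor (imaging grids vary); any fallback use is recorded. Sensitivity
compares per-well responses `100 (1 - normalized growth)` against the mean
response of a reference genotype; negative values mean reduced sensitivity
(or growth stimulation).

## What the synthetic generator emulates — and what it does not

`synthetic_config()` fixes the study conditions: 2 genotypes (WT, YAP KO),
two inhibitor families at 0.1/1/10 µM, 3 replicate wells per feature-matrix
group, 3 biological replicates × 4 technical wells for the per-cell assay,
and logistic growth (L = 100% confluency, k = 0.1/h WT and 0.07/h KO,
midpoints 36/42 h). Features are unit-variance with shared latent block
factors (loading `sqrt(block_rho)`), reproducing the redundancy the curation
stage must remove. Planted treatment effects shift a configurable fraction
of features (default 0.3 — `effect_size` alone cannot size the affected
set, so the fraction is an explicit parameter) by `effect_size` control-MAD
units at top dose, scaled log-linearly with dose from one third of the full
effect at the lowest dose (a zero-effect lowest dose would make that arm
uninformative); dependent features (default half) lose the effect entirely
in the KO (`ko_attenuation = 0`, all-or-none, giving unambiguous ground
truth; a partial attenuation factor is exposed). Outlier wells receive a
large constant shift on all features — the failure mode the scalar 2-MAD
well rule targets. Cell tables use log-normal intensities with a
multiplicative dose-dependent ratio reduction (default 0.5 at top dose);
growth tracks add multiplicative log-normal noise and, in spheroid mode,
sporadic 3× artefact spikes.

The generator emulates the *statistical* structure the analysis assumes —
not images, not segmentation errors beyond tabular spikes, not
pharmacology. Passing recovery tests therefore demonstrates that the
analysis correctly inverts its own generative assumptions (shift detection,
dependency classification, artefact rejection); it does not certify
performance on real Cell Painting data, where feature distributions are
skewed, effects are correlated with the block structure, and plate effects
are not purely multiplicative.

## Numerical and degenerate-input choices

* Tied medians → `NA` disruption score, not disrupted, clamped before
  dependency subtraction.
* Zero-MAD control features are dropped at normalization with a report; a
  zero-variance well profile is an error at distance computation (it has no
  profile shape).
* All outlier rules use strict inequalities, so zero-spread groups are never
  trimmed.
* Correlation trimming ties break towards the later column, making curation
  idempotent and order-stable.
* Exact-half trimmed spheroid wells (50%) are retained; exclusion requires
  strictly more.
* All CSV I/O is locale-independent (dot decimal separator); the pipeline
  manifest records the config hash, seed, package version and per-artifact
  checksums, and deliberately no timestamp, so fixed-seed runs are
  byte-identical.

## Problem sizes used by the tests and acceptance script

Simulation-based guarantees run at sizes a laptop handles in seconds:
disruption/dependency recall uses 200 replicates of a 40-feature,
8-wells-per-arm screen (planted effect 6 control-MAD units); the uniformity
permutation check uses 200 replicates of 4+4 wells with the exact 70-way
label permutation; the null calibration uses 1,000 independent features at
3 wells per arm; logistic recovery uses 100 noiseless tracks. These sizes
were chosen to keep Monte-Carlo error well below the asserted margins
(binomial SE < 1% at 200 × 12 planted features) while remaining quick to
re-run.

## Known limitations

* Dependency adjustment assumes matched (feature, treatment, dose) designs
  across genotypes; unbalanced designs are a reconciliation error, not a
  partial result.
* The 2-MAD well rule needs ≥3 replicates; duplicate-well designs pass
  through unfiltered.
* The logistic fit assumes a single growth phase; biphasic or regressing
  cultures fall back to linear slopes.
* Uniformity compares wells within groups only; it does not correct for
  position effects within plates.
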