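---
title: "Methods and design notes for eaetx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for eaetx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `eaetx`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely
open. The companion README shows a worked example; the test suite and
`scripts/acceptance.R` compute every empirical claim referenced here.

## Study designs the package addresses

The package targets single-channel bead-array experiments with a
randomized block structure:

* a **spinal-cord design**: six mouse groups — wild type (WT), healthy
  opticospinal-EAE controls (OSE0), mildly (OSE1) and severely (OSE4)
  diseased OSE mice, adjuvant-only controls (CFA), and induced MOG EAE at
  score 4 (MOG4) — with four expression chips each carrying one sample
  per group (24 samples);
* a **T-helper-cell design**: naive TH0 plus in-vitro polarized TH1 and
  TH17 cells (4/7/7 samples) derived from four mouse pools, the pools
  playing the chips' role.

The chip or pool is a *block*: samples sharing it are positively
correlated. All group comparisons are expressed as zero-sum contrasts of
group means (`design_spec`).

## Preprocessing

**Detection filter.** Bead arrays report a per-probe/per-sample detection
p-value (the probability that the observed intensity is background).
`filter_probes` retains probes detected (p < `detect_alpha`, default
0.05) in at least `detected_fraction` (default 0.9) of samples, and drops
probes whose annotation quality is `bad` or `no_match`. The published
wording of such filters ("removed if detection p < 0.05 in more than 10%
of the samples") taken literally removes exactly the well-detected
probes; we implement the standard retain-if-detected semantics and
provide `literal = TRUE` to reproduce the verbatim rule, recording the
discrepancy rather than silently resolving it.

**Variance stabilization.** Raw bead intensities have additive background
plus multiplicative signal noise, so the variance grows with the mean.
`vst_transform` (i) calibrates each sample to the across-sample reference
mean by an affine map fitted with least-trimmed squares, so that planted
or real differential expression cannot sway the calibration; (ii)
estimates the background level and spread from undetected probes
(detection p > 0.5), falling back to the lowest 5% of intensities; and
(iii) applies the generalized log
`h(y) = log2((y + sqrt(y^2 + c)) / 2)` to the background-subtracted
calibrated intensities with `c = (2 * bg_sd)^2`. For intensities well
above background `h` converges to `log2(y)`, so downstream fold changes
are on the log2 scale with no rescaling constant; near background the
transform is compressive. We deliberately do not reproduce a full
maximum-likelihood variance-stabilization fit: the contract is the
variance-flattening property itself, which the acceptance suite measures
as the ratio of median replicate standard deviations in the top versus
bottom intensity decile (required ≥ 5 before, ≤ 2 after on the default
generator). The LTS line is fitted by deterministic concentration steps
from an OLS start (refit on the 80% of points with smallest squared
residuals until the active set stabilizes); the test suite checks it
against `MASS::lqs` on a contaminated fixture.

**Batch checks.** `batch_association` regresses each of the first
`n_pcs` (default 10) sample-space principal components on the block and
position factors and reports one-way ANOVA p-values, skipping degenerate
factors.

## Differential expression with a random block effect

**Model.** For probe *g* the expression vector follows a group-means
linear model with covariance `sigma_g^2 * V(rho)`, where `V` has unit
diagonal and `rho` off-diagonal within each block (compound symmetry).
This is the marginal model implied by an additive random block shift, and
it is what justifies a *single* correlation shared by all probes.

**Consensus correlation.** `estimate_consensus_correlation` maximizes
the REML likelihood in `rho` separately per probe, profiling out
`sigma_g^2`, then combines the per-probe estimates as
`tanh(mean(atanh(rho_g), trim = 0.15))`. The trim (default 0.15, a
package default) keeps non-convergent or boundary probes from dominating;
constant probes are dropped with a message. Estimates are clamped to the
admissible range `(-1/(max block size - 1), 0.99]`. Computationally,
compound symmetry has a rho-free eigenbasis (the normalized one-vector of
each block and any orthonormal complement), so the data are rotated once
and every REML evaluation is a cheap weighted least squares. The test
suite cross-checks the consensus against `limma::duplicateCorrelation`
(agreement to < 0.02 on shared simulations) without using it in the
implementation. Parameter recovery on the generator's normalized output
(planted rho = 0.3 within ±0.1, rho = 0 within ±0.05 at 2000 probes) is
part of the acceptance suite; the estimator inherits the mild downward
bias of trimmed consensus estimators, visible there.

**GLS and moderation.** `fit_gls` whitens with `V(rho)^(-1/2)` and fits
all probes in one pass; `d = n - p` residual degrees of freedom. Under
the scaled inverse-chi-square prior `sigma_g^2 ~ s0^2 * d0 / chisq(d0)`,
the observed `s_g^2` follow `s0^2 * F(d, d0)`, so `log s_g^2` has mean
`log s0^2 + psi(d/2) - log(d/2) - psi(d0/2) + log(d0/2)` and variance
`psi'(d/2) + psi'(d0/2)`. `moderate` matches these two moments, inverting
the trigamma function by Newton iteration. When the method-of-moments
excess variance is non-positive the prior is degenerate: `d0 = Inf` and
`s0^2` is the geometric mean of the variances, which returns the common
value when all `s_g^2` are equal. `contrast_tests` then forms the
moderated t on `d0 + d` degrees of freedom (normal at `d0 = Inf`,
ordinary t at `d0 = 0`), with BH adjustment within the contrast.
The significance threshold for "differentially expressed" is adjusted
p < 0.05 by default and configurable; acceptance requires realized FDR
≤ 0.075 and sensitivity ≥ 0.5 at planted |logFC| = 1 on default
synthetic data, averaged over 20 seeds.

## Directional sets and enrichment

Set membership is **direction-agnostic** — a probe significant in any
direction belongs — with the direction kept as annotation. This matches
how enrichment tables count genes, while the Venn display
(`directional_venn`) tallies up- and downregulated transcripts
separately, so a probe regulated in opposite directions in two contrasts
appears in both direction-specific tallies. The named analysis sets are
boolean rules over significance flags, with the control contrasts
defaulting to CFA−WT and OSE0−WT: CDT (both disease contrasts, no
control), OSE4sp / MOG4sp (one disease contrast only), OSE1ex (mild
contrast, no control), OSE1sp (mild contrast only). CDT, OSE4sp and
MOG4sp are pairwise disjoint by construction and OSE1sp is a subset of
OSE1ex; both facts are asserted in tests. Gene-level projections use
unique gene ids, drop unannotated probes with a count, and flag genes
whose probes disagree in direction.

**Permutation overlap test.** Each permutation draws as many random genes
from the universe as there are unique DE genes and records whether the
random overlap with the test set reaches the observed one;
`p = max(n_ge, 1) / n_perm`, censored (displayed `< 1/n_perm`) when no
permutation reaches it. Two implementation notes:

* The null overlap distribution is symmetric in the two set sizes, so
  the sampler draws the *smaller* of (DE set, test set) and counts
  membership in the other — distributionally identical and much faster
  for the large DE sets typical here. The acceptance suite checks the
  sampler against the exact hypergeometric tail on a 20-case grid at
  100,000 permutations and against exhaustive enumeration on a 12-gene
  universe.
* Each row of an enrichment table gets its own RNG stream derived from
  the master seed and a hash of the row's labels, so results do not
  depend on execution order.

**Adjustment family.** Published enrichment tables of this design follow
the *step-down* (Holm) adjustment: with censored cells represented by
their bound `1/n_perm`, Holm adjustment of the three published raw
columns reproduces all 20 adjusted cells at two significant figures,
including the running-maximum pairs — the acceptance suite recomputes
this. Methods sections often cite BH instead; both are provided
(`adjust = "holm"` default for `run_enrichment_suite`, `"BH"`
selectable), and the discrepancy is documented rather than resolved. The
permutation universe defaults to the unique annotated genes of the
filtered platform and is caller-configurable (e.g. to a protein-coding
reference), since published analyses rarely state it.

## Scores, clusters, paired tests

`geneset_pc_scores` runs covariance-scale PCA (centered, unscaled
variables) of the samples × member-transcript submatrix, standardizes
scores to unit variance for display, and fixes each component's sign so
its loading sum is positive — a deterministic replacement for the
arbitrary orientation of eigenvectors; the disease-direction reading is
left to the analyst. `compare_score_groups` tests each non-control group
against pooled controls; the test is Welch's t by default (Wilcoxon
selectable) with BH adjustment — the underlying publications typically do
not name this test, so it is a documented, configurable default.

`kmeans_stability` repeats k-means (default k = 4, 100 restarts) with
random initialization, canonicalizes each partition by numbering clusters
in order of their smallest member index, and reports the modal partition
with its frequency; `bipartition_respect` measures how often no cluster
mixes two prescribed sides (e.g. healthy vs diseased groups). Clustering
operates on the first two display PCs by default, configurable to full
expression space.

`magnitude_binomial` and `direction_consistency` pair probes across two
contrast tables and test success fractions against 0.5 with the exact
two-sided binomial test in the minimum-likelihood convention (sum of
outcome probabilities no larger than the observed outcome's), accumulated
in log space so that p-values far below double underflow remain usable
via `log_p`. Exact ties in |logFC| are excluded and counted — whether
published analyses dropped or counted ties is typically unstated, so the
choice is explicit here. Confidence intervals are two-sided 95%
Clopper–Pearson from beta quantiles, with the all-agree case giving
`(0.025^(1/n), 1]` exactly.

## The synthetic-data generator

`simulate_experiment` emulates, per probe, log2 signal = baseline + group
effect + block effect + residual, then maps to the raw scale as additive
background `N(60, 5)` plus the exponentiated signal scaled by log-normal
multiplicative noise (sd 0.05 on the natural-log scale). Detection
p-values are the upper-tail probability of the background distribution at
the observed intensity — small for expressed probes, uniform for the 10%
of probes simulated as background-only. Key parameters and why:

* `d0 = 4`, `s0sq = 0.05`: residual variances are drawn scaled
  inverse-chi-square so the moderation hyperparameters are recoverable by
  construction (acceptance: d0 within [3.2, 4.8], s0sq within
  [0.04, 0.06] in ≥ 18/20 seeds at 5000 probes).
* `sigma_block` is expressed in units of the probe's residual sd, making
  the implied within-block correlation `rho = sigma_block^2 / (1 +
  sigma_block^2)` homogeneous across probes — the compound-symmetry
  structure the downstream model assumes. `sigma_block_for_rho` converts
  a target correlation. Default 0.5 (rho = 0.2), a moderate chip effect.
* Differential expression is planted at the **gene** level (all probes of
  a planted gene shift together) with fraction `de_prop = 0.1` per
  disease contrast and fixed magnitude `effect_size = 1` log2 units —
  the conditions under which FDR and sensitivity are assessed. Planting
  shifts the positive-coefficient group of each contrast, so effects
  spill into other contrasts sharing that group (e.g. OSE4−WT), exactly
  as real biology would; the truth tables record the realized per-contrast
  fold changes, not the planting schedule.
* Baseline log2 intensities `N(7, 1.5)` and the background parameters
  were chosen once as bead-array-like magnitudes that give the raw scale
  a strongly increasing mean–variance relationship (top/bottom decile
  replicate-sd ratio well above 5), which is the property the glog
  transform must remove.
* `output_scale = "normalized"` returns the log2 signal directly, without
  the measurement layer. Parameter-recovery checks (block correlation,
  variance prior) use this output because they test estimators against
  the model those estimators assume; the raw output adds background and
  multiplicative noise that attenuate the within-block correlation — a
  real phenomenon, but one that would conflate measurement-layer effects
  with estimator quality.
* `plant_gene_set` includes each universe gene with Bernoulli probability
  whose odds are `omega`-fold higher for DE genes, renormalized to
  expected size K (uniform at `omega = 1`, DE-only sampling at
  `omega = Inf`).

What the generator does **not** emulate: probe sequences and
cross-hybridization, spatial chip artifacts, bead-level summarization,
sex effects in the T-cell design (supported via the group/block
machinery but off by default, as the published designs do not state a
sex term), and outlier samples. Passing tests therefore demonstrate
correctness of the statistical machinery under its assumed model plus a
realistic measurement layer — not robustness to every artifact of real
bead arrays.

## Numerical choices and degenerate inputs

* REML optimization: golden-section search (`stats::optimize`) with
  tolerance 1e-4 on the clamped interval; near-zero-variance probes are
  excluded from the consensus; duplicated samples within blocks drive the
  estimate to the upper clamp 0.99, which is tested.
* Trigamma inversion: Newton iterations from `x = 0.5 + 1/y`, with
  asymptotic branches for extreme arguments.
* Hypergeometric tails are computed via `phyper` in log space; exact
  binomial tails via `dbinom(log = TRUE)` and log-sum-exp.
* Ties in the paired tests are removed before testing; `k = n/2` returns
  p = 1 exactly.
* Empty analysis sets yield flagged enrichment rows with p = 1 rather
  than errors, so one degenerate set cannot abort a table.
* All library code restores the caller's RNG state; every stage of
  `run_pipeline` derives its own stream from the master seed by fixed
  offsets, and per-row enrichment streams are hashed, so results are
  independent of execution order.

## Problem sizes

The test and acceptance suites run at 2000–5000 probes, 20-seed
replication for error-rate averages, 500 replicates for calibration
checks, and 100,000 permutations where oracle agreement is measured —
sizes at which every targeted property is measurable with comfortable
Monte-Carlo margins.

## Known limitations

* The consensus-correlation estimator is mildly biased toward zero (as
  trimmed consensus estimators are); the acceptance bounds account for
  this, and strongly unbalanced designs with very few blocks will widen
  it.
* The glog transform's background estimate needs either detection
  p-values or enough low-intensity probes; arrays filtered to expressed
  probes *before* normalization fall back to the lowest-5% heuristic.
* The pipeline accepts externally deposited expression matrices as TSV
  inputs, but platform-specific annotation (probe quality, probe-to-gene
  maps) must be supplied by the caller; no annotation database is
  bundled or fetched.
* P-values from the permutation test are bounded below by `1/n_perm`;
  tables mixing censored and uncensored rows are adjusted under the
  documented censoring convention rather than by re-running with more
  permutations.
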