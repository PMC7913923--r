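---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirtbi)
```

`mirtbi` re-implements a plasma miRNA biomarker discovery workflow for the
rat lateral fluid-percussion model of traumatic brain injury: quality
control, count normalization, differential expression, nested
cross-validated feature selection, droplet digital PCR (ddPCR) absolute
quantification, and ROC/cutpoint diagnostics, with a synthetic-cohort
generator standing in for the original sequencing data. This vignette
documents the statistical models, the tunable parameters, and the design
choices made where the methods left genuine freedom.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream stage is exercised.

**Counts.** `simulate_count_matrix()` draws negative-binomial (NB) counts.
Each miRNA receives a baseline abundance `2^N(baseline_log2_mean,
baseline_log2_sd)` (defaults 7 and 2: median counts around 128 with a
realistic four-order-of-magnitude abundance spread); group effects multiply
the mean by `2^effect`; per-sample library sizes, uniform over
`library_size_range` (default 0.8–1.2 million miRNA-mapped reads), scale
all means relative to the midpoint of the range. The `dispersion` field is
the NB *size* parameter shared across miRNAs — size → ∞ is the Poisson
limit — with default 10, i.e. a dispersion α of 0.1, a typical value for
abundant miRNAs in bulk plasma small-RNA-seq with biological replicates.
The default rat design plants the three validated markers (miR-9a-3p,
miR-136-3p, miR-434-3p) at the whole-cohort RT-qPCR 2^−ΔCt fold changes
(`rtqpcr_reference_folds()`): these are the study's expression-level
measurements, whereas ddPCR copies/well are not comparable across assays
(the assays used different cDNA dilutions) and therefore parameterize only
the copy-number simulations. Two further low-abundance candidates with
moderate effects mimic the machine-learning hits that failed PCR
validation.

**Cq tables.** `simulate_cq_table()` uses `Cq = baseline − log2(relative
abundance) + N(0, noise_sd)` (default noise 0.5 cycles, a typical
inter-replicate SD for SYBR assays); the hemolysis pair miR-23a/miR-451
and the reference miR-28-3p are always present, and samples flagged as
hemolyzed get their pair difference forced above the 5-cycle threshold by
0.5–3 cycles.

**ddPCR wells.** Template molecules partition over droplets with Poisson
occupancy, so the positive-droplet count is Binomial(n, 1 − e^(−c/n)).
Amplitudes come from two Gaussian clusters (defaults 4000 and 14000 AU with
SDs 700/900 around a 10000 AU threshold), clamped to their side of the
threshold so that amplitude calling reproduces the simulated occupancy
exactly — the generator emulates well-separated clusters, not "rain".

**Copy numbers.** Between-animal copies/well are log-normal around the
printed geometric group means with log-scale SD 0.3. The study reports no
between-animal variance, so 0.3 is a free, configurable parameter: it
corresponds to a coefficient of variation of about 31%, between the
instrument-level precision of ddPCR and the ~80% CVs seen for unnormalized
human plasma input.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artifacts (adapter loss, UMI
collisions, mapping bias), compositional coupling between miRNAs,
correlated dispersion structure, batch and hemolysis covariation with
expression, ddPCR rain, or the heavy-tailed heterogeneity of human
cohorts. Conclusions from the synthetic cohorts are about the pipeline's
statistical behavior, not about plasma biology.

## Quality control

Hemolysis flags are strict inequalities at both thresholds (absorbance
coefficient > 0.25 at 414 nm; ΔCq(miR-23a − miR-451) > 5 cycles), so
boundary values pass. The two methods are independent and may disagree —
in the study, pooled plasma was 35% hemolyzed by absorbance and 0% by
ΔCq — so both flags are carried and the default policy is report-only:
no sample is excluded downstream. A sample missing either pair member is
unassessable rather than flagged.

## Normalization and exploratory summaries

CPM divides by the per-sample total of miRNA-mapped reads, which may
exceed the in-matrix column sums when the matrix holds a filtered subset.
The prevalence filter retains miRNAs with count ≥ `min_count` (default 1)
in at least `ceiling(min_fraction × n)` samples (default 80%).

The stability ranking (`normfinder_stability()`) is a per-assay one-way
decomposition: inter-group variance of the group means around their grand
mean, intra-group sample variance, combined as the mean over groups of
`|group deviation| + sqrt(within-group variance / n_g)` — an
Andersen-style combination of bias and noise in which a constant assay
scores exactly 0. Sample-effect centering (subtracting each sample's mean
over assays) is deliberately omitted: it would make a constant assay
inherit the other assays' variation. By default the input is
log2(x + 1)-transformed, matching the approximately additive error model
the decomposition assumes; `log2_transform = FALSE` reproduces the
raw-count mode (which yields stability values on the count scale — the
study's famously large stability value for miR-28-3p is an artifact of
that mode and is not a reproduction target). PCA runs on log2(x + 1) with
feature centering; Spearman matrices use mid-ranks, with correlations
involving a constant sample reported as undefined (and maximal distance
for clustering); "detected" for Venn counts means count > 0 in at least
one sample of the group, a rule the source analysis left undefined.

## Differential expression

The DE module is an intentionally simplified NB pipeline — no dispersion
shrinkage toward a trend, no fold-change shrinkage, no independent
filtering — so exact concordance with full-featured DE packages is a
non-goal; calibration and sign-recovery on well-powered simulations are
the test surface. Per miRNA: normalize by median-of-ratios size factors;
pool within-group variances; estimate dispersion by method of moments,
`max((σ² − μ̄)/μ̄², 10⁻⁸)`; form the Wald statistic
`log(μ_A/μ_B) / SE` with `SE² = (1/μ_A + α)/n_A + (1/μ_B + α)/n_B`.

Two numerical choices matter. First, the two-sided p-value refers the
Wald statistic to a **t distribution with `n_A + n_B − 2` degrees of
freedom** rather than a normal: with n = 10 + 10 and a method-of-moments
dispersion, the normal reference is anticonservative (empirical type-I
error ≈ 0.07 at nominal 0.05 in our null simulations) while the t
reference is calibrated (≈ 0.05); the acceptance suite verifies the
[0.03, 0.07] band on 2000 simulated null miRNAs. Second, a group mean of
exactly zero (with signal in the other group) receives a half-count
continuity correction so the fold change stays finite; miRNAs all-zero in
both groups are excluded and reported.

## Nested-CV feature selection

The outer loop is leave-one-out; the inner loop is stratified 3-fold
cross-validation (an inner leave-one-out on ~9 training samples is
degenerate for AUC, which needs both classes in the validation pool).
Within each outer training set: zero-variance features are dropped,
features are standardized with training statistics only — the test suite
verifies that replacing a held-out sample's values by arbitrary constants
leaves its fold's model untouched — the grid is searched over
regularization strength (default {0.01, 0.1, 1, 10}), number of features
({1, 2, 5, 10, 20}), selection method (RFE with step 1, or a univariate
F-score filter), and penalty (L1/L2), maximizing the pooled inner AUC with
ties resolved to the earliest grid row. The winner is refit on the full
outer training set and scores the held-out sample with its positive-class
probability; CV AUC is the rank-formulation AUC over held-out scores only.

**Class-balanced observation weights.** Leave-one-out training sets are
inherently imbalanced against the held-out sample's class. With
unweighted fits the intercept tilts every held-out score away from its own
class, and the pooled null CV AUC collapses far below 0.5 (in our null
simulations, to a mean of about 0.25 with a large atom at exactly 0).
Logistic fits therefore weight each observation by
`n / (2 n_class)`, which restores a near-chance null distribution and
removes the artifact; this is an estimator-quality choice, not a tuning
knob.

The permutation test repeats the full nested CV on uniformly permuted
labels and reports the add-one estimator
`p = (1 + #{AUC_perm ≥ AUC_obs}) / (B + 1)` (default B = 1000), which
cannot reach zero. Feature importance is the outer-fold mean of absolute
standardized coefficients (eliminated features contribute 0), normalized
to sum to one, descending with lexicographic tie-breaks.
`select_candidates()` intersects the top-k (default 5) with DE
significance; the flagged intersection is the validation-priority set.

At the study's sample sizes this estimator is honest rather than
flattering: on a 9-sample synthetic sequencing subset, spuriously
discriminative noise features can enter individual folds and drag the CV
AUC well below 1 even with strong planted markers — which is precisely why
the workflow treats machine-learning candidates as hypotheses for PCR
validation, not endpoints.

## ddPCR quantification

Each well is Poisson-inverted: `λ = −ln(1 − p)` with `p` the
positive-droplet fraction (amplitudes at or above the threshold count as
positive), and `copies = λ × n_total` — template molecules among the
analyzed droplets. A saturated well (p = 1) is an error, not a number.
The alternative `"reaction"` mode, `copies = λ × 20 µL / 0.85 nL`,
rescales to the nominal reaction volume; it is off by default because the
printed copy magnitudes follow the per-analyzed-droplet convention.
Replicates are summarized by the arithmetic mean. In the linear regime
(p < 0.1) the Poisson correction inflates raw positives by at most ~5%,
which the tests bound at 6%.

Group fold changes are ratios of arithmetic group means reported to one
decimal with **half-up rounding**: base R's round-half-even would turn a
ratio of exactly 5.05 into 5.0, whereas the study's reporting convention
(like most statistical GUIs) rounds it to 5.1; half-up reproduces all
printed fold values.

## ROC, cutpoints and flagging

AUC uses the rank (Mann–Whitney) formulation with mid-rank ties;
significance is the two-sided Mann–Whitney U test, exact when the combined
n is at most 20 with no ties, tie-corrected normal approximation with
continuity correction otherwise. Cutpoint candidates are the midpoints
between adjacent distinct observed values plus ±∞; a value **at or above**
the cutoff is classified positive (the elevated-marker direction — the
source does not state its convention, so ≥ is fixed and documented); the
chosen cutoff maximizes sensitivity + specificity, with ties resolved to
the highest specificity and then to the smallest cutoff (a tie-break the
reference cutpoint software leaves unspecified). When all values are
equal the problem is degenerate (best achievable sum is 100) and the
result is flagged. Elevated-subpopulation flagging uses strictly greater
than `mean + k·SD` of the reference group (sample SD, k = 1 by default);
the optional covariate cross-tabulation (S100B at 0.1 µg/L) places samples
with missing covariates in an explicit unknown margin.

## Orchestration

`run_pipeline()` executes simulate → QC → normalize/EDA → DE → select →
quantify → ROC/flags from a single config (`default_config()`, YAML
overrides via `read_pipeline_config()`), writes every artifact, and
records md5 checksums in a manifest; reruns with an identical config are
byte-identical, and a failing stage is recorded in the manifest before the
error propagates. All study thresholds appear as named defaults (0.25;
5 cycles; count ≥ 1 in 80%; FDR 0.05; 10000/6000 AU; mean + 1 SD;
0.1 µg/L), so the default profile is the study's analysis.

## Problem sizes used by the test suite

Simulation sizes were chosen so the whole suite runs comfortably on one
core: 2000 null miRNAs for DE calibration; 200 permutation-calibration
runs of 12 samples × 8 features with 59 permutations each (59 because the
add-one estimator needs at least 40 permutations for p < 0.05 to be
attainable, and the discrete AUC support at n = 12 makes a strict-
domination rule over ~40 draws tie-sensitive); 20 seeded recovery runs of
303 miRNAs × 15 samples; 500-replicate ddPCR round-trips; 100 random
instances for the exhaustive ROC/cutpoint oracles. The default pipeline
config simulates 300 miRNAs and 19 permutations; all sizes scale up via
the config.

## Known limitations

* The DE model is two-group only (the study design is one-factor); no
  covariates, no shrinkage. DE counts from the original data are not
  reproducible from synthetic cohorts and are not targets.
* CV AUC values printed in the study (0.95, 1.0) depend on the real
  sequencing data and the exact (unpublished) grid; they are qualitative
  anchors. The permutation calibration and recovery properties are the
  testable surface.
* The NormFinder variant (with/without inter-group covariance correction)
  is not specified by its one-line citation in the source; the
  decomposition implemented here is documented above and tested against
  its own hand-computed oracle.
* The a414 hemolysis coefficient is treated as an opaque input; no
  spectrum processing.
* Copies-per-well follows the per-analyzed-droplet convention; whether the
  instrument applied Poisson correction to its printed values is not
  stated, and both modes are provided for inspection.
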