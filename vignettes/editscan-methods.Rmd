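---
title: "Methods: differential RNA editing, marker selection, and proteome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential RNA editing, marker selection, and proteome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and their defaults, the numerical
choices, what the synthetic generators do and do not emulate, and the
known limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The differential-editing model

At a candidate editing site, one sample yields `k` edited reads out of
`n` covering reads; the editing frequency is the binomial proportion
`f = k/n`. The per-replicate uncertainty is summarized by the
likelihood-ratio confidence interval

> `CI(k, n) = { p : 2[ℓ(k/n) − ℓ(p)] ≤ χ²₁(level) }`,

with `ℓ(p) = k log p + (n−k) log(1−p)` and the `0·log 0 = 0`
convention. By Wilks' theorem the deviance is asymptotically χ²₁, so the
`level` quantile gives asymptotic `level` coverage. The deviance is
monotone on each side of `k/n`, so both bounds are found by bisection;
tolerance is absolute `1e−8` (far below any biological signal, cheap at
desk scale, and — unlike Newton steps — immune to the flat likelihood
near `k = 0`/`k = n`). The lower bound is exactly 0 iff `k = 0`, the
upper exactly 1 iff `k = n`.

**Coverage.** The interval is asymptotic; at small `n` its true coverage
oscillates because `k` is discrete. The acceptance suite computes the
empirical coverage pooled over 20,000 draws across
`n ∈ {10, 30, 100} × p ∈ {0.05, 0.2, 0.5}` (about 94%, within 3 points
of nominal) and reports the per-cell actuals. Per-cell coverage at
`n = 10` dips well below nominal for central `p`: the 0.5 boundary falls
just inside the deviance threshold for `k = 2` and `8`, a knife-edge of
the interval itself, which the same suite verifies to be
grid-search-exact (step `1e−6`, agreement within `2e−6` for all
`(k, n)`, `n ≤ 50`). No continuity correction is applied; Wald and
Bayesian intervals are out of scope (the Wald value appears only as a
large-`n` oracle in the tests).

**From interval to weight.** The group comparison needs a variance per
replicate. The interval is mapped to a standard deviation by

> `σ = (upper − lower) / (2 z)`, `z = Φ⁻¹((1+level)/2)`,

i.e. the SD a normal distribution would need to produce an interval of
that width, floored at `σ_min = 1/(2n)`. The floor is this package's
explicit choice for boundary sites (`k = 0` or `k = n`, where one bound
sits on the parameter boundary and the width underestimates the
sampling SD): it keeps all weights finite while preserving
coverage-driven weighting. Half a read (`1/(2n)`) is the natural
resolution of a count of `n` reads.

**The regression.** Per site, the per-sample frequencies are regressed
on an intercept plus a 0/1 group indicator by weighted least squares
with weights `w = 1/σ²`, via explicit 2×2 weighted normal equations (no
model-fitting black box; an independent dense-algebra oracle checks the
implementation to `1e−10`). With a binary covariate the slope is the
weighted difference of group means; `SE(β)² = [(XᵀWX)⁻¹]₂₂`, the
known-variance form. An unweighted mode (`weighted = FALSE`) exists for
sensitivity analysis; its SE ignores residual scale and is not a
calibrated test.

**Coverage filter and call.** Sites must have `n ≥ min_reads`
(default 10, inclusive) in *every* sample — the quantifier matters and
is tested. A site is significant when `|β|/SE(β)` strictly exceeds
`sd_threshold` (default 3); `z = 3` exactly is not significant.
Direction is `hyper` (case group edited more) for `β > 0`, `hypo`
for `β < 0`. The phrase "more than 3 standard deviations from the
confidence limits" admits a second reading — the slope clearing its own
confidence limit by 3 SD, i.e. `|β|/SE > 3 + z` — which is implemented
as `rule = "beyond_ci"` and documented as the stricter variant; the
`zstat` reading is the default because it is the only one that uses
both the regression slope and a standard-deviation scale without double
counting the level. No multiple-testing correction is applied: the
fixed 3-SD rule *is* the procedure being reproduced; sites are tested
independently.

**Realized type-I error.** The weights are estimated from the same
counts being compared: a sample whose `f̂` drifts toward an extreme gets
a narrower interval, hence more weight, which drags the weighted mean
outward and inflates `var(z)` above 1. The effect is strongest at low
editing frequencies (small expected `k`), exactly where the default
generator places most sites (`Beta(1, 9)` baselines). The acceptance
suite measures the realized null significant fraction at 4v4,
coverage 50, 20,000 sites; it comes out near 1.7% — above the
normal-theory two-sided 3-SD tail (≈0.27%) and above the ≤1% bound the
acceptance criterion states, so that criterion is left red rather than
tuned. Users should read the 3-SD rule as a fixed selection heuristic,
not a calibrated 0.27% test, at sites with low coverage-times-frequency.

**Summaries.** Genes with at least one significant site are intersected
case-insensitively with user-supplied panels. Percentages are rounded
to the nearest integer, half away from zero — the only rounding rule
consistent with the published-style arithmetic the acceptance suite
checks (16/113 → 14%, 10/113 → 9%, 22/30 → 73%). Zero significant
genes yields flagged `NA` percentages, never a division error.

## 2. Pileup parsing

`parse_mpileup_line()` implements the samtools mpileup text dialect:
`^` + mapping-quality pairs and `$` are stripped, `+`/`-` indel runs are
skipped by their stated length, `*` (deletion placeholder) and `<`/`>`
(reference skips) count toward neither `k` nor `n`, `.`/`,` are
reference calls, and base letters count toward `n` (toward `k` when they
match the edited base case-insensitively — both strands count, since the
statistics never use strand). A depth field disagreeing with the parsed
`n` by more than the number of placeholders triggers a warning and the
parsed value wins. Coordinates are 1-based throughout, matching
mpileup.

## 3. Iterative random-forest marker selection

Preprocessing follows the hippocampal recipe: male samples only, genes
with expression `< 1` in *all* retained samples removed, then
`ln(x + 1)`. The offset is a documented divergence from a bare natural
log: FPKM zeros exist, `ln(0)` does not, and `x → ln(1+x)` maps 0 to 0
while converging to `ln x` where the filter keeps genes.

The selection procedure fits `n_iterations` forests (default 10,000),
each with a fresh sub-seed derived from the master seed, records the
`top_k_per_iteration` genes (default 10, the order of the final panel
sizes) by importance in each fit, and ranks genes by selection
frequency. Ties break lexicographically, both inside an iteration and
in the final ranking, making the output a pure function of
(data, config). The forest itself is a compact compiled CART ensemble
(bootstrap per tree, `mtry = ⌊√p⌋` features per node, Gini splits,
grown to purity — with a handful of replicates trees are tiny), with
mean-decrease-in-Gini importance by default and out-of-bag permutation
importance by flag. It uses a self-contained xorshift RNG so results
are bit-identical across platforms. The ensemble is infrastructure
behind a fit/importance contract; the iteration-and-frequency
procedure, the validation, and the projection are the implemented
method.

**Validation.** `lda_validate()` is leave-one-out cross-validated
linear discriminant analysis — chosen over resubstitution as the
stricter test — with the pooled within-class covariance ridge-
regularized by `ε = 1e−6 · trace/dim` so panels larger than the sample
count remain solvable, and a nearest-centroid fallback when a training
class degenerates to one sample or the covariance has zero trace (ties
go to the majority class, so a constant gene scores the majority-class
rate). `pca_project()` is a per-gene-centered SVD returning the first
two component scores, each loading vector oriented to a non-negative
sum for deterministic signs; rank-deficient inputs report a zero second
component with a flag.

**Design note on testability.** Purity-based importance cannot
distinguish a planted marker from a noise gene that happens to separate
two small groups perfectly: both achieve maximal Gini decrease, and
bootstrap resampling of a separable point set stays separable. The
expected number of such chance separators among `G` noise genes with
`m` samples per group is about `2G/C(2m, m)` — roughly 2.7 at
`m = 4` for `G = 95`, but 0.2 at `m = 6`. The expression generator
therefore defaults to six samples per group: it is a realistic bulk
RNA-seq design and the smallest at which recovery of a planted 4-SD
panel is information-theoretically clean, which the acceptance suite
then demonstrates across five independent seeds. With three samples per
group (common in brain studies) the same procedure still *selects
discriminating genes* — but a simulation cannot then adjudicate which
discriminating genes are "true", and a real study cannot either; the
validation (LDA, PCA) speaks only to separation, not causality.

## 4. SILAC pooling and integration

Peptide H/L ratios belonging to a protein are pooled per experiment by
the **median** (robust to outlier peptides); the geometric mean — the
MaxQuant-style alternative — is available as `method = "mean_log"`.
Percent change is measured on the linear ratio scale symmetrically in
an H/L swap: `+20%` means `ratio ≥ 1.2` and `−20%` means
`ratio ≤ 1/1.2` (the `ratio ≤ 0.8` reading is available as
`down_rule = "linear"`).

Three call rules, each assigning a distinct category:

* `replicated_changes`: `|change| ≥ 20%` in **both** experiments,
  concordant direction (threshold inclusive, "at least").
* `concordant_mrna_protein`: `|change| > 15%` in **at least one**
  experiment (strict, "more than"), mRNA `p < 0.05`, and protein and
  mRNA changes in the same direction.
* `protein_only_candidates`: the replicated-change rule **plus**
  unchanged mRNA, operationalized as `p ≥ 0.05` and
  `|log2 FC| < log2(1.2)` — the differential-expression significance
  convention inverted. Upregulated calls are flagged as candidate
  ubiquitin-ligase substrates (protein up with flat mRNA is the
  signature of lost degradation).

Proteins observed in only one experiment are excluded with a message,
as are proteins with no gene mapping (mapping is a user-supplied
two-column table; no identifier services are queried). Annotation
percentages per direction and overall use the same
half-away-from-zero rounding as the editing summaries.

## 5. The synthetic world

The generators state a world and keep it fixed; they are pure functions
of their configuration including the seed.

* **Pileups**: per-site baseline frequency `Beta(1, 9)` (most editing
  frequencies are low, matching the character of real editing data);
  coverage Poisson (negative binomial by option) with mean 50 by
  default; non-null sites add `delta_f` to the case group, truncated to
  `[0, 1]` with a warning and recorded truth; counts binomial, or
  beta-binomial with intra-site correlation `ρ` (mean-`f` mapping
  `α = f(1−ρ)/ρ`) to probe robustness to overdispersion the binomial
  model ignores. What it does **not** emulate: shared ADAR trans
  effects (sites are independent), mapping artifacts, allelic SNPs
  masquerading as editing, strand bias.
* **Expression**: log-normal baselines (per-gene log-mean `N(2, 1)`,
  unit log-SD), planted group shift in log-SD units on a known subset,
  six samples per group by default (see the design note above), sex
  metadata with optional female samples to exercise the male-only
  filter. Not emulated: gene-gene correlation, library-size effects,
  count noise.
* **SILAC**: protein true ratios `1`, `1 + pct/100`, or its reciprocal
  (changed proteins split evenly up/down, concordant across
  experiments), peptide ratios log-normal around truth. Not emulated:
  peptide-specific ionization biases, missing peptides, shared
  peptides.

A green test on this world establishes that the procedures do what they
claim under their own assumptions — it does not establish performance
on real data, where the un-emulated features above are exactly the
hazards.

## 6. Numerical and degenerate-input choices

* Bisection everywhere a root is needed (guaranteed bracketing on the
  unimodal deviance); absolute tolerance `1e−8`.
* χ² and normal quantiles are computed, never hard-coded, so `level`
  is configurable.
* `0 · log 0 = 0`; likelihood at the boundary returns `−Inf` rather
  than `NaN`.
* Empty site tables propagate to empty result tables; a single group
  is an error at container construction.
* Selection-frequency ties and LDA ties have documented deterministic
  resolutions (lexicographic; majority class).
* Sub-seeds are derived as `(seed · 2654435761 + iter · 40503) mod 2³¹`
  to keep iterations independent under one 32-bit master seed.

## 7. Known limitations

* The CI-weighted test's realized type-I error exceeds its nominal
  3-SD tail at low frequency × coverage (section 1); interpret calls
  at such sites as a ranked heuristic.
* The Wilks interval's per-cell coverage at `n = 10` is materially
  below nominal for central `p` — an intrinsic discreteness effect.
* Gini importance cannot rank among perfect separators; marker panels
  from very small designs are separating sets, not causal sets.
* "Pooling" peptide ratios by median differs from MaxQuant's protein
  ratio; with few peptides and asymmetric outliers the two can
  disagree materially.
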