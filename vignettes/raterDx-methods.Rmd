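---
title: "Tie-aware evaluation of probabilistic diagnostic raters: models and design choices"
author: "raterDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tie-aware evaluation of probabilistic diagnostic raters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raterDx)
```

# Scope and data model

raterDx evaluates reader studies in which every observer — typically one
automated classifier and several human experts — assigns a probability
vector over a fixed set of diagnostic categories to every case, while the
reference standard is a binary disease/normal label. The central container,
`AssessmentTable`, extends `SummarizedExperiment`: one assay per category
(subjects × raters), truth labels in `rowData`. Validity enforces a
complete grid, non-negative values and unit mass per cell; the design
deliberately has no notion of missing reads — an incomplete grid is a data
error, not something to impute, because every downstream pairwise statistic
assumes the same cases under both observers.

The default category set is the seven-way dementia differential (CN, AD,
bvFTD, SD, PNFA, PSP, DLB) with AD as the positive and CN as the negative
class, but every function works for any `CategorySet`.

# The partial-credit scoring rule

The predicted label is the category with the highest assigned probability.
Human readers genuinely record exact ties; discarding them (by first-index
or random tie-breaking) either inflates or deflates measured performance.
Instead, `assignCredit()` gives each of the k tied top categories credit
1/k, and a case scores `credit[truth]`: 1 when uniquely correct, 1/k when
the truth is among the tied leaders, 0 otherwise. Aggregating credit
vectors by true label yields the fractional confusion matrix; row sums
remain exactly the class sizes, so no case mass is created or lost.

Two numerical decisions deserve note:

* **What counts as a tie.** Default: equality within an additive tolerance
  of 1e-9 — effectively exact equality for recorded scores, while never
  merging genuinely distinct floating-point model outputs. A
  reported-precision mode (`digits =`) rounds before comparison, for data
  recorded at, say, one-decimal percentages where 33.3 vs 33.3 is a true
  tie. Tolerance and rounding are the caller's statement about how the
  scores were produced, not tuning knobs.
* **Binary collapse.** Sensitivity is the credit mass on (AD, AD) divided
  by n_AD — so a CN/AD tie on a true AD case contributes 1/2, and mass a
  rater puts on any non-CN/AD category contributes 0 to all three binary
  proportions. A multi-class system is thereby required to beat not only
  CN but the whole differential.

Confidence intervals use the Wilson score form with the fractional success
count substituted directly. Wilson was chosen over Wald for its small-n
behaviour (the motivating design has n = 38); a Wald variant is also
reported since symmetric printed intervals are common in the literature,
and the two can disagree visibly at these sample sizes. Weighted F1 is
computed over the truth classes (CN, AD) with all predicted columns in the
precision denominators; a full multi-class F1 would be vacuous when truth
spans only two classes.

`tieAwareKappa()` generalizes Cohen's κ to credit vectors: observed
agreement is the mean per-case dot product, expected agreement the dot
product of mean credit profiles. With hard labels it reduces exactly to
the classical contingency-table κ (a property the test suite asserts);
truth-vs-rater and rater-vs-rater κ are the same operation with truth
encoded as unit vectors. When both observers are degenerate on the same
single category, p_e = 1 and κ is reported as `NA` with a reason rather
than silently dropped — the convention for every undefined statistic in
the package.

# Agreement statistics

Pearson and Spearman correlations of the continuous AD probabilities are
both always computed (they answer different robustness questions and small
reader studies rarely settle normality); Spearman is implemented exactly as
Pearson on mid-ranks with the t approximation for p, so the documented
identity `spearman = pearson ∘ rank` holds on every input including ties.

The intraclass correlation uses the single-measure absolute-agreement
two-way form,

ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + k·(MSC − MSE)/n),

computed from the mean squares of the subjects × raters decomposition.
"Consistency" ICC(3,1) and absolute agreement are often conflated in
applied reports; we implement the absolute-agreement quantity because
systematic calibration offsets between an automated model and a human
reader are precisely what such comparisons must detect. Negative values
are legitimate (between-rater disagreement exceeding between-subject
spread) and are returned as-is.

Bland–Altman limits are mean ± 1.96·SD of the paired differences
(sample SD, n−1); the per-case (mean, difference) pairs are exported for
plotting rather than plotted by the package. Levene's test is the one-way
ANOVA on absolute deviations from the group mean (the classical form;
`center = "median"` gives Brown–Forsythe).

# Discrimination

ROC analysis treats the AD probability as a continuous ranking score with
the "positive iff score ≥ t" convention — stated explicitly because
tie-heavy human scores make the convention visible as diagonal curve
segments. The AUC is the Mann–Whitney probability with half credit for
ties, computed via mid-ranks; it equals exhaustive pair counting and the
trapezoidal area under the empirical curve to machine precision.

Bootstrap CIs resample subjects with replacement *within* each truth class
(stratified), so no replicate can lose a class, and take the percentile
interval; BCa was rejected as needless complexity for a 38-case design
where the percentile interval is already the common practice. 2,000
replicates is the default. Percentile intervals are not guaranteed to
contain the point estimate and the package does not pretend otherwise.

`delongTest()` implements the placement-value form: each positive case's
placement is the fraction of negatives it outranks (ties half), the
variance of the AUC difference combines the empirical covariance matrices
of the paired placement vectors from both classes. Identical score vectors
give zero variance and an explicitly undefined p. The test suite checks
the implementation against an independent ROC package, verifies its type-I
error in [0.035, 0.065] under equal true AUCs at n = 50/50 with 2,000
replicates, and compares its SE against a 2,000-resample paired bootstrap.
The three pairwise comparisons of a three-observer study are reported
unadjusted, the norm for exploratory reader studies; users needing
familywise control can apply `p.adjust` to the reported p-values.

## Power for paired AUCs

`detectableAucDifference()` answers the planning question "what AUC gap
can n_pos/n_neg paired cases detect?". The analytic mode uses the
exponential-approximation variance
V(A) = [A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)]/(n₊n₋),
Q₁ = A/(2−A), Q₂ = 2A²/(1+A), evaluated at a stated `baselineAuc`
(default 0.80), with Var(Δ) = 2V(1−r) for between-observer correlation r.
At the default design (18/20, r = 0.5, α = 0.05, power 0.80) this yields
0.207 ≈ 0.21. The variance model behind published one-line power
statements is rarely reported, so the baseline AUC is an explicit,
documented argument rather than a hidden constant, and a simulation mode
(paired binormal observers, DeLong test per replicate, bisection on the
gap with common random numbers) provides an assumption-light cross-check;
the two agree within ±0.02 at the default spec.

# Calibration and clinical utility

The Brier score is computed on the AD channel against the binary outcome
(the multiclass Brier is out of scope while truth spans two classes).
Calibration curves default to 5 equal-width bins: with ~38 cases,
quantile bins put ~8 cases per bin at 5 bins either way, but equal-width
bins keep interpretable edges; both strategies are available and the bin
count is a parameter. Bins are half-open [lo, hi) with the last closed,
so counts always conserve N.

Decision curve analysis reports net benefit
NB(p_t) = TP/N − (FP/N)·p_t/(1−p_t) per observer on a default grid of
0.01 steps over [0.05, 0.95], against treat-all
(prevalence − (1−prevalence)·p_t/(1−p_t), which crosses zero exactly at
the prevalence) and treat-none (identically zero), plus a per-observer
flag for positivity across the clinically quoted [0.1, 0.9] range. The
positivity convention matches the ROC convention (≥ p_t) for internal
consistency.

# The study simulator

Because per-case scores from real reader studies are rarely shareable, the
generator produces complete studies with *known* population operating
characteristics:

* subject latent severity s ~ N(0,1) for CN, N(d,1) for AD;
* observer o perceives u = λ_o·s + √(1−λ_o²)·ε, so two observers' perceived
  scores correlate as λ_o·λ_o′ — a single shared latent dimension, the
  simplest mechanism that produces the low-but-structured inter-observer
  agreement real studies show;
* AD probability p = plogis(a_o + b_o·u); the slope/intercept are the
  observer's calibration and are deliberately decoupled from its
  discrimination (λ): an observer can rank well and still be badly
  calibrated, which is exactly the dissociation the framework is built to
  expose;
* residual mass 1−p splits between CN and a fixed per-observer leakage
  profile over the remaining categories — leakage weights are constant
  fractions of the non-AD mass, a marginal-tendency model chosen because
  observed error profiles describe *where* alternative assignments go, not
  a severity-dependent mechanism;
* with probability τ the two leading categories are replaced by their
  mean (an exact tie); vectors are then rounded to the recorded precision
  and renormalized. Exact ties arise only from the tie event or rounding,
  never from floating-point coincidence.

For a tie-free observer the AD probability is a monotone transform of u,
so the population AUC is Φ(λ_o·d/√2) (`expectedAuc()`), which gives the
generator a closed-form anchor: parameter-recovery tests simulate 50
replicates of n = 1,000/1,000 and require the empirical mean AUC within
±0.01 of the closed form.

The shipped `reference` preset (18 AD / 20 CN, three observers) back-solves
λ from target AUCs 0.90 / 0.71 / 0.62 at d = √2·Φ⁻¹(0.90) ≈ 1.81: an
automated "model" observer (λ = 1, leakage 0.45 of residual mass with DLB
dominant, no tie events, calibrated so its mean AD probability in true AD
cases sits near 42% and mean CN probability in true CN cases near 47%) and
two human observers (λ ≈ 0.43 / 0.24, tie propensities 0.15 / 0.2,
near-zero leakage, milder links). These are statements of the emulated
study conditions, fixed once; the preset makes no attempt to reproduce any
specific study's per-case numbers, only population-level characteristics.

Two honest caveats. First, tie events and rounding perturb the ranking, so
observers with τ > 0 realize AUCs slightly *below* their tie-free
expectation (about 0.02–0.03 at τ = 0.15–0.2) — the closed form is exact
only for tie-free configurations, and the recovery tests use those.
Second, the generator emulates the statistical structure the analysis
assumes (latent unidimensional severity, logistic links, fixed leakage); a
green test suite shows the *analysis* is correct under those conditions,
not that real radiologists behave this way. Features of real data the
generator does not emulate include case-difficulty heterogeneity beyond
one dimension, reader drift over a session, and correlation between tie
propensity and difficulty.

Randomness: one master seed; the latent severities and each observer draw
from deterministic substreams (`seed + j·1299721 mod 2³¹−1`), so adding or
removing an observer never perturbs the others' draws. All seeded
functions restore the caller's RNG state.

# Orchestration and reporting

`runEvaluation()` executes scoring → agreement → discrimination → DeLong →
calibration/decision curves → power in a fixed order and assembles a
`MetricReport`. Reports serialize to JSON with full precision and stable
key order, making a seeded run byte-identical — a cheap, strong
reproducibility check that the test suite enforces end to end. Every
statistic that can be undefined (constant scores, zero variance,
degenerate κ) is serialized as `null` plus a machine-readable reason.

Problem sizes used by the validation suite — 500 random AUC instances at
n ≤ 12, 200 random tables at N ≤ 20, 100 ICC matrices, 2,000-replicate
DeLong size and bootstrap-SE checks, 10,000-replicate Wilson coverage, 50
generator-recovery replicates at n = 1,000/1,000 — were chosen so each
oracle comparison has enough resolution to detect a real defect at its
stated tolerance while the whole suite stays comfortably runnable on a
laptop.

# Known limitations

* Truth is binary by design; metrics over a multi-class truth would need
  different F1/κ conventions and are not provided.
* The ICC is the single-measure absolute-agreement form only; no
  hierarchical or repeated-measures variants.
* Percentile bootstrap only (no BCa); DeLong p-values are unadjusted by
  default.
* The generator's single latent factor cannot represent observers who
  disagree because they attend to different image features; its
  between-observer correlation is always non-negative.
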