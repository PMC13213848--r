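# raterDx

Tie-aware evaluation of probabilistic multi-class diagnostic raters.

## The problem

In reader studies of dementia neuroimaging, an automated MRI classifier and
human radiologists each assign a **probability vector** over several
diagnostic categories — here the seven-way differential CN, AD, bvFTD, SD,
PNFA, PSP, DLB (cognitively normal, Alzheimer's disease, behavioural-variant
frontotemporal dementia, semantic dementia, progressive nonfluent aphasia,
progressive supranuclear palsy, dementia with Lewy bodies) — to every
subject, while ground truth is a binary CN/AD label. Comparing such
observers fairly is subtle:

* human readers often record **exact ties** between their top categories,
  which forced-choice scoring throws away;
* an automated multi-class system spreads probability across the whole
  differential, so mass leaking to, say, DLB must count against its binary
  CN/AD performance;
* categorical accuracy, continuous-score agreement, ranking (ROC/AUC),
  calibration and clinical utility answer *different* questions and must be
  reported side by side.

raterDx implements this complete evaluation framework, plus a
latent-severity simulator of whole studies with known operating
characteristics for validating every stage.

## The statistics at its core

**Partial-credit decision rule.** The predicted label is the category with
the highest assigned probability. If the true category is uniquely maximal
the case scores 1; if k categories tie for the maximum and the truth is
among them it scores 1/k; otherwise 0. Tabulating per-case credit vectors
by true label gives a **fractional confusion matrix** whose rows still sum
to the class sizes. Accuracy, sensitivity and specificity are credit
proportions with **Wilson** score intervals (fractional successes
substituted directly); weighted F1 and a **tie-aware Cohen's κ**

κ = (p_o − p_e) / (1 − p_e),  p_o = mean per-case dot product of credit
vectors,  p_e = dot product of mean credit profiles

reduce exactly to their classical forms when no case is tied.

**Agreement.** Pearson r and Spearman ρ (mid-ranks) of the continuous AD
probabilities, the single-measure absolute-agreement intraclass correlation
ICC(A,1) from two-way mean squares, Bland–Altman limits of agreement
(mean difference ± 1.96 SD), and Levene's test for equal variances.

**Discrimination.** Empirical ROC curves on the continuous AD probability,
the Mann–Whitney AUC (half credit for ties), stratified percentile
bootstrap CIs (2,000 replicates by default), and **DeLong's test** for two
correlated AUCs via placement-value covariances. A planning tool returns
the minimal detectable AUC difference for a paired design,
Δ = (z₁₋α/₂ + z_power)·√(2V(A)(1−r)), with V(A) the
exponential-approximation AUC variance.

**Calibration and utility.** Brier score, binned calibration curves, and
decision curve analysis: net benefit NB(p_t) = TP/N − (FP/N)·p_t/(1−p_t)
against treat-all and treat-none strategies.

**Simulator.** Each subject has a latent severity (N(0,1) for CN, N(d,1)
for AD); observer o perceives u = λ_o·s + √(1−λ_o²)·ε and maps it through a
logistic link to an AD probability, with configurable leakage of residual
mass across the differential, exact-tie propensity and recording precision.
A tie-free observer has closed-form AUC Φ(λ_o·d/√2), which anchors
parameter-recovery tests.

## Worked example

```r
library(raterDx)
study <- generateStudy(referenceConfig(), seed = 7)
study
#> AssessmentTable: 38 subjects x 3 raters x 7 categories
#>   categories: CN, AD, BVFTD, SD, PNFA, PSP, DLB
#>   raters: model, radiologist1, radiologist2
#>   truth: 18 AD / 20 CN

report <- runEvaluation(study, nBoot = 2000, seed = 7, verbose = FALSE)
report
#> MetricReport (raterDx 0.99.0)
#>   raters: model, radiologist1, radiologist2
#>   model          acc 0.68  sens 0.44  spec 0.90  AUC 0.799  Brier 0.237
#>   radiologist1   acc 0.59  sens 0.47  spec 0.70  AUC 0.588  Brier 0.260
#>   radiologist2   acc 0.58  sens 0.39  spec 0.75  AUC 0.600  Brier 0.254
#>   pairwise blocks: 3 agreement, 3 DeLong
```

The 38-subject study (18 AD / 20 CN) is simulated from the shipped
`reference` preset: a high-discrimination automated observer whose residual
mass leaks mostly toward DLB, and two noisier human observers whose mass
concentrates on CN/AD with occasional exact ties. Per-rater accuracy /
sensitivity / specificity are partial-credit proportions; AUC is the
Mann–Whitney area on the continuous AD probability; Brier measures
calibration (0 is perfect). Drilling in:

```r
cl <- reportData(report)$classification$model
sprintf("model accuracy %.2f (95%% CI %.2f-%.2f)",
        cl$accuracy$estimate, cl$accuracy$lower, cl$accuracy$upper)
#> "model accuracy 0.68 (95% CI 0.53-0.81)"

dl <- reportData(report)$delong$model_vs_radiologist1
sprintf("DeLong model vs radiologist1: delta %.3f, p = %.4f", dl$delta, dl$p)
#> "DeLong model vs radiologist1: delta 0.211, p = 0.0332"

runPower(18, 20)   # paired-AUC design sensitivity at this sample size
#> Correlated-AUC power analysis (analytic mode)
#>   n = 18 positive / 20 negative, r = 0.50, alpha = 0.050, power = 0.80, baseline AUC = 0.80
#>   minimal detectable AUC difference: 0.207
```

`writeReport(report, "report.json")` serializes everything (byte-identical
under a fixed seed); `exportReportTables(report, "tables/")` writes the
confusion matrices, ROC points, calibration, Bland–Altman and decision
curves as CSV. A thin command-line front end with `simulate`, `evaluate`,
`compare` and `power` subcommands lives at `inst/scripts/raterDx.R`.

## File formats

* Assessment CSV (long format, one row per subject-rater pair):
  `subject_id,rater_id,CN,AD,BVFTD,SD,PNFA,PSP,DLB`; percent or fraction
  scale is declared, never guessed. Example:
  `inst/extdata/example_assessments.csv`.
* Truth CSV: `subject_id,truth`. Example: `inst/extdata/example_truth.csv`.
* Report: JSON with stable key order; undefined statistics are `null` with
  a `reason`. Generator preset: `inst/extdata/reference_config.json`.

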