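# rwemulate

Target-trial emulation for oncology cohorts, with a built-in audit of when
the emulation can be trusted.

Randomized phase 3 trials tell us whether a treatment works *on average* in a
selected population; observational EHR cohorts contain the patients those
trials never enrolled. `rwemulate` is for biostatisticians and
pharmaco-epidemiologists who want to (i) reconstruct a trial inside an
observational cohort — eligibility rules, arms, time zero at the start of the
qualifying therapy — and estimate its treatment effect with inverse
probability of treatment weighting, (ii) stratify that effect by
machine-learned prognostic phenotype, and (iii) *quantify*, by simulation on
data with known ground truth, how badly the estimates break when the
positivity or no-unmeasured-confounder assumptions fail.

Because real oncology EHR databases are proprietary, the package ships a
synthetic-cohort generator that emulates their structure (longitudinal labs
with observation dates, 30–50% missingness in ECOG and labs at diagnosis,
confounded treatment assignment, right-censored survival) with the generating
model fully known — every estimator in the package is validated against that
ground truth.

## The statistics at the core

**Prognostic phenotyping.** Survival models (gradient-boosted Cox-loss
ensemble, random survival forest, linear survival SVM, penalized and
unpenalized Cox) are tuned by grid search + five-fold CV to maximize the
cumulative/dynamic time-dependent AUC at a clinical horizon,

```
AUC(t) = Σᵢ Σⱼ I(yⱼ > t) I(yᵢ ≤ t) ωᵢ I(f̂(xⱼ) ≤ f̂(xᵢ))
         ─────────────────────────────────────────────────
         ( Σⱼ I(yⱼ > t) ) ( Σᵢ I(yᵢ ≤ t) ωᵢ )
```

with inverse-probability-of-censoring weights `ωᵢ = 1/Ĝ(yᵢ⁻)` from the
censoring Kaplan–Meier `Ĝ`. Risk-score tertiles define low/medium/high-risk
phenotypes.

**Emulation.** Within the trial-eligible cohort, a logistic propensity model
gives `eᵢ = Pr(Zᵢ = 1 | Xᵢ)` and weights `ωᵢ = Zᵢ/eᵢ + (1−Zᵢ)/(1−eᵢ)`
(no trimming). Balance is checked by standardized mean differences (target
< 20%); weighted Kaplan–Meier curves yield median OS, RMST at the
benchmark-implied horizon (benchmark median + 12 months) and survival
probabilities, with 1,000-replicate percentile bootstrap CIs re-estimating
the propensity inside every replicate; the hazard ratio comes from a
weighted Cox model with Huber sandwich standard errors and is compared with
the RCT benchmark by three agreement rules (direction concordance, CI
overlap, standardized log-HR difference < 1.96).

**The audit.** A two-step semi-synthetic DGP (logistic treatment model + Cox
outcome model with exponential survival times, baseline rate calibrated to
the base cohort's event fraction) generates replicate datasets under four
regimes: assumptions hold; 30% or 40% of patients structurally denied
treatment (propensity forced to 0); or two confounders hidden from the
analysis. Relative bias and 95% CI coverage of the weighted-Cox HR are
reported per regime, sample size and phenotype.

## Worked example

```r
library(rwemulate)

cohort <- generate_cohort(cohort_config(n_patients = 4000, seed = 5))
#> <rwe_cohort> aNSCLC-like n = 4000 (53% treated, 87% events)

trial <- read_trial_spec(system.file("extdata", "trial_synthetic_io.yaml",
                                     package = "rwemulate"))
result <- emulate_trial(cohort, trial, reps = 500, seed = 42)
#> <rwe_emulation> SYNTH-IO-01 [key eligibility] n = 1530
#>   HR 0.602 (0.524-0.691), robust SE 0.070
#>   agreement: significance = TRUE | CI overlap = TRUE | standardized difference = TRUE
#>   low    rmst diff 3.73 months (mOS 20.3 vs 10.4)
#>   medium rmst diff 4.64 months (mOS 19.9 vs 9.33)
#>   high   rmst diff 2.52 months (mOS 13.1 vs  8.8)
```

Reading this: 1,530 of 4,000 synthetic patients meet the key eligibility
rules (first-line therapy, biomarker-positive within 30 days of treatment
start). After weighting, the emulated hazard ratio 0.60 (95% CI 0.52–0.69)
agrees with the trial benchmark (HR 0.70, 0.58–0.85) on all three rules, and
the per-phenotype rows give each tertile's restricted-mean survival benefit
in months with the per-arm weighted-KM medians beside them.

Auditing the estimator on the same cohort's fitted DGP:

```r
dgp <- fit_dgp(cohort)
audit <- run_cases(dgp, cases = 1, sizes = 2000, reps = 200, seed = 7)
#>   case    n stratum mean_hr true_hr rel_bias_pct coverage_pct
#> 1    1 2000    full   0.618   0.617        0.120         96.0
#> 2    1 2000     low   0.613   0.617       -0.650         93.0
#> 3    1 2000  medium   0.620   0.617        0.480         95.5
#> 4    1 2000    high   0.618   0.617        0.166         94.0
```

When both assumptions hold (case 1), the weighted Cox HR is essentially
unbiased and its 95% CI covers the truth at the nominal rate in every
phenotype. Running `cases = 2:4` shows the signature of violated
assumptions: stable bias with coverage that *worsens* as n grows.

A thin CLI wrapping these functions lives at `inst/cli/rwemulate.R`
(subcommands `fixtures`, `train`, `emulate`, `simulate-audit`, `report`).

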