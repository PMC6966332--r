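# markerscan

Multifactorial ranking of continuous tumor biomarkers by their impact on
time-to-event outcomes, built for chemo-radiotherapy cohorts in advanced
HPV-negative head and neck squamous cell carcinoma (HNSCC) — and usable for
any cohort in which a panel of continuous scores must be compared against
several survival endpoints under clinical covariate adjustment.

The package is aimed at biostatisticians and translational researchers who
have (a) a gene × sample expression matrix plus gene-set definitions, or
(b) any per-patient table of continuous marker scores, together with
time/event columns for locoregional control (LRC), distant metastasis (DM),
overall survival (OS) and progression-free survival (PFS).

## What it computes

For each marker *m* and endpoint *E* with clinical adjustment set *Z*:

1. **Robust dichotomization cutoff.** For every admissible cutoff *c*
   (midpoints of distinct observed values leaving ≥ 10% of patients per
   side), and for each of *B* bootstrap resamples of the cohort (default
   *B* = 10000), fit the Cox proportional-hazards model

   *h(t | x) = h₀(t) · exp(β·1[m > c] + γᵀZ)*

   and record whether the marker term has Wald *p* < 0.05. The per-cutoff
   fraction of significant resamples is smoothed with a 9-point moving
   average; the argmax is the selected cutoff.
2. **Final multivariable fit** at the selected cutoff on the original
   cohort (low group = reference): HR = exp(β̂) with 95% Wald CI.
3. **Backward selection by AIC** over all dichotomized markers plus
   clinical covariates, removing one variable at a time while the AIC
   (−2 log PL + 2k) improves.
4. **Cutoff-averaged HR profiles**: the marker's multivariable HR at every
   admissible cutoff and its mean — a cutoff-independent effect summary
   compared across endpoints in a spider table.

The partial likelihood uses Efron's tie correction, maximized by a compiled
Newton–Raphson with step-halving (score sup-norm < 1e-7); separated fits
are flagged, never silently reported. A Gaussian-copula synthetic cohort
generator with known ground truth (correlated marker scores, Table-style
clinical marginals, exponential proportional-hazards event times with
death-censoring of LRC/DM and derived PFS) backs the entire test suite.

## Worked example

```r
library(markerscan)

cfg    <- sim_config(n_patients = 197, seed = 42)   # default 12-marker panel
cohort <- simulate_cohort(cfg)

scan <- bootstrap_scan(cohort, "chronic_hypoxia", "LRC", B = 500, seed = 42)
scan
#> <cutoff_scan> chronic_hypoxia on LRC: 158 cutoffs, B = 500
#>   selected cutoff -0.1701 (smoothed fraction 0.924)

fit <- final_fit(cohort, "chronic_hypoxia", scan$selected_cutoff, "LRC")
fit
#> <cox_fit> n = 197, events = 39, AIC = 343.57
#>                       term    hr conf.low conf.high p.value
#>  chronic_hypoxia_grouphigh 3.107   1.5325      6.30 0.00167
#>                  sexFemale 0.205   0.0626      0.67 0.00873
#>              cisplatin<200 2.735   1.4377      5.20 0.00216

hr_across_cutoffs(cohort, "chronic_hypoxia", "LRC")
#> <hr_profile> chronic_hypoxia on LRC: mean HR 2.503 over 158 cutoffs (0 failed)
```

Reading the output: the scan found the chronic-hypoxia score dichotomization
most robustly associated with locoregional failure at −0.17 (92% of
bootstrap cohorts significant after smoothing, with the cohort simulated at
a true HR of 3.9 switching on at the median score of 0). At that cutoff the
high-hypoxia group carries a 3.1-fold locoregional failure hazard (95% CI
1.5–6.3) after adjusting for sex and cumulative cisplatin dose, and the
cutoff-averaged HR of 2.5 summarizes the association over all admissible
cutoffs. `tidy()`, `glance()` and `autoplot()` methods give tibble and
ggplot views of every result type; `run_full_analysis(run_config(...))`
chains all stages for a whole marker panel and writes TSV/JSON artifacts.

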