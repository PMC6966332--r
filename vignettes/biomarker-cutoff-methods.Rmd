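---
title: "Bootstrap cutoff selection and multifactorial survival analysis of tumor biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap cutoff selection and multifactorial survival analysis of tumor biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerscan)
```

## The problem

In advanced head and neck squamous cell carcinoma (HNSCC) treated with
definitive cisplatin-based chemo-radiotherapy, a collection of tumor-biology
scores — chronic and acute hypoxia signatures, stem-cell related gene
expression (CD44, SLC3A2), EGFR, proliferation, immune-cell infiltration
(TIS, CD8, NK cells, CD8/Treg), EMT and DNA crosslink-repair defect
scores — each carry prognostic information, but they are usually studied one
at a time, on different cohorts, with ad hoc dichotomization cutoffs. The
question this package operationalizes is *multifactorial*: which of these
largely independent biological axes actually determine locoregional control
(the radiotherapy-response proxy), and which instead drive distant
metastasis or overall survival, once the relevant clinical covariates are
adjusted for?

`markerscan` implements that analysis pipeline as reusable, tested
components:

1. per-sample signature scoring from an expression matrix,
2. endpoint construction for LRC / DM / OS / PFS with death-censoring
   semantics,
3. a fast Efron-tie Cox proportional-hazards engine,
4. bootstrap-based robust dichotomization cutoff selection,
5. backward model selection by AIC over all markers and clinical
   variables, and
6. cutoff-averaged hazard-ratio profiles for cutoff-independent marker
   ranking,

together with a synthetic cohort generator that emulates the statistical
structure of such a cohort so that every stage can be validated against
known ground truth.

## Endpoints and censoring

Times run from the first day of treatment. Locoregional control (LRC)
events are recurrences in the irradiated head-and-neck region; distant
metastasis (DM) events are recurrences outside it. A death occurring before
a possible event *censors* LRC and DM at the death date — death is not an
LRC/DM event. Overall survival (OS) is death from any cause.
Progression-free survival (PFS) is the time to the first of death,
locoregional recurrence or distant metastasis; consequently, for every
patient `time_PFS <= min(time_LRC, time_DM, time_OS)`, an invariant the
tests assert row-wise. `build_endpoints()` applies these rules to raw
per-patient date records.

Each endpoint carries its own clinical adjustment set (the covariates
significantly associated with that outcome in the motivating cohort),
frozen into `default_endpoint_specs()`: sex and cumulative cisplatin dose
for LRC; sex, subsite and cisplatin for OS; stage, subsite and cisplatin
for PFS; sex and alcohol use for DM. Per-run univariable re-screening was
deliberately not made the default: frozen sets keep scans comparable across
markers and reruns.

## The Cox engine

All model fitting goes through a single compiled Newton–Raphson maximizer
of the partial likelihood with Efron's tie correction (Breslow available by
flag for cross-checks; Efron is the better approximation and the de facto
default in survival software). Numerical choices:

* convergence when the score vector's sup-norm falls below `1e-7`
  (at most 100 iterations, step-halving when a step would decrease the
  likelihood);
* covariate columns are mean-centered internally (estimates unaffected,
  exponentials stay in range);
* a coefficient escaping ±15 flags the fit as non-converged (separation)
  instead of silently returning a huge estimate — bootstrap resamples with
  separated groups are counted as *failed fits*, never as significant ones;
* categorical terms use the most frequent level as the reference, except a
  dichotomized marker group, whose reference is always the "low" group;
* rows with missing values in the active columns are dropped per fit
  (complete-case) and counted — no imputation;
* confidence intervals are Wald intervals from the observed information at
  the fixed 95% level, `AIC = -2 log PL + 2k` with `k` the number of
  estimated coefficients.

The test suite holds this engine to `survival::coxph()` at machine
precision on random tied data, and to a pure-R brute-force grid
maximization of the Efron partial likelihood (the grid search exploits the
likelihood's concavity: a full 0.01-step sweep over [-5, 5] followed by an
exact 1e-4-step refinement around the coarse argmax).

## Bootstrap cutoff selection

For one marker and one endpoint, `bootstrap_scan()`:

1. forms the candidate grid: midpoints between consecutive distinct
   observed marker values — midpoints rather than observed values avoid
   ambiguity about which side a boundary patient falls on;
2. discards cutoffs leaving fewer than 10% of patients
   (`ceiling(0.10 n)`) on either side, to maintain statistical power;
3. draws `B` patient-level bootstrap resamples (with replacement, size
   `n`, uniform weights — by default `B = 10000`); every candidate cutoff
   is evaluated against the *same* `B` resampled cohorts;
4. for each resample and cutoff, fits the multivariable Cox model of the
   dichotomized marker plus the endpoint's clinical covariates and records
   whether the marker term has Wald `p < 0.05`;
5. reports per cutoff the fraction of valid fits that were significant
   (failed fits are removed from the denominator and tallied separately,
   so `significant + non-significant + failed = B` always);
6. smooths the fraction curve with a 9-point centered moving average and
   selects the cutoff with the highest smoothed fraction.

Choices the procedure's verbal description leaves open, fixed here:

* the minimum-group-size rule is applied on the **full cohort** grid;
  resamples where a group comes out empty count as failed fits;
* near the edges the smoothing window **truncates** to the available
  neighbors — reflecting or padding would invent data;
* argmax ties are broken toward the cutoff nearest the cohort's median
  marker value (then by position), which is deterministic and favors
  balanced splits;
* resampling is plain nonparametric bootstrap of patients, unstratified.

`final_fit()` then refits the model on the original (non-resampled) cohort
at the chosen cutoff, low group as reference — the hazard ratios and
p-values one would report per marker and endpoint.

**A caution that is part of the method's honest description:** selecting
the cutoff that maximizes bootstrap significance and then testing *at that
cutoff on the same cohort* is post-selection inference. Under a null
marker the final-fit test rejects clearly more often than 5%; the
acceptance suite asserts this anti-conservatism as a property rather than
hiding it. Selected cutoffs are exploratory and need external validation;
no correction is applied, matching the procedure being reproduced.

## Backward selection by AIC

`backward_aic()` starts from the full Cox model over all dichotomized
markers and clinical covariates and repeatedly removes the single variable
whose removal most lowers the AIC, while any removal lowers it.
Categorical variables leave as whole blocks (all contrasts together). The
complete-case sample is fixed once from the full variable set so AICs are
comparable across nested models; candidates are scanned in alphabetical
order with ties broken by AIC and then name, so the trace is invariant to
input order; removal may continue down to the empty model, whose AIC is
`-2 log PL(0)`. Greedy descent can in principle miss the all-subsets
optimum; on simulated strong-signal cohorts the tests require agreement
with exhaustive search in at least 80% of runs (observed agreement is
higher).

## Cutoff-averaged hazard-ratio profiles

Because optimal cutoffs differ between endpoints, markers are also compared
cutoff-independently: `hr_across_cutoffs()` records the marker's
multivariable HR at *every* admissible cutoff and averages them — the area
under the HR-versus-cutoff-rank curve normalized by its width, i.e. the
unweighted arithmetic mean over the grid. Averaging ratios on the raw scale
is asymmetric (values below 1 are bounded by 0), so a geometric-mean option
(`scale = "log"`) is provided; the default stays arithmetic for fidelity to
the procedure being reproduced. Failed fits are excluded and counted.
`spider_table()` assembles the two-endpoint comparison (typically LRC vs
DM) behind a radial plot.

## Signature scoring

Three scorer families cover the twelve default markers:

* **single-gene** scores (CD44, SLC3A2, EGFR) are TPM rows;
  `counts_to_tpm()` normalizes counts by gene length and scales each
  sample to one million (conservation asserted to 1e-6 relative);
* **rank-set** scores: within each sample, genes are rank-transformed
  (average ranks on ties, the same convention as the Spearman correlations
  used throughout), ranks standardized to mean 0 / sd 1, and the score is
  the mean standardized rank over the up-genes minus the mean over the
  down-genes;
* **set-ratio** scores (CD8/Treg) are the difference of two standardized
  rank-set scores — numerically stable where a literal quotient would
  divide by near-zero standardized values; a quotient on strictly positive
  scores is available by flag.

The rank-z set score is a deliberate, exactly testable substitute for
kernel-density single-sample enrichment scores (GSVA/ssGSEA): it preserves
the per-sample ordering those methods target, is bit-identical under any
strictly monotone per-sample transform (so raw counts vs TPM is
immaterial), and has no hidden smoothing parameters. It does **not**
reproduce GSVA's numeric values, and classifier-specific protocols from the
original signature publications (e.g. nearest-centroid hypoxia
classification) are out of scope: all gene sets go through the generic
scorers, and published gene lists ship only as user-supplied fixtures.
Genes missing from the matrix are dropped with a warning when less than
half the set is absent, and are an error otherwise.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure the
analysis assumes — not recurrence biology:

* **Marker scores** come from a Gaussian copula: target Spearman
  correlations are converted to Pearson correlations with
  `2 sin(pi r / 6)`, repaired to the nearest positive semi-definite matrix
  by eigenvalue clipping at 1e-8 (configurations needing more than a 0.1
  entry change are rejected), and Cholesky-factored. Marginals are
  standard normal. The shipped targets are the cross-marker correlations
  reported for this disease setting: CD44–SLC3A2 0.57, acute hypoxia vs
  proliferation 0.58, vs TIS 0.51, vs CD8 0.54, acute vs chronic hypoxia
  0.26, EGFR–proliferation 0.26. Those acute-hypoxia entries alone would
  form an infeasible "star" (negative minimum eigenvalue, so the PSD
  repair would leave the scores near-collinear); the immune markers'
  mutual correlations — reported only qualitatively in such cohorts — are
  therefore filled in with values reproducing the pattern (TIS–CD8 0.65,
  TIS–NK 0.40, CD8–NK 0.35, proliferation 0.35 with TIS and CD8, CD8/Treg
  0.30 with CD8 and mildly negative with TIS and NK), which makes the
  target comfortably positive definite; its implied maximum variance
  inflation factor (~3.4) sits right at the value such cohorts report.
  All remaining pairs are 0. Calibration: at n = 5000 every empirical
  entry is within ±0.05 of its target.
* **Clinical covariates** are multinomial draws from the cohort's marginal
  frequencies (n = 197: sex 142/55, alcohol 146/22/22, tobacco 156/30/5,
  subsite 85/78/34, stage 135/40/20/2, cisplatin 126/67 over non-missing
  patients), independent of the marker scores — the motivating cohort
  showed no strong marker–clinical associations. Tumor volume is
  log-normal around the reported median of 23.2 cm³ (sdlog 1.1, matching
  the reported 1–750 cm³ range). Only marginals are emulated;
  cross-tabulations (e.g. sex × alcohol) are not.
* **Event times** are exponential proportional-hazards draws (a Weibull
  shape is exposed as an option; the exponential default keeps the
  events-per-person-time oracle closed-form). Marker effects switch on
  above a configured true quantile cutoff (or act linearly); clinical
  effects are level indicators. LRC and DM latent times compete with an
  independent background death time — death first censors them (no shared
  frailty; a documented simplification). PFS is derived as the minimum of
  the three, never drawn. Administrative censoring is exponential plus a
  hard 9-year horizon.
* **Default effect sizes** follow hazard ratios reported in this disease
  setting (chronic hypoxia 3.9 and acute hypoxia 1.9 on LRC; EMT 3.14 and
  acute hypoxia 2.44 on DM; cisplatin < 200 mg/m² 2.57 and female sex 0.52
  on LRC; moderate EMT / DNA-repair / EGFR-scale effects on OS), switching
  on at the median score. Baseline (reference-profile) rates were fixed
  once, at design time, so that the simulated cohort reproduces the
  motivating cohort's observed event rates under those effects — LRC
  ≈ 24%, DM ≈ 20%, about half the patients dying within follow-up:
  LRC 0.011/y, DM 0.015/y, death 0.04/y, censoring 0.10/y.
* **Reproducibility**: a single global seed feeds fixed per-operation
  streams (scores / clinical / event times / each scan), so any stage can
  be regenerated alone, bit-identically.
* `simulate_expression()` closes the loop for the scoring module: it
  plants per-sample log-mean shifts, monotone in a target score, on
  signature genes over a log-normal background, so rank-set scoring must
  recover the planted ordering (Spearman > 0.8 at the default amplitude
  of 2 on the log2 scale, a threshold fixed by a pilot run before the test
  was written).

What passing tests on these cohorts do **not** show: robustness to
informative censoring, marker–clinical dependence, non-proportional
hazards, RNA-seq read-level noise, or batch structure — none of which the
generator emulates.

## Problem sizes used by the shipped checks

The default demonstration and the validation suite run the full pipeline at
the cohort's own scale (n = 197, 12 markers, 4 endpoints) with `B = 200`
bootstrap cohorts per scan, and the recovery/calibration experiments at
n = 200 with `B` up to 500 over 25 seeds; these sizes keep a complete run
on a single CPU in the minutes range while leaving every assertion
well-powered. `B = 10000` — the default for real analyses — changes only
runtime, not code paths; the scan-stability check confirms selected
cutoffs move by at most a few percentile ranks between `B = 500` and
`B = 2000` under a strong effect.

## Known limitations

* Post-selection inference at the selected cutoff is anti-conservative
  (documented and asserted, not corrected — fidelity to the procedure).
* No multiple-testing correction anywhere, matching the reproduced
  analysis; correlation-report p-values are explicitly unadjusted.
* The rank-z set score is not GSVA; absolute score values are not
  comparable to published GSVA scores (orderings are).
* The generator draws clinical covariates independently of markers and of
  each other; real cohorts have cross-correlations.
* Time-varying covariates, stratified Cox, frailty models and
  proportionality diagnostics are out of scope.
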