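# alcslope

Radiation oncologists and biostatisticians studying cervical cancer treated
with concurrent chemoradiotherapy (CRT) face a confound: lymphopenia can
reflect tumour burden, treatment toxicity, or the patient's own
constitutional immune capacity. `alcslope` implements an analysis pipeline
around a simple kinetic biomarker that targets the third component: the
exponential slope of the absolute lymphocyte count (ALC) measured serially
*during* treatment.

Each patient's counts are fitted to

    ALC(t) = a1 · exp(−α t) + e1,      a1 ≥ 0,  e1 > 0

with `t` in days since the first radiotherapy fraction. `α` (1/day) is the
depletion rate; `e1` is the estimated nadir under continued irradiation;
`a2 = a1 + e1` estimates the pre-treatment count. `α` is profiled over a
dense grid on [0.01, 0.2] with an exact constrained least-squares solve at
each rate, and the lowest rate among the top-10 candidates fitting equally
well (R² within 1e-6) is selected — a deliberately conservative rule.

On top of the fit, the package provides:

- **Endpoints** separating *aggressive* (death before 30 months) from
  *non-aggressive* (death at or after 30 months) disease courses: DSS,
  DSS-A, DSS-NA and PFS, with explicit cause-specific censoring
  conventions.
- **Survival statistics**: Kaplan–Meier curves and horizon rates, two-group
  log-rank tests, Cox proportional-hazards models with AIC backward
  elimination, and baseline-table group comparisons (χ² / t-test /
  Wilcoxon with a Shapiro–Wilk gate).
- **An exosomal mRNA arm**: paired pre-treatment vs week-2 log2 fold
  changes after TMM normalization, a Pearson correlation screen against α,
  NLR and outcome, an exhaustive best-subset search maximizing adjusted
  R²/k, and signed composite scores tested by Wilcoxon rank-sum.
- **A synthetic cohort generator** with known ground truth (log-normal α,
  amplitude, nadir and NLR; piecewise-exponential survival in which slow
  depletion raises the early hazard and fast depletion the late hazard;
  negative-binomial paired counts with planted genes), so the entire
  pipeline is testable without patient data.

## Worked example

```r
library(alcslope)

sim <- simulate_cohort(sim_config(n_patients = 323, seed = 42))

# one patient's series and fit
series <- sim$cohort$alc[sim$cohort$alc$patient_id == "P0001", c("day", "alc")]
fit_alpha(series)
#> Lymphocyte decay fit: ALC(t) = a1*exp(-alpha*t) + e1
#>   alpha = 0.1545 /day   a1 = 1341   e1 = 5.067   a2 = 1346 cells/uL
#>   R^2 = 1 on 7 measurements

# the whole cohort
fits <- fit_cohort(sim$cohort)
fits
#> Cohort decay fits: 323 patients fitted
#>   alpha median [IQR]: 0.080 [0.058-0.113] /day
#>   a2 median: 1696 cells/uL   e1 median: 132 cells/uL

# aggressive/non-aggressive split and the stratified 2.5-year endpoint
clin <- sim$cohort$clinical
sp   <- split_dsd(clin, 30)
ep   <- build_endpoints(clin, sp$labels, "dss_a")
g    <- dichotomize(fits$table$alpha)$labels
lr   <- logrank_test(ep$time, ep$event, g)
km_at(km_estimate(ep$time[g == "high"], ep$event[g == "high"]), 30)  # 0.903
km_at(km_estimate(ep$time[g == "low"],  ep$event[g == "low"]),  30)  # 0.766
lr$p_value                                                           # 0.001
```

This patient's depletion rate (0.154/day, true value 0.161) sits in the
fast tail; the cohort median of 0.080/day with IQR [0.058–0.113] matches
the distribution the generator is anchored to. Of this cohort's 83 cancer
deaths, 53 occur before 30 months (aggressive) and 30 after. Patients with
above-median depletion rates have a *higher* 2.5-year aggressive-course
survival (90.3% vs 76.6%, log-rank p = 0.001) — slow depletion marks the
patients who die early, while fast depletion shifts risk to late deaths:
the directional reversal the two-endpoint design exists to detect.

The full pipeline (ingestion → fits → endpoints → survival tables →
exosome arm) runs from file inputs via `run_full(run_config(...))` or the
wrapper script `inst/scripts/run_pipeline.R`, writing a CSV report bundle
plus a run log with version, configuration hash and seed.

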