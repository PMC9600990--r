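---
title: "Lymphocyte depletion kinetics as a survival biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lymphocyte depletion kinetics as a survival biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcslope)
```

## The problem

Pelvic chemoradiotherapy depletes circulating lymphocytes, the most
radiosensitive blood cells. How fast a patient's absolute lymphocyte count
(ALC) falls during treatment — and where it plateaus — carries information
that pre-treatment markers such as the neutrophil-to-lymphocyte ratio (NLR)
do not: unstimulated (naive/memory) lymphocytes are markedly more
radiosensitive than stimulated ones, so the decay rate of the total count
reflects the composition of the circulating pool, a proxy for the patient's
constitutional immune capacity rather than for tumour burden.

`alcslope` estimates a per-patient decay rate from serial ALCs, uses it to
stratify survival endpoints that separate *aggressive* (early) from
*non-aggressive* (late) cancer deaths, and provides a companion arm that
relates paired exosomal mRNA fold changes to the decay rate and outcome.
A synthetic cohort generator with known ground truth makes every stage
testable without patient data.

## The decay model

Each patient's serial counts are fitted to

$$\mathrm{ALC}(t) = a_1 e^{-\alpha t} + e_1, \qquad a_1 \ge 0,\; e_1 > 0,$$

with $t$ in days since the first radiotherapy fraction. The three
parameters have direct clinical readings: $\alpha$ (1/day) is the depletion
rate — the biomarker; $e_1$ (cells/µL) is the plateau, the estimated nadir
under continued irradiation; and $a_2 = a_1 + e_1$ is the curve value at
$t = 0$, an estimate of the pre-treatment count. Typical cohort values are
$\alpha \approx 0.08$/day and $e_1 \approx 150$ cells/µL.

Fitting is deliberately simple and fully deterministic:

1. $\alpha$ is profiled over a dense grid on $[0.01, 0.2]$ (step
   $5\times10^{-4}$, 381 candidates). The bounds exclude decay too slow to
   distinguish from a flat series within an 8-week window and faster decay
   than total lymphoablation allows.
2. At each grid rate, $(a_1, e_1)$ solve a 2-parameter constrained least
   squares problem. The quadratic programme is solved exactly by active-set
   enumeration: the interior stationary point when feasible, otherwise the
   better of the two clamped edge solutions. Strict positivity of $e_1$ is
   made computable as $e_1 \ge$ `e1_floor` (1 cell/µL).
3. Candidates are ranked by $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (SST about
   the mean; negative values possible under the constraints are kept, so
   the ranking is always well defined). Among the `top_k = 10` best
   candidates, the **lowest** rate whose $R^2$ is within `tie_tol = 1e-6`
   of the best is selected.

The lowest-rate rule encodes a conservative bias: when several rates
explain the data equally well (series that plateau early, or contain few
informative early measurements), the slowest depletion compatible with the
data is reported. The tie tolerance is essential on a dense grid: without
it the ten best candidates straddle the optimum and the rule would sit
systematically ~5 grid steps low even for noiseless data. With it,
noiseless series generated at a grid rate are recovered exactly, while
genuinely flat profiles still resolve to the smallest rate among the
equally good candidates.

`fit_alpha()` returns a classed object with the usual modelling verbs:

```{r example-fit, eval = FALSE}
series <- data.frame(day = c(0, 7, 14, 21, 28, 42),
                     alc = c(1900, 1100, 640, 420, 320, 250))
f <- fit_alpha(series)
coef(f)          # alpha, a1, e1, a2
predict(f, 30)   # expected count at day 30
plot(f)          # data, fitted curve, plateau
```

## Derived clinical variables

* **Min-ALC** is the minimum count within 40 days of the start of
  radiotherapy (window closed at day 40), matching the five-week pelvic
  irradiation schedule plus slack; it is the observed counterpart of the
  fitted plateau.
* **Median imputation** is restricted to the pre-treatment ALC and NLR —
  the only fields such cohorts impute; missingness anywhere else is a
  validation failure. The even-count median is the midpoint of the two
  central order statistics.
* **Dichotomisation** labels values at or above the threshold `high`, so
  group labels read "≥ median" / "< median"; the threshold defaults to the
  sample median and accepts fixed constants (e.g. a rate of 0.08/day or an
  NLR of 2.43) for replicating a published stratification.

## Survival endpoints

Disease-specific deaths (DSD) are split at `split_months` (default 30; or
`"auto"` = the mean time-to-death among DSDs, which is what the 30-month
default represents empirically): deaths strictly before the threshold form
the *aggressive* class, deaths at or after it the *non-aggressive* class.
A death at exactly the threshold is non-aggressive.

Four endpoints are built per patient, all timed from the end of treatment:

| endpoint | event | censoring |
|---|---|---|
| DSS | any disease-specific death | survivors at last follow-up |
| DSS-A | aggressive death | non-aggressive deaths at their death time (default) or at the threshold; survivors at follow-up |
| DSS-NA | non-aggressive death | symmetric to DSS-A |
| PFS | first of progression or disease-specific death | survivors at follow-up |

Censoring deaths of the other class at their death time is the standard
cause-specific treatment of a competing event; the threshold variant is
exposed as a switch because either convention yields the same estimate at
the evaluation horizons in use (2.5 years for the aggressive endpoint,
8 years for the others). PFS uses the conventional first-event composite.

## Statistical machinery

Kaplan-Meier curves, two-group log-rank tests and Cox models ride on the
`survival` package; the backward elimination wrapped around `coxph` is
AIC-driven — starting from the full model, the term whose removal most
decreases AIC is dropped until no removal decreases it, with
collinearity-aliased terms removed up front — because reported model
selection in this setting is AIC-based. Hazard ratios carry 95% Wald
intervals and Efron tie handling (follow-up is month-resolved, so ties are
real). Baseline-table comparisons use the uncorrected chi-square test for
categorical variables (a continuity-correction flag exists) and, for
continuous variables, a Shapiro-Wilk gate at 0.05 per group routing to the
t-test or the Wilcoxon rank-sum test.

## The exosomal mRNA arm

Starting from a genes × samples read-count matrix with one pre-treatment
(control) and one week-2 (treatment) sample per patient:

1. genes undetected in more than half of all samples are removed (a gene
   detected in exactly half is kept);
2. TMM scaling factors are computed (30% trim on log-ratios, 5% on
   abundance, precision weighting, factors multiplying to one) via
   `edgeR`;
3. per patient and gene, `log2((treatment CPM + 0.5) / (control CPM + 0.5))`,
   where CPM uses the TMM-corrected effective library size — the
   pseudocount (configurable) guards zeros at the cost of shrinking fold
   changes of barely detected genes;
4. a Pearson screen selects genes associated with the decay rate, or with
   disease-specific death, or with both NLR and death, at p < 0.05
   (configurable — the threshold is a knob, not canon);
5. an exhaustive best-subset search over the candidates fits linear
   probability models of the 0/1 death indicator and returns, per size
   $k$, the subset with maximal adjusted $R^2$, choosing overall the
   maximiser of adjusted $R^2 / k$. The linear probability model is the
   only interpretation of an adjusted-$R^2$ criterion for a survival-type
   outcome at this cohort scale; the parsimony ratio rewards gene sets
   whose members carry *jointly* rather than redundantly predictive
   signal — in practice sums and differences of co-varying genes, which is
   exactly the form composite scores take;
6. composite scores are signed sums of fold changes,
   $\sum_{g\in plus} \mathrm{fc}_g - \sum_{g\in minus} \mathrm{fc}_g$, and
   group differences are tested with the Wilcoxon rank-sum test (exact
   enumeration for both sizes ≤ 8 without ties, tie-corrected normal
   approximation otherwise).

The exhaustive search is genuinely exhaustive (no branch-and-bound), with
a model budget that errors early rather than running unbounded; with the
default cap of 15 candidates the full enumeration is ~33k models.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with every distribution anchored to the marginal summaries such cohorts
report:

* decay rate ~ log-normal, median 0.08/day, IQR ≈ [0.055, 0.11]
  (`sdlog` 0.51); amplitude ~ LN(median 1485, `sdlog` 0.40); plateau ~
  LN(median 144 cells/µL, `sdlog` 1.0); NLR ~ LN(median 2.43, `sdlog`
  0.64);
* 3-18 measurements per patient (median 5): weekly draws over 8 weeks
  with ±2-day jitter, multiplicative log-normal noise with CV 0.10,
  values floored at 1 cell/µL and kept at 0.001 resolution so CSV
  round-trips are exact;
* survival is piecewise-exponential around the 30-month split. Before it,
  the monthly hazard `h_early = 0.0017` is multiplied by 2.5 for
  below-median decay rates and by 2.5 for at-or-above-median NLR; after
  it, `h_late = 0.0014` is multiplied by 3.0 for at-or-above-median decay
  rates. The baselines were solved so that the marginal 2.5-year
  aggressive-death incidence is ~14% and the late-death incidence ~8%
  under uniform administrative censoring on [30, 96] months (median 63);
  the censoring floor at 30 months reflects that the endpoint design
  requires every patient to be classifiable at the split. This is the
  simplest generative model expressing the qualitative reversal the
  endpoint framework exists to detect: slow depletion predicts early
  death, fast depletion predicts late death among eventual cancer deaths;
* expression: negative-binomial counts (dispersion 0.2) around log-normal
  gene baselines scaled to a target depth; planted genes shift their
  week-2 mean by `effect_slope` (log2 units, default 0.8) per z-score of
  their covariate on the log scale, **plus** a shared per-patient response
  factor (sd 0.7) common to all planted genes. The shared factor models
  between-patient differences in the global magnitude of the week-2
  exosomal response; because it survives library-size normalisation, it
  is what makes *differences* of planted genes far more informative than
  single genes — the mechanism behind composite scores.

What the generator does **not** emulate: batch effects, fragment-level
sequencing noise, informative censoring, measurement-schedule dependence
on patient condition, or correlation between the decay rate and stage or
pathology. Passing tests therefore demonstrate the pipeline's correctness
and its behaviour under the assumed structure, not performance on real
cohorts.

## Numerical choices and degenerate inputs

* Zero-variance series make $R^2$ undefined and are flagged (cohort runs
  continue past them).
* The active-set solve guards a near-singular interior system (very fast
  decay makes the design nearly collinear) by falling back to the edge
  solutions.
* The log-rank statistic with zero events in both groups is defined as 0
  with p = 1.
* Monotone-likelihood Cox fits (separation) raise an error naming the
  terms; the pipeline records the failed endpoint model and continues.
* Ties in the candidate ranking resolve toward the lower decay rate, and
  ties at a dichotomisation threshold go to the high group.

## Calibration results and limitations

The test-suite and acceptance script recompute, from scratch at fixed
problem sizes (50 small series for the fitting oracle; cohorts of 200 and
2000; 400 null and 200 effect replicates at n = 300; 100 expression
replicates at n = 39):

* the grid fitter agrees with a 10×-finer brute-force oracle to one grid
  step, and the constrained solve to $10^{-6}$ in $R^2$;
* the median absolute decay-rate error at study noise is ~0.015/day,
  below the 0.02/day the biomarker's group assignments tolerate;
* null cohorts reject at the nominal 5% in the aggressive-endpoint
  log-rank and in the correlation screen;
* with a true early hazard ratio of 2.5 at n = 300, the aggressive
  endpoint's log-rank detects the decay-rate effect in about 80% of
  replicates — the event rates the hazards are anchored to (~40 events)
  cap the attainable power near 0.84 — and the early/late direction
  reversal is observed in essentially all replicates;
* exact recovery of a planted two-gene composite as the overall
  adjusted-$R^2/k$ optimum at n = 39 is unreliable (near zero through the
  full counting pipeline, and at most ~0.7 even with noise-free fold
  changes and a balanced outcome): with a handful of binary events, the
  search criterion identifies strong joint signal but cannot reliably pin
  the exact membership. Subset searches at this scale should be read as
  candidate-generating, not confirmatory — consistent with treating
  composite-score findings as hypothesis-generating.

The main known limitations are inherited from the design: the decay model
is phenomenological (no dose-to-blood mechanism); the aggressive /
non-aggressive split is a single fixed threshold; and the exosome arm's
linear probability models ignore censoring within the follow-up window.
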