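---
title: "Grading models, survival evaluation and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading models, survival evaluation and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pcgrade implements three grading systems for radical-prostatectomy (RP)
specimens of prostatic adenocarcinoma, the survival machinery with which
such systems are compared, and a synthetic cohort generator that makes
the whole pipeline testable without patient data. This vignette explains
the models, the tunable parameters, and the design choices made where
the conventions of the field leave room.

## The three grading systems

**Gleason score and ISUP/WHO Grade Group.** The input is the composition
of the invasive carcinoma as percentages of Gleason patterns 3, 4 and 5
(`p3 + p4 + p5 = 100`; intraductal carcinoma is not part of the
composition). The primary pattern is the most extensive one; the
secondary pattern is the highest-grade remaining pattern occupying at
least 5% of the tumour. If no other pattern reaches 5% the secondary
equals the primary (a pure pattern-3 tumour is 3+3). Pattern 5 present
below 5% and not selected as a component is recorded as *tertiary
pattern 5*. The Gleason score (primary + secondary) maps onto Grade
Groups (GG): GS ≤ 6 → GG1, 3+4 → GG2, 4+3 → GG3, GS 8 → GG4, GS 9–10 →
GG5.

Two conventions deserve comment because they are rarely written down:

* *Secondary selection is by grade, not extent.* A tumour read as
  70/23/7 (%GP3/%GP4/%GP5) takes pattern 5 — not the more extensive
  pattern 4 — as its secondary component, giving GS 3+5 = 8 (GG4). This
  is forced by the worked example the systems are defined with: the same
  tumour read as 70/27/3 keeps pattern 5 below the 5% threshold and is
  GG2 with tertiary pattern 5.
* *Ties in extent* (e.g. 50/50) resolve to the higher grade as primary.
  The field convention is unsettled; the conservative (risk-upgrading)
  choice is used and applied uniformly.

**IQ-Gleason.** The integrated quantitative Gleason score is
`p4 + p5 + 10·[p5 > 0] + 7.5·[p5 > 20]`, a continuous score on
[0, 117.5]. Its five-tier categorisation uses the printed integer bins
0–25, 26–50, 51–75, 76–100, 101–117.5. Because the bonuses generate
half-point scores (e.g. 25.5), the bins are implemented as [0,25],
(25,50], (50,75], (75,100], (100,117.5], which preserves every printed
label while covering the continuum. Note that the maximum 117.5 is
attained on the whole face `p3 = 0, p5 > 20`, not only at `p5 = 100`.

**cGrade.** The cribriform grade keeps the GG when invasive cribriform
and/or intraductal carcinoma (IC/IDC, one merged flag) is present in a
GG2–5 tumour and subtracts one point when it is absent; GG1 with IDC is
upgraded to cGrade 2. A GG1 record flagged IC/IDC is interpreted as
IDC-only (cribriform growth is a pattern-4 morphology) and triggers a
warning rather than an error.

## Survival machinery

All evaluation tools are implemented in the package rather than wrapped:

* `km_estimate()` — the product-limit estimator; censored-only times
  reduce the risk set without changing S.
* `logrank_test()` — the k-group statistic from observed minus expected
  events under the hypergeometric null, chi-square on k − 1 df.
* `cox_fit()` — Newton–Raphson with step halving on the Cox partial
  log-likelihood. Ties are handled by Efron's approximation by default
  (Breslow available); convergence is declared when the log-likelihood
  changes by less than 1e-9 (cap 100 iterations); standard errors come
  from the inverse observed information, confidence intervals are Wald
  (`exp(coef ± 1.96 se)`). A monotone likelihood (complete separation)
  is reported as an error when the fitted linear predictor spans more
  than 40 log-units. The score test at β = 0 is returned and, for a
  single binary covariate on untied data, equals the log-rank statistic
  — one of the suite's cross-checks against the `survival` package.
* `harrell_c()` — Harrell's concordance over comparable pairs: the pair
  is usable when the earlier time carries an event (equal times with
  exactly one event treat the event-bearing patient as earlier; two
  events at the same time are not comparable); tied scores count 1/2.
  The implementation is the O(n²) definition, verified against a naive
  pair-enumeration oracle.
* `bootstrap_c()` — patient resampling with replacement (default
  B = 1000), percentile 2.5/97.5 interval, seeded and reproducible.
  Scorers are re-evaluated inside every resample, so Cox-based scores
  are refit per replicate. Replicates without comparable pairs are
  dropped with a warning; more than 10% dropped is an error. Within an
  endpoint `run_analysis()` gives all systems the *same* resamples, so
  `compare_systems()` can report paired bootstrap differences — a
  deliberate strengthening over comparing overlapping intervals.
* `merge_sparse_groups()` — when the lowest grade category has fewer
  than `min_events` events it is merged upward (producing a combined
  "1 & 2" reference when the lowest groups are metastasis-free), but
  never past the point where only one comparison group would remain.
* `median_impute()` — median imputation for missing PSA.

For the c-index of the categorical systems the default risk score is the
ordinal category number (1–5). An alternative `linear_predictor` mode
scores patients by a univariate Cox fit on the dummy-coded categories,
refit inside each bootstrap replicate; the two differ whenever the
estimated hazard ratios are non-monotone across categories. The ordinal
default keeps the score model-free and the comparison symmetric across
systems.

## The synthetic cohort generator

No patient-level data accompany the grading systems, so
`generate_cohort()` draws cohorts whose *structure* matches a
grade-stratified RP series while every parameter stays known:

* **Strata and compositions.** Five latent severity strata with weights
  0.194/0.444/0.118/0.132/0.112 (a published GG distribution). Stratum 1
  is a pure pattern-3 tumour; strata 2–5 draw (p3, p4, p5) from
  per-stratum Dirichlet distributions, with an explicit per-stratum
  probability that any pattern 5 is present so that tertiary pattern 5
  arises naturally. Percentages are rounded to one decimal and
  renormalised to sum exactly 100, mirroring reporting granularity.
* **IC/IDC.** Bernoulli with logit `−3.1 + 0.09·p4`: ≈4.3% prevalence at
  p4 = 0 (IDC-only low-grade cases) rising to ≈85% near p4 = 55,
  matching the rising prevalence of IC/IDC with pattern-4 quantity.
* **Endpoints.** Biochemical recurrence (BCR) and distant metastasis
  times follow Weibull proportional hazards on the standardised
  continuous IQ-Gleason score (centre 40, scale 30) plus an additive
  IC/IDC effect, with independent uniform administrative censoring on
  (0, 200] months. Defaults: shape 1.1 for both endpoints; scales 250
  (BCR) and 600 (metastasis); log-HR per severity SD 0.9 (BCR) and 1.3
  (metastasis); IC/IDC log-HR 0.8 (BCR) and 1.2 (metastasis). The
  IC/IDC effects were calibrated once against published within-grade
  contrasts (GG2 tumours without IC/IDC show near-zero metastasis rates
  and roughly a third of the recurrence rate of those with it); the
  endpoint asymmetry mirrors the finding that grading discriminates
  metastasis better than recurrence.
* **Covariates.** Age ~ N(64.5, 5.5²); PSA lognormal around a median of
  8.3 ng/ml with 27/1064 of values set missing (imputed by
  `run_analysis()`); pT stage and margins are generated with
  stratum-dependent frequencies but are carried verbatim, not used in
  the hazard.
* **Observer noise.** `perturb_observer()` adds truncated Gaussian noise
  to (p4, p5) and renormalises — a model of inter-observer variability
  in quantifying minor high-grade components.
  `reclassification_experiment()` reports how often each system's
  category changes under such noise; the continuous IQ-Gleason score can
  only move by the noise itself plus the 10/7.5-point bonus jumps, which
  is why it is the stabler quantity.

What the generator does **not** emulate: the joint dependence of the two
endpoints (they are conditionally independent given the linear
predictor), hazard effects of stage/margins/PSA, multifocality,
centre-selection effects, and any real inter-observer process. Passing
tests therefore demonstrate correctness of the machinery and the
*qualitative* reproduction of the published structure (rising IC/IDC
prevalence, grade-monotone hazards, categorisation losing
discrimination), never the published cohort-specific numbers.

## Numerical and design choices

* All randomness flows from a single top-level seed; `run_analysis()`
  derives the endpoint-level resampling seed as `seed + 7919·k` for the
  k-th endpoint, and every generator function restores the caller's RNG
  state.
* Composition closure is enforced at 1e-9; one-decimal rounding pushes
  its residue onto the largest component.
* The secondary-pattern threshold is strict: exactly 5% pattern 5 is a
  score component, anything below is tertiary.
* Report bundles are written through a staging directory and copied only
  on success, so a failing stage leaves no partial output; the run log
  records seed, a hash of the configuration and the package version (no
  timestamps), making bundles byte-reproducible.
* Problem sizes used by the test suite — e.g. 200 replicates of n = 2000
  for parameter recovery and type-I error, eight cohorts of n = 700 with
  40 bootstrap replicates for the discrimination ordering — were chosen
  as the smallest sizes at which the Monte-Carlo checks are stable.

## Known limitations

* Only univariate Cox models are provided; the comparison of grading
  systems is deliberately unadjusted.
* Biopsy-specimen grading conventions differ from the RP conventions
  implemented here.
* The bootstrap interval is percentile; an optimism-corrected estimate
  in the style of Harrell requires a trainable scorer and is not the
  reported default.
* Competing risks, time-dependent covariates and interval censoring are
  out of scope.
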