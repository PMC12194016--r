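---
title: "Decomposing time on task in construction-based matrix tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing time on task in construction-based matrix tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In a construction-based figural matrix test the participant does not pick an
answer among distractors but composes it by clicking symbols from a
construction kit. Each symbol belongs to a symbol group, and each group is
tied to one logical rule of the matrix (addition, subtraction, intersection,
...). The software logs every click with a timestamp, which makes the total
time on task (ToT) of an item decomposable into three log-file times (LFTs):

* **onset time** — from item onset until the participant engages with the
  first rule: a global orientation component;
* **interrule time** — between finishing one rule and the first click of the
  next: the hypothesised core cognitive component, in which a rule-specific
  solution plan is constructed;
* **intrarule time** — between consecutive clicks within one rule: the
  behavioural execution of the plan.

`lftimes` implements this decomposition, the derived structuredness and
motivation scores, and the statistical battery used to validate the
interpretation of the components: a quadratic ToT-performance regression,
hierarchical (Ward) clustering of processing strategies, per-cluster
acceleration analyses, a parallel mediation path model, a hierarchical
regression of performance on ToT and the LFTs, and crossed random-intercept
models for incomplete-attempt effects.

## The decomposition and its conventions

For one item log, clicks are segmented by rule
(`segment_by_rule()`), and `item_times()` computes

* `tot` = time of the terminal event (submit or timeout),
* `first_click` = time of the first click,
* between-rule gaps (consecutive clicks on different rules) and within-rule
  gaps (same rule).

These satisfy, exactly,
`first_click + sum(gaps) + (tot - last_click) = tot`,
which the test suite asserts to 1e-9 on a thousand simulated logs.

Two conventions are deliberate choices, both switchable:

* **Interrule denominator.** An item's interrule time is the summed
  between-rule gap divided by, per default, the *observed number of
  transitions*. Dividing by the number of rules (or rules − 1) is offered as
  well, but only the per-transition version is invariant to the inflation of
  the transition count by rule jumps. The flip side, documented here because
  it matters for interpretation: excursion-style jumping *dilutes* the
  per-transition interrule time, so jumpy processing looks fast between
  rules. This mechanical coupling makes the observed interrule-jump
  correlation more negative than the latent one.
* **Onset residualization.** The first click happens only after the first
  rule's plan is formed, so the raw first-click time confounds orientation
  with planning. The onset time is defined as the residual of a pooled OLS
  regression of first-click time on the item-level interrule time, recentred
  by the grand mean first-click time (keeping seconds and a positive mean).
  The sentence describing this procedure in the assessment literature can be
  read in either regression direction; we default to residualizing the
  first-click time — the construct is "first-click time purged of
  rule-planning time" — and expose `onset_direction = "inter_on_first"` for
  the literal alternative. Pooling is global (one regression across all
  participant-items), matching the single-regression reading.

## Scores

* **Rule-jump score**: executed between-rule transitions minus the necessary
  ones. The necessary count is `n_rules - 1`, the minimum number of
  transitions when each rule's symbols are clicked as one block; incomplete
  attempts can score negative.
* **Acceleration (delta-M)**: mean of the first `floor(n/3)` items minus the
  last `floor(n/3)` (7 and 7 for 22 items), per time component; positive
  means speeding up across the test.
* **Response to difficulty (RtD)**: intraindividual slope of item time on
  item difficulty `1 - P`, with `P` estimated from the analysed sample.
  Slopes are z-standardized within participant by default (the slope is then
  the correlation, scale-free and comparable across participants); raw
  seconds-per-difficulty slopes are available.
* **Incomplete-attempt propensity (IAP)**: an item attempt counts a rule as
  attempted when at least one click lands in its symbol group; the indicator
  fires when fewer rules were attempted than the item contains. The
  participant mean is the global IAP, the group-mean-centred remainder the
  current IAP.
* **Classical item statistics**: difficulty `P`, item-rest correlation, and
  Cronbach's alpha in the variance-of-total form (verified against the
  covariance form to 1e-12 in the tests).

## The statistical stage

* **Quadratic ToT effect**: `score ~ z(ToT) + z(ToT)^2` against
  `score ~ z(ToT)`, standardized betas in the `b * sd(x) / sd(y)` convention
  and an F-change test on (1, n − 3) df.
* **Strategy clustering**: Ward's method on Euclidean distances of the
  z-standardized test score and interrule time, in the `ward.D2` convention
  (merge cost = increase in within-cluster sum of squares; documented
  because `ward.D` on unsquared distances yields different heights). The
  number of clusters maximizes the average silhouette width over k in 2..10;
  k = 1 is admitted only if every candidate stays below a weak-structure
  threshold (0.25). Stability is reported from bootstrap resamples
  (silhouette distribution and pairwise co-assignment agreement). The binary
  structured/unstructured contrast used by the downstream analyses is always
  taken from the dendrogram's primary split, which coincides with the
  selected solution when k = 2.
* **Cluster contrasts**: Welch t with Welch–Satterthwaite df, paired with a
  pooled-SD Cohen's d — the combination conventionally reported together in
  this literature.
* **Parallel mediation**: interrule time X, mediators intrarule time M1 and
  rule jumps M2, outcome score Y; all standardized, paths estimated by the
  model's OLS regressions (`M1 ~ X`, `M2 ~ X`, `Y ~ X + M1 + M2`). The
  mediator residual covariance is fixed at zero, leaving one overidentified
  moment — hence the single model degree of freedom; a flag frees it
  (saturated model, zero discrepancy). Fit indices come from the ML
  discrepancy `F = log det(Sigma) - log det(S) + tr(S Sigma^-1) - p` with
  `chi^2 = (n-1) F` (the n − 1 scaling is the common SEM convention and
  affects the third decimal), RMSEA, CFI versus the independence baseline,
  and SRMR as the RMS standardized residual covariance. Confidence intervals
  are percentile bootstrap over participant resamples with a recorded seed;
  point estimates are seed-invariant.
* **Hierarchical regression**: score on ToT, then ToT + the three LFTs;
  unique R² as the drop in model R² when a predictor is removed (squared
  semipartial), F-change on (3, n − 5) df, VIF from auxiliary regressions.
* **IAP mixed model**: response time on global and current IAP with crossed
  random intercepts for participants and items, REML via `lme4` with
  Satterthwaite p-values via `lmerTest`.

## What the synthetic generator emulates

`generate_cohort()` produces full click streams, not feature tables, so the
whole pipeline — parsing, replay, decomposition, residualization, scoring,
statistics — is exercised end to end, with ground truth for every latent.
The generative model:

1. Participants are a mixture (56% structured) with class-specific ability
   (N(0.8, 0.8) vs N(−0.8, 0.8)).
2. All duration components are log-normal (positive, right-skewed; with only
   location/scale information available, the family is our assumption).
   Onset locations shrink geometrically with test position (practice).
3. Structured participants draw a planning gap before every rule whose
   location decreases with ability and whose practice-related decline rate
   grows with ability — only in the structured class, which is what makes
   the interrule acceleration performance-correlated there and nowhere else.
   Unstructured participants have short gaps with no ability coupling.
4. Slower planners also execute more slowly (intrarule scaling) and emit
   more rule-jump excursions (Poisson rate coupled to the within-class
   z-scored latent gap). An excursion revisits the symbol group of a
   previously processed rule and toggles straight back, perturbing jump and
   transition counts without changing the final selection — keeping
   correctness and structuredness separable.
5. A rule is solved with probability
   `plogis(1.15 + ability - difficulty - 0.15 * excursions)`; failed rules
   swap one solution symbol within the group. The intercept calibrates the
   cohort's overall success level so that class score means land near the
   published two-cluster pattern (roughly 12 vs 2 of 22) under the fixed
   ability and difficulty distributions; without it the structured class is
   floor-compressed and the score axis carries no class separation.
6. The whole time budget of an item scales with
   `1 + rtd_slope * z(difficulty)` (planting RtD), items are abandoned
   before all rules with a Beta(0.3, 12) per-participant propensity
   (planting IAP; abandoned items run into the limit), and everything is
   right-censored at the 90-s item limit.
7. The first click occurs at onset + first planning gap, so first-click
   times are confounded exactly the way the residualization assumes.

Defaults were calibrated once, before the test suite was frozen, against the
intended study conditions: a two-cluster solution under silhouette
selection, class recovery (median adjusted Rand index at or above 0.8 over
20 seeds), an inverted-U ToT effect, and the qualitative cluster pattern
(structured: higher score, longer interrule time, fewer jumps). Two
structural facts surfaced during that calibration and are worth knowing
when interpreting synthetic results:

* the time limit itself couples times, jump counts and score (slow attempts
  get truncated), so "null" configurations for mediation checks must
  disable censoring and abandonment;
* per-transition dilution (above) reverses the sign of the observed
  interrule-jumps association relative to the planted one.

What the generator does **not** emulate: item-content effects beyond a
scalar difficulty, within-item learning, response-time/accuracy trade-off
strategies, drift-diffusion-style within-trial dynamics, or IRT-grade
measurement structure. Passing recovery tests therefore shows the pipeline
is correct and well-calibrated for data with this statistical skeleton, not
that real matrix-test data satisfy the model.

## Numerical choices and degenerate inputs

* Event validation is strict: non-monotone within-item times, events after
  the terminal event, or times beyond the limit are errors naming the
  offending participant-item, never silently repaired.
* Zero-variance inputs degrade explicitly: residualization falls back to
  centring with a warning; zero-variance items yield `NA` item-rest
  correlations; RtD slopes with constant difficulty are `NA` with a warning;
  identical points refuse to cluster.
* Ties in event times are kept in input order (stable ordering); excursion
  clicks therefore stay adjacent.
* Bootstrap and simulation seeds always flow from one root seed through
  fixed substreams, so every pipeline run is byte-reproducible.
* Problem sizes in the test suite (cohorts of 200 participants and 22
  items, 20 replicate seeds, 100 null-coverage datasets at 500 bootstrap
  draws, 200 permutation fits) were chosen as the smallest sizes at which
  the checked properties are stable Monte-Carlo statements.

## Known limitations

* The mediation module fits exactly the one recursive 4-variable path
  model; it is not a general SEM engine (no latent variables, no FIML
  missing-data handling).
* Percentile bootstrap intervals for products of coefficients are known to
  be slightly conservative near zero effects.
* With per-transition normalisation, heavy rule jumping deflates observed
  interrule times; comparisons across groups that differ strongly in jump
  rate mix planning speed with jumping style. The alternative denominators
  exist precisely for that sensitivity analysis.
* The packaged 22-item bank mirrors only the structural composition
  (rule counts, groups, time limit) of the published instrument; symbols
  and solutions are synthetic placeholders.
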