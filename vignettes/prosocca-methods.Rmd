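---
title: "Models and methods behind prosocca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prosocca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosocca)
```

# Overview

`prosocca` implements a complete analysis chain for two cost–benefit
measures of prosocial behavior — harm aversion (money traded against
electric shocks for self or another person) and prosocial effort (work
for credits versus rest, for self or another person) — and for relating
the derived prosociality indices to an 18-variable battery of affective
and psychiatric trait scores. This vignette documents the models, the
synthetic-cohort generator, the numerical choices, and the design
decisions that were genuinely open.

# The choice models

## Harm aversion

Each trial offers a harmful option (more money, more shocks) and a
helpful option. Writing `Δm` and `Δs` for the harmful-minus-helpful
differences in money and shock count, the value difference is

$$\Delta V = (1-\kappa)\,\Delta m - \kappa\,\Delta s,$$

mapped to a choice probability by a softmax,
$P(\text{harmful}) = 1/(1+e^{-\beta \Delta V})$. The harm-aversion
weight `κ ∈ [0, 1]` is condition-specific (`κ_self`, `κ_other`), as is
the inverse temperature `β ∈ [0, 100]`; at the upper β bound the curve
is effectively a step function, at β = 0 choice is random. A
participant with weight κ is indifferent on a trial exactly when
`Δm/(Δm+Δs) = κ`, which is why the trial generator controls the spread
of this ratio (below). The softmax is written here for the *harmful*
option, with `ΔV` the harmful-minus-helpful value difference; the
direction is a convention, and all downstream indices are unaffected by
it.

**Hyperaltruism** is `κ_other − κ_self ∈ [−1, 1]`: positive values mean
the decider gives up more money to spare another person shocks than to
spare themselves.

## Effort discounting

Each trial offers work (reward `R ∈ {2,3,4}` credits at one of four
effort levels) against a fixed rest option worth 1 credit. Reward is
discounted parabolically by effort,

$$SV = R - \lambda E^2, \qquad
P(\text{work}) = \frac{e^{\beta\,SV}}{e^{\beta\cdot 1}+e^{\beta\,SV}},$$

with condition-specific discount rates `λ_self`, `λ_other ∈ [0, 0.5]`
and a single shared β. The 0.5 cap is not arbitrary: beyond it every
offer in the 12-cell design falls below the rest value, so larger
values are behaviourally indistinguishable.

**Effort coding.** The task defines effort as 30/50/70/90 % of each
participant's calibrated maximum. The model needs a numeric `E`; we
code the four levels as `E = 3, 5, 7, 9` (tenths of the calibrated
maximum). This is the coding under which the 0.5 cap has exactly the
property above (`4 − 0.5·3² = −0.5 < 1` already at the lowest effort
level), and under which realistic discount rates land in the few-percent
range. It is a design decision of this package: percent-scale or
fraction-scale codings would rescale λ without changing the ordering of
participants, and every rank-based statistic downstream is invariant to
such monotone rescalings.

**Prosocial effort** is the reverse-coded apathy difference
`−(λ_other − λ_self) ∈ [−0.5, 0.5]`; reverse-coding is implemented as a
sign flip, again harmless to rank statistics.

## Maximum-likelihood fitting

Both models are fitted per participant by bounded multi-start
L-BFGS-B with analytic gradients:

* β is optimised on a log scale for stability; search bounds are
  `[1e-4, 100]` (harm) and `[0.01, 30]` (effort).
* `n_starts = 10` restarts drawn uniformly in bounds; ties are broken by
  lowest negative log-likelihood, then lowest `κ_other` (respectively
  `λ_other`).
* Per-choice probabilities are floored at `1e-12`, so the likelihood is
  always finite even for deterministic responders.
* Boundary estimates (κ at 0/1, λ at 0/0.5) are retained and flagged,
  not censored: with 35 trials per condition an always-helpful responder
  genuinely is at the identifiable edge of the κ range.
* The harm likelihood separates over conditions (parameters are
  condition-specific), so each (κ, β) pair is fitted on its own trials;
  the effort model shares β, so its three parameters are fitted jointly.
* Missed effort trials carry no likelihood term and are dropped. The
  alternative — penalising misses — would require a response-time model
  the tasks do not support.

The test suite holds the optimizer to a dense grid-search oracle
(κ step 0.01 × β grid, λ step 0.005 × β grid): the fitted NLL must be
within `1e-3` of the grid minimum on every tested dataset.

# Quality control

Two performance-based exclusion rules, applied before any analysis:

* **Attention checks.** Four harm-task trials (two per condition)
  contain a dominated option (one option has both more money and fewer
  shocks). Choosing a dominated option even once excludes the
  participant.
* **Missed trials.** Missing strictly more than 10 % of the 48 effort
  trials excludes the participant. "Strictly" matters at the
  granularity of the design: 4/48 (8.3 %) is retained, 5/48 (10.4 %)
  excluded. The denominator is the full 48-trial set.

The harm task has no missed-trial rule (responses were not
time-limited); the effort task has no attention checks (each choice has
real consequences). Exclusion is idempotent and removes the participant
from every table.

# The trait–prosociality CCA

The 18 trait scores (X) and the 2 prosociality indices (Y) are z-scored
(n − 1 denominator) and analysed by canonical correlation analysis.
The solver whitens each set symmetrically — `R_xx^(-1/2)`,
`R_yy^(-1/2)` by symmetric eigendecomposition — and takes the SVD of the
whitened cross-correlation matrix. Singular values are the canonical
correlations; back-transformed singular vectors are the standardized
weights. This route is numerically stable and is verified in the tests
against both `stats::cancor` and direct numerical maximization of
`cor(Xa, Yb)`.

Conventions and derived quantities:

* `min(p, q) = 2` canonical functions; each function's sign is flipped
  so the hyperaltruism loading on its own variate is positive.
* Loadings are correlations of observed variables with their own
  variate; cross-loadings with the opposite variate. The identity
  `cross = loading × r` holds to machine precision and is asserted at
  `1e-10` on every fit.
* **Sequential Wilks/Rao tests.** Function k is tested via
  `Λ_k = Π_{i≥k}(1 − r_i²)` and Rao's F approximation, using effective
  sample size `n − k + 1` when testing function k — the sequential
  convention of the standard statistical packages, which yields the
  familiar df pairs (36, 610) and (17, 306) at p = 18, q = 2, n = 325.
* **Permutation test.** Roy's largest root (the largest squared
  canonical correlation) under joint permutation of Y's rows, 1,000
  permutations by default, `p = (1 + #{perm ≥ obs})/(1 + n_perm)`.
  Permuting Y rather than X is a labelling choice; the statistic is
  symmetric and the tests verify both sides. The implementation
  pre-whitens once, so each permutation costs a single small
  cross-product.
* **Role classification.** On function 1, with the conventional 0.3
  cutoff: high loading + high weight → contributor; high loading + low
  weight → collinear contributor (its variance is carried by other
  traits); low loading + high weight → suppressor candidate; otherwise
  negligible. Function 2 is reported but left unclassified — with only
  two index variables the second function typically contrasts the two
  tasks rather than measuring shared prosociality.
* **Commonality analysis.** Predictors are the traits with |loading| ≥
  0.3 or |weight| ≥ 0.3 on function 1; the criterion is the
  prosocial-set variate of function 1 (the most direct operationalisation
  of "the predicted dimension"; other criterion choices exist, and this
  one is a documented package decision). For each predictor, `total` is
  its squared zero-order correlation with the criterion, `unique` the
  drop in full-model R² when it is removed, and `common = total −
  unique`. Negative common components are real and flag suppression.
  The implementation works on correlation submatrices and is held to an
  independent all-subsets (Möbius-inversion) oracle at `1e-10`.

# Univariate statistics

* **Wilcoxon signed-rank** (self vs other parameters): zero differences
  dropped, average ranks for ties, z from the plain normal approximation
  with tie-corrected variance and no continuity correction — the
  convention of the era's statistical packages. The tests verify the z
  against exact enumeration of all sign patterns for n ≤ 10.
* **Spearman correlations** across tasks, with asymptotic t p-values;
  invariant to the reverse-coding conventions above.
* **Fisher r-to-z comparison** of correlation magnitudes, treating the
  two correlations as independent. This mirrors the widely used online
  calculators; a dependent-correlation test (e.g. Steiger's) would be
  more appropriate statistically and is deliberately out of scope as a
  fidelity choice.
* **Repeated-measures ANOVAs** on per-participant work proportions
  (beneficiary × effort, beneficiary × reward), delegated to
  `car::Anova`; Greenhouse–Geisser correction is always applied to
  effects with ≥ 3 levels (fractional dfs), and partial eta squared is
  `SS_effect/(SS_effect + SS_error)`.

# The synthetic cohort generator

No participant-level data are deposited, so the generator is the
package's study population. Its defaults encode the study conditions:

* **Harm trial sets**: 35 trade-off trials per beneficiary condition
  plus 2 attention checks each. `Δm` lies on a 0.1-unit grid in
  [0.1, 10], `Δs` is an integer in [1, 19]. The original optimized
  trial sets are not published; instead the generator stratifies the
  implied indifference ratio `Δm/(Δm+Δs)` across (0, 1), guaranteeing
  identifiability of κ over its range (≥ 8 of 10 deciles covered, by
  construction and by test).
* **Effort trial set**: the fixed 48-trial design, 2 beneficiaries × 4
  effort levels × 3 rewards × 2 repeats.
* **Choices** are Bernoulli draws from the softmax models at each
  participant's true parameters; compliant agents always take the
  dominant option on checks.
* **Traits and indices** follow a single-factor model: a latent
  affective factor `A ~ N(0,1)`; trait `j` is `l_j A + sqrt(1-l_j²) ε`
  rescaled to instrument-like means and SDs (synthetic values; only the
  correlation structure matters downstream). Default loadings: empathic
  concern +0.60 and perspective taking +0.55; emotional apathy −0.60,
  externally oriented thinking −0.55, affective psychopathy −0.55,
  interpersonal psychopathy −0.50; the remaining twelve traits ±0.05.
  The six substantive magnitudes are chosen so that their attenuated
  loadings on the first canonical variate (≈ 0.43 and above at n = 325)
  clear the 0.3 interpretation cutoff reliably — the generator's
  contract is that planted traits are the ones recovered as
  contributors.
* **Indices** load equally on `A`, with the loading solved in closed
  form from the target first canonical correlation: with
  `s = Σ l²/(1−l²)` and `u = 2c²/(1−c²)`, the population first
  canonical correlation of the single-factor model is
  `sqrt(s/(1+s) · u/(1+u))`. The default target is 0.37; a target of 0
  (with zero loadings) gives an exact null cohort; infeasible targets
  (> 0.95, or requiring index communality ≥ 0.95) raise an error.
* **Ground-truth parameters**: `κ_self ~ N(0.37, 0.15)` clipped to
  [0, 1]; `κ_other = κ_self + 0.08 + 0.15·(hyperaltruism index)`,
  clipped. `λ_self ~ N(0.02, 0.06)` clipped to [0, 0.5];
  `λ_other = λ_self + 0.09 + 0.08·(apathy index)`, clipped. Softmax
  temperatures are lognormal around 5 (harm) and 2 (effort). The means
  and shifts match the magnitudes reported for these tasks; the SDs are
  chosen to give realistic dispersion while keeping most draws interior.
* **Careless participants**: 5 % of the cohort fails each attention
  check with probability 1/2 and misses 15 % of effort trials; everyone
  else misses 2 % at random. Only the effort task generates misses.

What the generator does *not* emulate: questionnaire item-level
responses (traits are continuous subscale scores), execution success on
the box-ticking task, response times, bot-like free-text behavior,
multi-set trial randomisation, or floor/ceiling discreteness of real
questionnaires. Passing tests therefore demonstrate that the *pipeline*
is correct and well calibrated under a realistic planted model — not
that the substantive findings would replicate in new human data.

# Validation design and problem sizes

The suite validates each stage at sizes chosen to balance statistical
resolution against a desk-scale runtime:

* Oracle equivalence: 20 simulated participants per fitter against
  dense grids; CCA against brute-force maximization at n = 50, p = 3,
  q = 2; commonality against the all-subsets oracle with 10 predictors.
* Parameter recovery: 200 participants at the tasks' trial counts
  (κ ~ U(0.05, 0.95) at β = 5; λ ~ U(0, 0.3) at β = 2); rank
  correlations between true and recovered `κ_other`/`λ_other` must
  exceed 0.8, and interior κ bias must stay below 0.05.
* Permutation calibration: 500 null cohorts at n = 325 with 200
  permutations each (rejection rate 0.05 ± 0.02); power: 50 cohorts
  with planted first canonical correlation 0.4 (≥ 90 % rejections).
* Planted-effect power: 100 cohorts at n = 325; Wilcoxon tests on the
  κ and λ shifts and the sign of the index correlation, evaluated on the
  generator's ground-truth parameters. Using true rather than refitted
  parameters keeps the experiment at simulation scale; the recovery
  experiment separately establishes that fitted parameters track the
  true ones, and `run_full()` demonstrates the fitted path end to end.

# Interfaces

The orchestration layer is a pair of R functions — `run_simulate()`
writes a cohort (trials/traits/ground-truth CSVs plus a JSON manifest),
`run_full()` executes every stage and returns (and optionally writes)
all result tables — driven by a serializable configuration
(`default_config()`, `read_config()` for JSON/YAML). This package is
meant to be driven from R, so these functions *are* its entry point;
`scripts/acceptance.R` shows the pattern as a thin command-line wrapper.

# Known limitations

* κ is not scale-free: rescaling the money units of `Δm` moves the
  implied indifference ratios, so κ values are comparable only within a
  fixed trial currency. Fits are, however, invariant to trial order.
* With near-deterministic responders β is only weakly identified above
  a data-dependent ceiling and often lands on its search bound; κ (the
  quantity of interest) remains well identified, which is why recovery
  is asserted for κ and λ, not β.
* The Fisher r-to-z comparison assumes independent correlations even
  though the compared correlations share participants (a deliberate
  fidelity choice, documented above).
* The commonality criterion (which variate to predict) is not uniquely
  determined by the method's description; the package's choice is stated
  and tested, not asserted as the only valid one.
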