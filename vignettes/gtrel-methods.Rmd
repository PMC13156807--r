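---
title: "Methods: generalizability-theory reliability for trial-level scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalizability-theory reliability for trial-level scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrel)
```

## The measurement model

Psychophysiological scores — single-trial ERP amplitudes, per-split HRV
indices, rectified EMG, skin-conductance responses — are aggregates over
noisy replicates. Generalizability theory (GT) treats an observed score as
a sum of effects from the *object of measurement* (persons) and the
*facets* of the measurement procedure (trials, occasions, splits):

$$X_{pio} = \mu + \nu_p + \nu_i + \nu_o + \nu_{pi} + \nu_{po} + \nu_{oi} + \nu_{pio,e}$$

Each effect is a mean-zero random variable with its own variance
component; the highest-order interaction is confounded with residual error
and carries the `",e"` suffix throughout the package (`pi,e`, `pio,e`,
`p(i:s),e`). Supported layouts are Persons × Trials (`one_facet`), Persons
× Trials × Occasions (`two_facet`), Persons × (Trials : Splits)
(`splits`), and splits crossed with occasions (`splits_occasion`,
experimental, see below). A *fixed* facet (e.g., task) restricts inference
to the observed conditions: components are estimated per condition, and the
"global" set is explicitly an unweighted average over those conditions.

Assumptions: effects are uncorrelated across sources, exchangeable within
a facet (trial order carries no meaning), and — for the Gaussian family —
homoscedastic within a cell. Missingness from artifact rejection is
assumed ignorable (unrelated to the score value).

## G study: variance-component estimation

**Expected mean squares (`estimate_ems`)** computes ANOVA mean squares and
solves the EMS equations. On balanced Gaussian data this is exact and
coincides with REML; it is the package's oracle estimator. Raw solutions
can be negative when a component is near zero; they are preserved in
`$raw`, truncated to 0 for downstream use, and flagged in
`$truncation_flags`. Unbalanced data are rejected with an error directing
to the Bayesian path.

**Bayesian multilevel model (`estimate_bayes`)** fits the same
decomposition as a crossed random-effects model in JAGS, handling
unbalance at the observation level and keeping every posterior
variance draw strictly positive. Point estimates are posterior medians;
coefficients are evaluated per draw and summarized by the median and a 95%
equal-tailed credible interval, so the point value is the median of
per-draw coefficients, not the coefficient of median components.

Defaults and the reasoning behind them:

- `gt_mcmc()`: 4 chains × 1000 kept draws after 500 adaptation and 500
  burn-in iterations. The seed is mandatory — there is no silent default —
  and per-chain RNGs are derived from it, so runs are exactly
  reproducible. The JAGS `glm` module is loaded for block updates of the
  crossed effects; without it these models mix an order of magnitude more
  slowly.
- Convergence is a hard gate: if any monitored parameter's split-chain
  potential scale reduction factor exceeds `rhat_max` (default 1.01), or a
  draw is non-finite, estimation *fails* rather than returning a dubious
  fit. Models with a location trade-off (e.g., per-task means against
  per-task mean trial effects in the heteroscedastic model) may need
  longer chains to clear the gate.
- `gt_priors()`: component SDs get half-Student-t(3) priors scaled by 2.5
  × the observed score SD on the modeling scale — weakly informative,
  diffuse relative to the data, and the source of strict positivity. The
  grand mean gets a normal prior centered on the sample mean with SD 10 ×
  the observed SD.

**Families.** `gaussian` models scores on the identity scale;
`lognormal` models the linear decomposition of log scores (strictly
positive, right-skewed data such as band power); `gamma_chisq` models
square-root scores (positively skewed, zero-bounded power-like data).
Components and all downstream coefficients are reported **on the modeling
scale** (log or square-root); they are not back-transformed.

**Fixed facets and heteroscedasticity.** With one fixed facet in the
Persons × Trials layout a single joint model estimates per-condition
person, trial, and residual components (centered parameterization: person
effects are drawn around the per-condition mean, which mixes far better
than zero-centered effects plus an intercept; the mean trial effect of
each condition is additionally swept into the person-effect prior so the
condition mean does not trade off against a slow common drift of that
condition's trial effects). With `heteroscedastic_by`,
per-condition log residual SDs are drawn from a higher-level normal
distribution — a multilevel location-scale model. Richer layouts with a
fixed facet fall back to one fit per condition; component estimates are
equivalent, joint contrasts are not available.

## D study: from components to reliability

A `dstudy_scenario()` fixes the replicate counts $n'$ the projected
measurement averages over. *Relative* error variance collects the
person-by-facet interactions (error affecting relative standings);
*absolute* error adds facet main effects (error affecting absolute
levels). One facet: $\sigma^2_\text{rel} = \sigma^2_{pi,e}/n'_i$,
$\sigma^2_\text{abs} = \sigma^2_\text{rel} + \sigma^2_i/n'_i$. Two facets:
$\sigma^2_\text{rel} = \sigma^2_{pi}/n'_i + \sigma^2_{po}/n'_o +
\sigma^2_{pio,e}/(n'_i n'_o)$, with $\sigma^2_o/n'_o + \sigma^2_i/n'_i +
\sigma^2_{oi}/(n'_i n'_o)$ added for the absolute form. SEMs are the
square roots of these error variances.

Coefficients (`reliability_coefficient`):

- `G` (generalizability, $E\rho^2$) uses relative error; `D`
  (dependability, $\phi$) uses absolute error. When every facet
  main-effect variance is zero the two coincide exactly.
- `ICC_rel` / `ICC_abs` are the single-replicate ($n' = 1$)
  intraclass correlations — per-trial reliability, independent of the
  replicate counts.
- `CE` (equivalence), `CS` (stability), `CES` (both) for two-facet
  designs: `CE` moves the person × occasion term into the numerator
  (generalizing over forms/trials but not occasions), `CS` the person ×
  trial term; `CES_G` equals `G`.
- `CUT` (cut-score dependability): the squared deviation of the cut score
  from the estimated grand mean joins $\sigma^2_p$ in numerator and
  denominator, so classifications relative to a cut far from the mean are
  more dependable; at $C = \mu$ it reduces exactly to `D`. The estimated
  grand mean is used as-is (no small-sample bias correction).

All-zero component sets raise an *undefined-coefficient* error rather than
returning 0/0. `project()` sweeps one replicate count over a grid, reports
the smallest count reaching a target, and otherwise flags the target
unreachable together with the asymptote (the limit with all non-vanishing
error terms retained — with finite occasion counts, adding trials cannot
push `G` past $\sigma^2_p/(\sigma^2_p + \sigma^2_{po}/n'_o)$).
`contrast()` differences per-condition coefficient draws and reports 95%
credible intervals and the posterior probability of a positive difference.

## Split designs

`enforce_split_convention()` groups consecutive trials into equal-length
splits, identically for every person; a trailing partial split is dropped
and logged. Trial order is only a grouping device (trials are
exchangeable). With unequal observed split lengths the per-split trial
count $n'_{i:s}$ used in coefficients is user-supplied; the harmonic mean
of the observed lengths is a reasonable choice. The `splits_occasion`
layout composes the split-design terms with the occasion terms; because
this composition is a reconstruction rather than a printed table, results
carry an `experimental` flag and only `G`, `D`, ICCs and `CUT` are
offered.

## Difference scores

For $D = X - Y$ the universe-score variance is $\sigma^2_{X(p)} +
\sigma^2_{Y(p)} - 2\sigma_{XY(p)}$ — the person-level covariance always
enters, which is why strongly correlated constituents yield unreliable
differences (`ceiling_analysis()` quantifies this). Error terms enter at
each measure's own replicate counts; error-level covariances are divided
by harmonic-mean counts $\ddot n = 2/(1/n_X + 1/n_Y)$ and are estimable
only for concurrently observed measures — for non-concurrent measures they
are *exactly zero by design*, not estimated-as-small. A numerator at or
below zero is a first-class `undefined` state with a diagnostic note
(absence of between-person variance in change is a finding, not a
failure).

Covariance components (`estimate_covariances`): the EMS path uses the
polarization identity $\mathrm{cov} = (\mathrm{VC}[X+Y] -
\mathrm{VC}[X-Y])/4$ on raw solutions for concurrent pairs and the sample
covariance of person means otherwise; the Bayes path fits a bivariate
model with half-t SD priors and uniform correlation priors (Persons ×
Trials layout only). Every covariance is clipped to the Cauchy–Schwarz
bound implied by the variance components, with clipping flagged.

## Synthetic data

`simulate_gt()` draws every effect of the chosen layout independently with
its stated variance and applies the family transform (identity /
exponential / square), so estimators can be validated by parameter
recovery against a stored truth record. Per-person unbalance is generated
by independent trial retention (ignorable by construction); zero-inflation
emulates nonresponse trials. A measure-pair block generates difference-
score data with person-level (and, when concurrent, trial-level) bivariate
effects. `make_worked_example()` produces a three-task dataset with
identical per-trial components but unequal retained trial counts — the
situation where per-trial ICCs agree while dependability at the observed
counts is ordered by trial count. Scope limits: one fixed facet; the
measure-pair generator covers the Persons × Trials layout only;
non-Gaussian families transform a latent Gaussian decomposition (they are
GT-faithful on the modeling scale, not literal gamma/χ² sampling models).

## Numerical and design choices

- EMS negative solutions: truncate-and-flag (raw values preserved) rather
  than refitting with constraints, keeping the estimator a pure oracle.
- Monotonicity caveat: `G`, `D`, `CES` and `CUT` are nondecreasing in
  every replicate count, but `CE` in $n'_o$ (and `CS` in $n'_i$) can be
  non-monotone for some component sets, because the same term moves in
  numerator and denominator; the property tests assert only the provable
  directions.
- Coefficient intervals clip to [0, 1]; point values beyond 1 by more than
  1e-12 are errors, not clipped silently.
- Balance is defined as: every person carries every observed
  facet-condition tuple with equal replicate counts (tuples, not the full
  cross-product, so nested layouts validate correctly).
- A facet observed at a single condition cannot be modeled
  (identifiability error); declaring it `hidden` documents that reported
  reliability is conditional on that condition.

## A worked example

```{r, eval = FALSE}
we <- make_worked_example(seed = 301, n_persons = 300)
design <- gt_design(gt_facet("trial", "random"), gt_facet("task", "fixed"))
fit <- estimate_ems(we$table, design)
lev <- components_by_fixed_level(fit, "task")
sapply(lev, function(v)
  reliability_coefficient(v, dstudy_scenario(coefficient = "ICC_rel"))$value)
```

See the README for the full walk-through, including dependability at the
observed trial counts and the equal-count comparison.
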