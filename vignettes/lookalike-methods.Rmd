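---
title: "Look-alike fusion by chained-equations imputation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Look-alike fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lookalike)
```

## The statistical problem

Two person/incident-level datasets describe overlapping populations but
different individuals: a recipient A (here, administrative records of a
sexual-violence support service) and a donor B (a victimisation survey).
A block of variables exists only in B. Record linkage is impossible —
the data are pseudonymised by design — so the package treats the donor-only
block as *unit-missing data in A* and fills it by multiple imputation,
conditioning on a harmonized comparison vector C of covariates both sources
share. The defensible estimand is the conditional law of the target given C
as it exists in the donor: the fused dataset *mimics the donor's
associations*, it does not reveal the recipient's unobserved truth. That is
the look-alike assumption, and the package's validation machinery is built
around checking its observable consequences rather than hiding them.

## Imputation model

Fusion stacks A and B on C and runs fully conditional specification: each
incomplete variable $X_j$ has a univariate conditional
$X_j \sim g_j(X_j \mid X_{-j}, C, \varphi_j)$, visited in a fixed order for
$T$ iterations, the whole chain repeated independently for $m$ completed
datasets. Imputation is *proper*: before every redraw the model parameters
$\varphi_j$ are drawn from an (approximate) posterior, so between-imputation
variance reflects parameter uncertainty:

* **Bayesian linear** (continuous targets): $\sigma^{2*} =
  \mathrm{RSS}/\chi^2_{\nu}$ on the residual degrees of freedom, then
  $\beta^* \sim N(\hat\beta, \sigma^{2*}(X'X)^{-1})$, then
  $y^{\mathrm{mis}} \sim N(X\beta^*, \sigma^{2*})$. This is exact under the
  conventional noninformative prior.
* **Logistic / multinomial / negative binomial**: large-sample draws
  $\beta^* \sim N(\hat\beta, \hat V)$ at the MLE (the multinomial fitter is
  a baseline-category logit maximised by BFGS with analytic gradient;
  covariance from the numerical Hessian). The source text calls
  $\varphi_j$ a "parameters prior" without naming a posterior family; the
  package resolves this as standard approximate proper imputation rather
  than fully conjugate Bayes, which only exists cleanly for the linear case.
* **Predictive mean matching** (option for counts or non-normal continuous
  targets): type-1 matching — donors ranked by $|\hat y_i^{obs} -
  x_j'\beta^*|$, one of the `pmm_k = 5` closest sampled uniformly. Ties in
  predicted values are broken by the (stable) order step; imputed values are
  always members of the observed support.
* **Negative-binomial draws** (default for counts, matching the analysis
  family chosen for the frequency-of-abuse application): mean
  $\exp(X\beta^*)$, dispersion $\alpha^* = \exp(\mathrm{lnalpha}^*)$ with
  lnalpha drawn from its delta-method normal approximation.

Missing cells are initialized at $t = 0$ by resampling observed values of
their own column (the source is silent; this is the common default and only
affects transient iterations). With exactly one incomplete variable — every
application shipped here — each sweep refits on the same observed rows, so
the draw at $T = 1$ already has the stationary distribution; $T$ matters
only for multi-variable chains. Convergence is *reported*, not tested:
per-variable mean/sd traces by iteration are stored in
`run_mice()$diagnostics`, since the source asserts convergence at $t = T$
without stating a criterion.

Two engine-level numerical policies:

* Design columns that are **constant on the observed rows** (for instance
  the dummy of a comparison-vector category with zero donor support) are
  inestimable and are dropped from that conditional; imputation for such
  rows proceeds at the reference-level behaviour, and `fuse()` has already
  raised an extrapolation warning naming the category.
* `fit_negbin()` flags a **boundary** fit when the estimated
  extra-dispersion factor $\hat\alpha \bar\mu < 0.05$ (variance within 5% of
  Poisson): lnalpha is then reported as $-\infty$ with no SE rather than a
  meaningless large-negative number with a huge SE.

## Pooling and validation regressions

Each analysis (OLS, logistic, NB2 — classical, non-robust SEs, matching the
reported tables, with categorical predictors reference-coded as named
`variable=level` dummies) is fitted on every completed dataset and combined
by Rubin's rules: $\bar Q$, within-variance $W$, between-variance $B$,
$T = W + (1 + 1/m)B$, with Barnard–Rubin small-sample degrees of freedom and
two-sided $t$ p-values. The source never states its combining procedure;
Rubin + Barnard–Rubin is the field standard and is what the significance
stars (`*** < 0.001`, `** < 0.01`, `* < 0.05`) in the synthetic column are
computed from. By construction $T \ge W$, which is the mechanism behind the
headline empirical finding that fused analyses are more conservative than
donor complete-data analyses.

The NB2 dispersion is reported as lnalpha (variance $\mu + \alpha\mu^2$),
pooled like any coefficient when finite; `select_count_family()` fits
Poisson and NB2 and recommends by joint AIC/BIC, reporting disagreement
rather than resolving it silently.

## What the synthetic generator emulates — and what it does not

The restricted survey and service datasets are represented by two
`population_profile()`s whose config files carry the published descriptive
statistics verbatim: category probabilities for eight categorical
comparison-vector variables, (mean, sd) for age and number of dependants,
default sizes 1,232 (survey-like) and 6,102 (service-like). Choices the
published numbers do not determine:

* **Independence.** Only marginals are published, so covariates are drawn
  independently by default. A `dependence` hook accepts user-supplied
  child-given-parent category tables, but no dependence structure is claimed
  from the source.
* **Age** is a left-truncated (at 16, the eligibility floor, inclusive)
  normal rounded to whole years. The profile states the *observed*
  mean/sd, so the latent normal is moment-matched such that the truncated
  distribution reproduces them exactly; naive truncation of the stated
  normal would inflate the mean by ~2 years and fail any calibration check.
* **Dependants** is a moment-matched negative binomial (Poisson when the
  stated variance does not exceed the mean).
* **Outcomes** follow the generative linear predictor $X\beta + D\gamma$
  with family noise; the shipped models take $\beta$ from the published
  donor-survey regression columns. The gaussian residual variance is not
  published; $\sigma^2 = 121$ (sd 11 years) was chosen once to reproduce the
  scale of the published standard errors and is not revisited.
* **Clustering.** Repeat service users exist in the real data (6,102
  referrals from 5,333 individuals) but the published analysis is
  referral-level; `cluster_rate` defaults to 0, and cluster-level
  covariates $D_j$ are carried as data, never modelled.

A green calibration test therefore establishes that the generator reproduces
the published *marginals* and that the pipeline recovers *its own*
generative structure — not that the generator reproduces the real datasets'
joint distribution, nonresponse mechanisms, survey design (weights are never
used), or temporal structure (time is deliberately not a comparison-vector
variable).

## Fusion-level design decisions

* **Stacked fitting.** Conditionals are fitted on the stacked A+B file; with
  the target fully missing in A the observed rows are exactly B, so this is
  equivalent to fitting on the donor alone, and it generalizes correctly to
  partially missing targets.
* **Source indicator excluded** from predictors: with unit missingness its
  coefficient is unidentified.
* **Main effects only**, mirroring the additive validation regressions; no
  interactions are imputed-on by default.
* **Direction swap** (`direction_swapped`) exchanges donor and recipient —
  the robustness exercise; the fused size then equals the new recipient's n,
  and pooled SEs grow, reproducing the reported asymmetry between the
  6,102- and 1,232-row directions.
* The three-column comparison table renders estimate+stars with SEs in
  brackets beneath, CSV round-trips at full double precision, and the
  concordance report (sign agreement, star agreement, mean absolute
  relative difference with an $\varepsilon = 10^{-8}$ denominator guard,
  significance flips) operationalizes "the fused data mimic the donor".

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `m` | 10 | datasets | unstated in the source; common MI practice, configurable |
| `maxit` (T) | 10 | sweeps | unstated; irrelevant for single-target fusion (see above) |
| `pmm_k` | 5 | donors | standard PMM pool size |
| `cluster_rate` | 0 | probability | referral-level analysis |
| `sigma2` (age model) | 121 | years² | matches published SE scale |
| visit order | schema order | — | immaterial for one incomplete variable |
| stars | 0.05 / 0.01 / 0.001 | p | the tables' footnote |

Every seed in the package flows through one utility that derives child
streams deterministically, so `(inputs, seed)` reproduce any artifact
bit-identically; pipeline manifests store the seeds they used.

## Known limitations

* Validity rests on the look-alike (conditional exchangeability) assumption:
  given C, the target's law is the same in both populations. It is
  untestable from the data being fused; the package surfaces its observable
  proxies (covariate-support warnings, concordance metrics) instead.
* The approximate normal draws for non-gaussian conditionals understate
  parameter uncertainty slightly at small donor sizes.
* Categorical harmonization ships only the publicly stated recodes; real
  source systems need their full code inventories added to the JSON rules
  (the cell-level mapping table of the original application is not public).
* Structured configs are JSON rather than YAML, as no YAML parser is
  available in the supported dependency set.
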