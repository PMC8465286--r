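---
title: "Principal-component logistic regression for insurance-strata health surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal-component logistic regression for insurance-strata health surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pclr)
```

## The problem

Adults in US states that did not expand Medicaid can fall into a coverage
gap: aged 18–64, income below the eligibility line, no private insurance and
no Medicaid. `pclr` implements a reusable version of a PCA-based logistic
regression ("PCA-LA") analysis of self-reported health status in BRFSS-style
categorical telephone-survey data, comparing three insurance strata
(above-poverty, traditional Medicaid, Medicaid gap) under four model
scenarios. Categorical predictors are strongly inter-correlated in such
surveys; fitting the logistic model on principal-component scores and
back-transforming the coefficients controls that multicollinearity while
keeping the report in the original variable space.

## The model

Respondent answers are mapped to small-integer codes by a declarative
codebook and standardized column-wise to $X^*$ (mean 0, sd 1; sample,
$n-1$, convention by default — the choice is recorded on the object so tests
can pin it). With $R$ the predictor correlation matrix and
$R = V \Lambda V'$ its eigendecomposition, the unrotated loadings are
$L = V\Lambda^{1/2}$ and $r$ components with eigenvalue strictly above 1 are
retained (Kaiser rule). A varimax rotation with Kaiser normalization is
applied to the retained columns, and component scores are

$$Z_j = \sum_i l_{ij} X_i^*,$$

the literal loading-weight definition. The binary health-status outcome
($1$ = good, $0$ = fair/poor) is modelled by maximum-likelihood logistic
regression (IRLS, log-likelihood tolerance $10^{-8}$, at most 100
iterations) on the $r$ scores, giving slopes $a$ with covariance
$\mathrm{Cov}(a)$ from the inverse observed information. Coefficients are
mapped back to variable space by

$$\lambda = L\,a, \qquad \mathrm{Cov}(\lambda) = L\,\mathrm{Cov}(a)\,L',$$

with Wald statistics $\mu_i = \lambda_i / \sqrt{\mathrm{var}(\lambda_i)}$
and two-sided normal p-values. (The source prints the Wald statistic as
$\lambda/\mathrm{var}(\lambda)$; since it is called a Wald test and reported
with conventional confidence intervals, we treat the missing square root as
a typo.) The odds ratio of level $k$ of variable $i$ against its referent
level is

$$\mathrm{OR}_{ik} = \exp\!\big(\lambda_i\,(c_k - c_{\mathrm{ref}})/s_i\big),$$

where $c$ are the level codes and $s_i$ the standardization sd — the
standardized-contrast rule, chosen because it collapses to the direct
logistic odds ratio when all components are retained and preserves monotone
level ladders.

### Why loading weights rather than regression weights

Regression-method score weights $W = R^{-1}L$ give rotated scores that are
exactly uncorrelated, which is aesthetically attractive. But they break the
package's strongest internal oracle: with $Z = X^*W$ the induced
variable-space coefficient of a component fit is $Wa$, so the loading-based
back-transformation $\lambda = La$ would return $R\,b$ rather than the
direct coefficient vector $b$ under full retention. With loading weights
($W = L$), $\lambda = La$ **is** the induced variable-space coefficient for
any $r$ and any orthogonal rotation, and the full-retention equivalence test
passes at $10^{-6}$. We therefore default to loading weights;
`component_scores(method = "regression")` remains available (its scores are
exactly orthogonal even after rotation, and `back_transform()` then uses the
same weight matrix so the two stay consistent). Unrotated loading-weight
scores are exactly uncorrelated in either case.

## Pipeline stages and tunable parameters

1. **Screening.** Pairwise Pearson correlations on the ordinal codes (a
   documented approximation; no polychoric correction) with exact-t
   p-values. A predictor is eliminated when it has fewer than `min_links`
   significant correlations with the other predictors (default: half of
   them). The published elimination of SEX/RACE/EM/CVD/DT is not always
   reproduced by that stated rule on pooled samples — stratum composition
   differences alone induce significant correlations — so the pipeline also
   accepts an explicit retained-variable override and defaults it to the
   published nine (`reference_retained_predictors()`). The screen is run
   pooled, matching the single published correlation table.
2. **Adequacy.** KMO from the anti-image partial correlations and
   Bartlett's sphericity $\chi^2 = -(n-1-(2p+5)/6)\ln\det R$. The source
   text is self-contradictory about its own KMO cutoff (0.56 reported as
   "more than" 0.7), so the package reports the statistic against a
   configurable cutoff and takes no side. On degenerate inputs (tiny
   cohorts) the diagnostics are skipped with a warning rather than aborting
   the run.
3. **Extraction and rotation.** Eigenvalue retention threshold 1.0
   (strict), varimax with Kaiser normalization on, criterion tolerance
   $10^{-10}$, at most 1000 pairwise-rotation sweeps; a deterministic sign
   convention (largest-magnitude loading per column positive) removes
   eigenvector ambiguity. Communalities below 0.7 produce warnings, never
   automatic exclusion (the source itself retains variables below its own
   cutoff); `communalities(enforce = TRUE)` exposes the offenders for
   callers that want to drop them. The published "after six iterations" is
   incidental SPSS output, not a reproduction target. PCA is pooled by
   default with per-stratum regressions (one published loading table, three
   scenario fits); `pca_mode = "per_stratum"` is available.
4. **Scenarios.** Per stratum: per-variable dummy fits (unadjusted), one
   all-variable dummy fit (adjusted), per-component score fits reported
   through the back-transformation (PCA-unadjusted; each variable is
   reported via the component it loads highest on — the source does not
   state the convention, and a per-component refit mirrors the unadjusted
   direct convention), and the all-component fit (PCA-adjusted). Stars
   follow the published footnote: `*` for p < 0.001, `**` for p < 0.05.
   Separation and non-convergence are detected (diverging coefficients,
   bound 15 on standardized inputs) and downgrade the affected block to a
   flagged "degenerate" row — the published tables print `0.0 [0.0, 0.0]`
   in such cells; we refuse to print a numeric 0 for an undefined estimate.
   The 0.6 classification threshold of the source plays no role in its
   printed results; it is exposed only through `classify()`.
5. **Validation.** Per component, pooled- and Welch-variance two-sample
   t-tests against the outcome grouping and a one-way ANOVA with the
   group-size-weighted linear-trend decomposition of the between-group sum
   of squares. The published F-table's grouping variable (716 between-group
   df) is unidentifiable from the text, so the grouping is an explicit
   argument defaulting to health status.

## The synthetic world

Published individual-level data are not deposited, so every test runs on a
generator whose defaults state the world once: three strata in the published
54,754 / 4,615 / 3,714 proportions (scaled to a 50,000 total); nine ordinal
predictors driven by four independent standard-normal factors through a
block loading matrix (two strong loadings of 0.85–0.90 per factor,
cross-loadings at or below 0.25, one deliberately low-communality variable),
discretized ordered-probit style against cutpoints fitted to the published
per-stratum category marginals; five independent noise predictors standing
in for the eliminated SEX/RACE/EM/CVD/DT; and a logistic outcome on the true
factor scores with coefficients $(0.4, -0.5, -0.6, -0.25)$ — signs matching
the published narrative (health-condition burden positively associated with
the good-health coding; education, age and marital-status codes negatively)
— and per-stratum intercepts calibrated by a one-dimensional Gaussian
integral to the published health-status prevalences (67.3% / 82.1% / 27.5%).
Stratifier fields are drawn so that `classify_insurance()` reproduces the
intended stratum for every record.

Discretization attenuates Pearson correlations, so the latent loading matrix
is *not* what component extraction on coded data estimates. The recovery
ground truth is therefore the varimax solution of the analytic code-scale
correlation matrix, computed by numerical integration of bivariate-normal
rectangle probabilities pooled across strata (`truth()$analytic_R`,
`truth()$expected_rotated_loadings`). What the generator does **not**
emulate: BRFSS design weights, nonresponse and missingness patterns, within-
stratum income/age confounding with the predictors, and measurement
misclassification. A green recovery test therefore establishes correctness
of the estimation machinery under the stated factor model, not fidelity of
the published coefficients.

## Numerical choices and degenerate inputs

* Sample correlation matrices are used throughout; standardization errors
  out on constant columns, naming the variable.
* `fit_logistic` requires both outcome classes and more observations than
  coefficients; quasi-separation raises an error naming the worst column.
* Ties in the varimax column ordering are broken by explained variance,
  then by the sign convention; `r = 1` solutions skip rotation entirely.
* Eigenvalue clustering at the retention threshold (near-identity
  correlation) triggers an instability warning by design.
* The income schedule is the published 35,000 / 47,000 two-point schedule,
  extended linearly (+12,000 per additional household member) because no
  further points are published; the schedule is an argument.
* The Medicaid-gap age window uses raw `age_years`, never the 4-level AS
  code.
* Missingness is handled by complete-case deletion (the source admits
  missing data and states no imputation).

## Known limitations

Plain Pearson on ordinal codes underestimates latent associations; the
published stratum counts are internally inconsistent between two of its own
tables (the pipeline reports its own counts and does not reconcile them);
the published LDC communality is inconsistent with its printed loadings (the
acceptance suite asserts the inconsistency rather than hiding it); and no
survey weighting is implemented. None of these affect the package's internal
correctness guarantees, which are established by the oracle-backed test
suite (`tests/testthat/`), not by agreement with the published coefficient
tables.
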