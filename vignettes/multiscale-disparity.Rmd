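---
title: "Multiscale GWR and the three dimensions of geographic disparity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale GWR and the three dimensions of geographic disparity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgwrdim)
```

## The problem

Ecological health-disparity studies ask how county-level characteristics --
demographic composition, clinical burden, deprivation -- relate to an outcome
rate such as opioid use disorder diagnoses per 1,000 beneficiaries. A single
global regression assumes each association is identical in every county.
That assumption fails in two distinct ways: an association can vary over
space (non-stationarity), and different covariates can vary at different
spatial scales (a clinical risk score may act within a commuting region
while a demographic share acts identically nationwide). `mgwrdim`
implements the modeling chain that separates these effects and then
classifies each covariate's disparity along three dimensions.

## Models

### GWR

Geographically weighted regression fits, at every unit $i$ with coordinates
$u_i$,

$$y_i = \sum_j \beta_j(u_i)\, x_{ij} + \varepsilon_i,
\qquad
\hat\beta(u_i) = (X^\top W_i X)^{-1} X^\top W_i y,$$

where $W_i$ is diagonal with adaptive bisquare weights
$w_{im} = \left(1 - (d_{im}/b_i)^2\right)^2$ for $d_{im} < b_i$ and $0$
otherwise, and $b_i$ is the distance from unit $i$ to its $k$-th nearest
unit (self included at distance 0, weight 1). The neighbor count $k$ is the
*bandwidth*; an adaptive (nearest-neighbor) rule keeps the effective sample
comparable where units are irregularly spaced. Ties exactly at $b_i$ receive
weight 0 -- the kernel support is open at $b$. Rows of the hat matrix are
$x_i^\top(X^\top W_i X)^{-1}X^\top W_i$; the trace $\mathrm{tr}(S)$ is the
model's effective number of parameters.

All models share one complexity-corrected criterion,

$$\mathrm{AICc} = 2n\log\hat\sigma + n\log 2\pi +
n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)}, \qquad
\hat\sigma^2 = \mathrm{RSS}/n,$$

with $\mathrm{tr}(S) = k+1$ for OLS, so OLS, GWR and MGWR are compared on
one scale. Bandwidth selection minimizes AICc by golden-section search over
integer neighbor counts; narrow ranges ($\le 50$ candidates) are scanned
exhaustively, the converged golden-section bracket ($\le 20$ wide) is always
scanned exhaustively, and ties return the smallest minimizer, so the search
is deterministic and, on unimodal profiles, exact.

### MGWR

Multiscale GWR relaxes the single-bandwidth assumption: the model becomes
additive, $y = \sum_j f_j + \varepsilon$ with $f_j = \beta_j(u) x_j$ a
surface smoothed at its own bandwidth. `fit_mgwr()` calibrates it by
back-fitting:

1. initialize each $f_j$ from the global OLS fit (so purely global data is
   already a fixed point);
2. cycle over terms: form the partial residual
   $e_j = y - \sum_{l \ne j} f_l$, select the bandwidth of the univariate
   GWR of $e_j$ on $x_j$ by AICc, and update $f_j$;
3. stop when the score of change
   $\mathrm{SOC}\!-\!f = \sqrt{\overline{(f^{(t)}-f^{(t-1)})^2} \big/
   \overline{(f^{(t)})^2}}$ of the total fit drops below `tol`
   (default `1e-5`, `max_iter = 200`); then freeze the bandwidths for two
   final stabilizing sweeps.

Every term update is linear in $y$ given the bandwidth sequence, so per-term
hat matrices $R_j$ with $f_j = R_j y$ are propagated through the iterations.
Their traces are the per-variable effective numbers of parameters
$\mathrm{ENP}_j$, which sum to $\mathrm{tr}(S)$ exactly; local standard
errors come from the rows of $R_j / x_j$ scaled by
$\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{tr}(S))$. Local tests use a
critical value at the corrected level $\alpha_j = \alpha / \mathrm{ENP}_j$
(dependent-tests correction); a nominal-$\alpha$ policy is available by flag
because published significance maps do not always state which convention
they use. The intercept is treated as a term like any other, with its own
bandwidth and surface. Variables are standardized throughout, so local
coefficients are comparable across variables and units.

Non-convergence at `max_iter` is carried as a status flag (with a warning),
not an error, so long runs can be inspected rather than lost.

### Monte Carlo test for non-stationarity

For each variable the observed statistic is the variance of its local
coefficients across units. Under the null of a flat surface, any assignment
of coordinates to units is equally likely, so the null distribution is built
by shuffling coordinates among units while holding the data fixed and
re-calibrating with bandwidths frozen at their fitted values; the p-value is
the add-one estimator $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$,
bounded below by $1/(B+1)$. Two implementation choices matter:

* **Bandwidths are held fixed under permutation.** Re-selecting bandwidths
  inside every permutation multiplies cost by the search depth while testing
  the same null; holding them fixed is a deliberate convenience deviation.
* **Permutation by re-indexing.** Shuffling coordinates only permutes the
  inter-unit distances, so the kernel weight matrix of a permuted dataset is
  exactly `W[perm, perm]` of the original. Weight matrices are built once
  per bandwidth and re-indexed per draw; a test verifies the equivalence
  against a from-scratch rebuild.

### The three dimensions

From a fitted MGWR, `dimension_report()` classifies each covariate:

* **Level of influence** -- the share of total population living in units
  where the local estimate is significant; $> 50\%$ makes the variable a
  *primary* influencer, otherwise *secondary*.
* **Scalability** -- the fitted bandwidth relative to the number of units
  $n$: above $0.75\,n$ *global*, below $0.25\,n$ *local*, the closed
  interval between *regional*. The wording "between 75 and 25 percent" is
  read as the closed interval $[0.25n,\ 0.75n]$; both boundaries are
  covered by unit tests, and `scalability_conflict()` flags any externally
  reported label that contradicts the rule rather than silently adopting it.
* **Specificity** -- within each unit, the covariate with the largest
  absolute standardized local coefficient, regardless of sign and of
  significance. Dominance is computed over *all* covariates because the
  published counts it mirrors partition every unit; ties break by column
  order and are logged. The intercept is excluded from influence and
  specificity but listed with its scalability class.

## Composite indices

`pca_index()` builds first-principal-component indices on the correlation
matrix (inputs mix percentages and logged dollars, so covariance PCA would
let units of measurement drive the loadings -- the correlation choice is
ours; the convention is not always stated in applied work). The component's
sign is fixed semantically by an *anchor* input whose loading must be
positive (e.g. poverty share for a deprivation index), loadings are reported
as input-score correlations, and the leading eigenvalue share is reported as
`variance_explained`. `mean_index()` averages standardized columns
(residential-stability style). Constant inputs are degenerate errors, not
silent NaNs.

## The synthetic generator

Real unit-level claims data are access-restricted, so validation runs on
synthetic datasets whose true local coefficients are known. Coefficient
surfaces come in three archetypes matching the scale taxonomy the classifier
is supposed to recover: `constant` (global), planar `gradient` (regional)
and compact bisquare `bump` (local). Covariates are drawn with exchangeable
correlation and z-scored; populations are log-normal rounded with floor 1
(county-like right skew, needed to exercise population-weighted influence
shares); noise is i.i.d. Gaussian, matching the model form.

The default preset (`synthetic_preset()`) uses $n = 400$ units uniform in
the unit square, six covariates (two constant $\pm$, two gradients of range
$\approx \pm 0.5$, two bumps of height $1.5$ and $-1.2$), correlation 0.3
and noise SD 0.3 -- amplitudes chosen so each term contributes comparably to
the outcome variance and the three scales stay separable at a desk-scale
$n$. Validation problem sizes ($n = 400$ for recovery, $n = 150$ with 99
permutations and 40 replicates for Monte Carlo calibration, $n = 300$ over
10 seeds for scale-class recovery, gradient slope 0.6 where the regional
scale must stay identifiable) are the package's own validation design.

What the generator does **not** emulate: real US county geography and
adjacency, spatially autocorrelated noise, non-Gaussian or sparse outcomes,
and measurement error in covariates. Passing recovery tests therefore shows
the estimator works when its model holds; it does not certify performance on
claims data.

## Numerical choices and edge cases

* Local solves use the Cholesky factorization of $X^\top W X$; a singular
  local design raises an error carrying the unit id (and variable context in
  MGWR) rather than producing silent NaNs.
* Self-weight is 1 by construction; duplicated coordinates (bandwidth
  distance 0) are rejected at data assembly.
* Local SEs divide hat-matrix rows by $x_{ij}$; where a covariate value is
  numerically 0 the SE is infinite and the unit is simply never significant
  for that variable.
* `standardize()` uses the sample SD ($n-1$) everywhere.
* Distances are planar Euclidean by default and haversine kilometres when
  coordinates are lon/lat (GeoJSON input or lon/lat column names), since
  applied county studies rarely state their metric.
* Dense $n \times n$ distance and weight matrices are used throughout --
  at the target scale ($n \le 5{,}000$) this is well within memory and far
  faster in R than sparse bookkeeping.

## Known limitations

* Back-fitting with per-term univariate smoothers is not algebraically the
  joint local WLS fit; with one covariate MGWR approaches, but does not
  exactly equal, single-bandwidth GWR (they agree near the global limit).
* The Monte Carlo test's fixed-bandwidth recalibration slightly understates
  bandwidth-selection uncertainty; in calibration runs it is conservative
  under the null.
* Local multicollinearity among MGWR terms is not diagnosed beyond the
  global VIF report.
* The outcome is treated as continuous; rate outcomes that are highly
  skewed or sparse are outside the model family.
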