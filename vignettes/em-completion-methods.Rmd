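---
title: "EM completion of solvent property tables: model, algorithm, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EM completion of solvent property tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emimpute)
```

## The model and its assumptions

A solvent screening table is an $n \times p$ matrix of descriptors — here
$p = 13$: eight physicochemical variables and five
toxicity/biodegradability/bioaccumulation endpoints — with missing cells
concentrated in the endpoints, which are expensive to measure. `emimpute`
models a row, after transformation, as a draw from a multivariate normal
$N(\mu, \Sigma)$ and assumes the missingness mechanism is ignorable
(MCAR/MAR): whether a cell is missing may depend on observed values but not
on the missing value itself. Under ignorability the observed-data likelihood
is valid for $\Psi = (\mu, \Sigma)$ and factors over the $G$ groups of rows
that share an observed-column set,
$$\log L(\Psi) = \sum_{g=1}^{G} \log L_g(\Psi), \qquad
  L_g(\Psi) \propto |\Sigma_g|^{-n_g/2}
  \exp\Big\{-\tfrac12 \sum_{i=1}^{n_g}
  (y_{ig}-\mu_g)^\top \Sigma_g^{-1} (y_{ig}-\mu_g)\Big\},$$
with $(\mu_g, \Sigma_g)$ the margin of $(\mu, \Sigma)$ on the group's
observed columns. The package always includes the $(2\pi)$ normalization
constant, so `mvn_loglik()` is the exact log-density of the observed data;
the constant does not affect the stopping rule but makes the value directly
comparable to any independent density evaluation, which is how the test
suite checks it.

Multivariate normality is an approximation for real property data. Five
heavy-tailed, strictly positive variables (Henry's law constant, oral LD50,
inhalation LC50, fish LC50, BOD half-life) are natural-log transformed first
(`to_model_space()`); variables already reported on a log10 scale (log KOW,
log KOA, log BCF) are left alone. Natural log is used because the package
treats the transformed scale as the model space throughout and reports
fitted endpoint means on it; transformed means around 7.6 (oral LD50) and
8.3 (inhalation) correspond to geometric means near 2000 mg kg$^{-1}$ and
3900 ppm, which is the right order for screening collections of this kind —
a base-10 transform would put them near 3.3 and 3.6.

### The sentinel rule

Some compounds lack an inhalation LC50 because they are not volatile enough
to be inhaled at toxic concentrations, which is informative — not ignorable
— missingness. `apply_sentinels()` encodes the standard expert judgment:
such cells are set to 5001 ppm, just above the 5000 ppm cut-off under which
a chemical is classified "harmful if inhaled", and marked observed. The flag
is an explicit per-row input rather than a heuristic on vapor pressure,
because the judgment of non-volatility belongs to the analyst, not the
package. Applying the sentinel before fitting removes those cells from the
ignorability assumption.

## The algorithm

`em_mvn()` iterates:

* **E-step** (`em_estep()`): for each missingness pattern, factor the
  observed block $\Sigma_{oo}$ once and, for every row of the pattern,
  replace the missing components by the conditional mean
  $\mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(y_o - \mu_o)$, adding the
  conditional covariance $\Sigma_{mm} - \Sigma_{mo}\Sigma_{oo}^{-1}
  \Sigma_{om}$ (the Schur complement) to the second-moment accumulator.
  This partitioned form was chosen over the sweep operator because every
  intermediate is a textbook conditional-normal quantity that the tests can
  compare against closed forms.
* **M-step** (`em_mstep()`): $\hat\mu = T_1/n$,
  $\hat\Sigma = T_2/n - \hat\mu\hat\mu^\top$ — the complete-data MLE with
  denominator $n$, since EM maximizes the likelihood. The starting values
  deliberately differ: available-case means and *sample* standard
  deviations ($n-1$) with correlations set to zero, matching the standard
  available-case initialization; the asymmetry is intentional and only
  affects the starting point.
* **Stopping**: after each M-step the observed-data log-likelihood is
  recorded; iteration stops when
  $L(\Psi^{(k+1)}) - L(\Psi^{(k)}) < \mathtt{tol}$ (default $10^{-4}$), or
  after `max_iter` (default 500) iterations with `converged = FALSE` and a
  warning. Because the trace is monotone for EM, the signed difference
  equals the absolute one. On complete data the first M-step already lands
  on the closed-form MLE and the first convergence check fires.

Imputation (`predict()` / `conditional_impute()`) is a single
conditional-mean fill under the fitted parameters — deterministic, no noise
draw and no multiple imputation, which matches the use case of publishing
one completed reference table. Back-transformed endpoint values
(`from_model_space()`) are plain exponentials with no lognormal
$+\sigma^2/2$ bias correction: the completed values are intended as
typical (geometric-scale) magnitudes, and a correction would make them
inconsistent with the observed cells around them. This understates
arithmetic means of skewed variables; users averaging completed raw-scale
values should know they are closer to medians than to means.

## Numerical choices

* **Scaled factorizations.** The 13 descriptors span roughly twelve orders
  of magnitude in variance (water solubility vs density), so every observed
  block is factored in correlation scale: $\Sigma_{oo} = D C D$ with
  $D = \mathrm{diag}(\sqrt{\sigma_{ii}})$, and the Cholesky factor of $C$
  drives all solves. The near-singularity guard — fail if the scaled
  block's condition estimate exceeds $10^{12}$ — is therefore invariant to
  units; a raw-scale threshold would reject well-posed problems that merely
  mix Pa with g cm$^{-3}$.
* **No silent regularization.** A near-singular block is an error by
  default, with `ridge = TRUE` opting into a tiny
  $10^{-8}\,\mathrm{tr}(\Sigma)/p$ diagonal inflation. Regularizing
  silently would corrupt the oracle comparisons in the tests.
* **Degenerate inputs.** Rows with zero observed cells and columns with
  fewer than two observed values are hard errors before fitting — both
  leave a margin of $\Psi$ unidentifiable, and proceeding would only defer
  the failure to a less informative place.
* **M-step PSD check.** The updated covariance is symmetrized and its
  smallest eigenvalue must be $\ge -10^{-8}\lambda_{\max}$; EM cannot
  produce an indefinite update except through floating-point error, so a
  violation indicates a numerical problem worth stopping for.

## Diagnostics

**PCA** (`pca_completed()`) eigendecomposes the *correlation* matrix of the
completed data by default. With variables spanning many orders of magnitude,
covariance PCA would load everything on water solubility; correlation PCA is
the only standardization under which loadings are comparable across
descriptors. A `use = "covariance"` switch exists for completeness. Signs
are fixed by making each component's largest-magnitude loading positive,
explained proportions are eigenvalues over their sum, and the analysis runs
on the completed matrix in model space, i.e. after imputation.

**Mardia's kurtosis test** (`mardia_kurtosis()`) computes
$b_{2,p} = \frac1n \sum_i d_i^2$, $d_i$ the Mahalanobis distance under the
$n$-denominator covariance, standardizes by the asymptotic null moments
($\mathbb E = p(p+2)$, $\mathrm{Var} = 8p(p+2)/n$) and reports a two-sided
normal p-value. Applied after conditional-mean imputation it is
approximate: imputed cells sit exactly on the regression surface and shrink
the tails, so the test is conservative there. Columns are standardized
internally (Mahalanobis distances are affine invariant), again for scale
robustness.

**Bootstrap** (`bootstrap_means()`) resamples rows — cases, not cells —
with replacement, reruns the entire EM fit per resample, and reports each
variable's bootstrap mean, standard error and `mean_error` = bootstrap mean
− full-data estimate, interpreted as a bias estimate. Everything is on the
model scale (log-transformed endpoints on the log scale, other variables in
native units), mixing scales exactly as the fitted mean vector does.
Resamples on which the fit is infeasible are redrawn with a logged count
and a $10B$ redraw cap; `seed` is a required argument so the whole result
is a pure function of `(data, B, seed, tol, max_iter)`.

## The synthetic generator: what it emulates, what it does not

`study_shaped_spec()` fixes the validation conditions once:
$n = 155$, $p = 13$, 85 fully observed rows, MCAR deletion restricted to
the gap-prone columns with per-column rates equal to the study's
missing-value counts divided by the 70 incomplete rows (expected missing
counts 3, 2, 3, 35, 46, 57, 62, 4 for melting point, Henry's law constant,
log KOA and the five endpoints respectively), means and standard deviations
at the reported magnitudes of the real collection (log-flagged variables on
the log scale), and a single-factor correlation structure with loadings 0.5
(pairwise $r = 0.25$) — enough correlation for imputation to be
informative, far from singular. `simulate_mvn_missing()` enforces the
fitting preconditions ($\ge 1$ observed cell per row, $\ge 2$ per column)
by bounded redraws of the offending rows' deletions.

What passing tests on this generator show: the estimator recovers $(\mu,
\Sigma)$ at the advertised rates, the likelihood is computed correctly, the
imputations are the conditional means, and the full pipeline holds together
at the study's shape. What they do not show: robustness to real data's
departures from normality (multimodality across chemical classes, skew
remaining after the log transform), to informative missingness beyond the
sentinel rule, or to outliers — the generator is exactly the model, so it
cannot probe model misfit. The Mardia test exists precisely because real
tables should be checked rather than assumed normal.

Validation problem sizes were likewise fixed once: parameter recovery uses
50 replicates of $n = 500$, $p = 5$ with unit variances, pairwise
correlation 0.5 (covariance condition number 6) and 20% MCAR; Mardia
calibration uses 500 null replicates at $n = 200$, $p = 4$ and a 3-df
multivariate-$t$ alternative at $n = 2000$; the end-to-end run uses the
study shape with $B = 200$ bootstrap resamples. These sizes give the
Monte-Carlo bands quoted in the tests while keeping a full suite run around
twenty seconds.

## Known limitations

* Single imputation understates uncertainty: completed cells carry no
  variance, so downstream statistics on the completed table are
  anti-conservative. The bootstrap quantifies uncertainty of the *means*
  only.
* Conditional-mean fills are shrunk toward the fitted regression surface;
  the completed table's covariance is biased low in the imputed margins.
* The normal model is fitted to a mixture of chemical classes; a
  class-conditional or mixture model could fit better but needs more
  complete data per class than screening tables usually have.
* The sentinel value (5001) enters the likelihood as a genuine observation
  on the log scale; with many sentinel rows this creates an artificial
  point mass that the normality diagnostics will (correctly) flag.

## Session info

```{r}
sessionInfo()
```
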