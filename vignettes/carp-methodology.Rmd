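---
title: "Detecting multidimensionality in binary item responses with the CARP test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multidimensionality in binary item responses with the CARP test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carptest)
```

## The problem

Nonparametric item response theory models a set of binary items
$X_1, \dots, X_J$ through the monotone homogeneity (MH) model: a single
latent variable $\Theta$, conditional independence of the items given
$\Theta$, and response probabilities $P(X_i = 1 \mid \Theta)$ that increase
in $\Theta$.  MH implies *conditional association* (CA): for any split of
the items into two parts and any function $h$ of one part, any two monotone
summaries of the other part covary nonnegatively given $h$.  The widely
used partial checks of CA — nonnegative covariances, nonnegative partial
correlations, MTP$_2$-type conditions, manifest monotonicity — are also
implied by *multidimensional* monotone factor models (MFMs) with
independent factors and simple structure, so they cannot tell a
unidimensional scale from a multidimensional one.  Two independent Rasch
blocks, for instance, pass all of them.

The CARP test targets a family of CA inequalities that multidimensional
MFMs do violate: for a *focal pair* $(i, j)$,
$$\mathrm{Cov}\!\left[X_i, X_j \mid Q_m(\hat X_{ij} + \hat X_{ji})\right] \ge 0,$$
where $\hat X_{ij}$ is the population least-squares prediction of $X_i$
from all items except $X_i$ and $X_j$, $\hat X_{ji}$ likewise for $X_j$,
and $Q_m$ groups the summed prediction into $m$ near-equal-probability
layers.  The intuition: if $X_i$ and $X_j$ load on different independent
dimensions, $\hat X_{ij}$ and $\hat X_{ji}$ estimate those two dimensions,
and fixing their sum induces a negative dependence between the dimensions —
hence between $X_i$ and $X_j$ — inside layers.  Under any MH model the
weighted rest score is a function of $\mathbf X_{-ij}$ (the focal weights
are forced to zero), so CA guarantees nonnegativity and the test has a
one-sided null.

## The test procedure

`carp_pair_test()` implements the procedure in four stages:

1. **Split.** The $N$ subjects are partitioned at random into a training
   sample of $L = \mathrm{round}(\ell N)$ subjects and a test sample of
   $M = N - L$.  Defaults follow the simulation evidence: $\ell = .5$ for
   $N \le 500$, $\ell = .3$ otherwise, and $\ell = .2$ is a good choice
   for $N \ge 5000$.
2. **Weights.** On the training sample, each focal item is regressed (OLS)
   on the other $J - 2$ items; the focal coefficients are fixed at exactly
   zero.  Estimation error here costs power, never validity: the split
   guarantees the conditioning variable is independent of the test sample,
   so Type-I control holds *no matter how poor the weights are*.
3. **Layers.** The weighted rest score
   $\hat{\hat X}_{ij} + \hat{\hat X}_{ji}$ is computed on the training
   sample and its $m$-quantile separators are taken there (type-1
   empirical quantiles at probabilities $s/m$; duplicate separators are
   collapsed, so ties can shrink the effective $m$).  Test-sample subjects
   are assigned to layers by right-closed intervals
   $q_{s-1} < x \le q_s$.  The default $m = 10$ (deciles) had the best
   power among the variants examined in the original simulations.
4. **Test.** A one-sided Mantel–Haenszel statistic on the layered
   $2 \times 2 \times m$ table,
   $Z = (n_{11+} - e_+ + 0.5)/\sqrt{v_+}$, with the expectation $e_+$ and
   variance $v_+$ of $n_{11+}$ computed under the least favorable null
   (all layer covariances zero).  The p-value is the lower-tail normal
   probability of $Z$; small values mean some layer covariance is
   negative, i.e. evidence against unidimensionality.

```{r}
x <- simulate_responses(standard_case_bank(2, 2, 8), 5000, seed = 1)
carp_pair_test(x, 1, 3, ell = 0.2, seed = 1)
crs_pair_test(x, 1, 3)
```

`crs_pair_test()` is Rosenbaum's comparator: the same statistic with the
full sample layered by the observed values of the *unweighted* rest score
$\sum_{k \ne i,j} X_k$ ($J - 1$ possible layers, no split).  It is the
benchmark the CARP test converges to, from below, in balanced
two-dimensional designs as $N$ grows; the CARP test wins when the
dimensional structure is unbalanced ($J_1/J < .27$ or $> .73$) or when a
third dimension holds at least a third of the items.

### Numerical choices and degenerate inputs

* **Tied or collinear data.** OLS with constant or collinear predictors
  uses the minimum-norm least-squares solution, which fixes a unique,
  platform-stable coefficient vector where plain normal-equation solving
  would fail.
* **Degenerate layers.** A layer with fewer than two test subjects, or a
  zero row or column margin, contributes $0/0$ to the variance sum; such
  layers are excluded from $n_{11+}$, $e_+$ and $v_+$ alike (keeping them
  with zero contribution gives the identical $Z$; excluding them also from
  $n_{11+}$ keeps the three sums over a common set of layers).
* **No-decision outcomes.** If every training score is identical (no
  layering possible) or every layer is degenerate, the test returns a
  flagged no-decision rather than a silent $p = 1$; the study harnesses
  count no-decisions as non-rejections, which is conservative.
* **Continuity correction** is the fixed $+0.5$ of the statistic's
  definition.

## Testing many pairs

`carp_scan()` screens all $J(J-1)/2$ pairs on the training sample: a pair
enters the screening set $\mathcal S$ when its training-sample MH numerator
$n_{11+} - e_+$ (a weighted sum of layered covariances, no continuity
correction) is negative.  Weights and separators are estimated on the full
training sample and the numerator is evaluated on those same rows — the
family-wise error argument only requires that screening be a function of
the training sample, independent of the test sample, so no inner split is
needed and screening power is maximal.  Test-sample p-values are then
compared against $\alpha / |\mathcal S|$ (Bonferroni over the screened
set; Benjamini–Hochberg over $\mathcal S$ is available as the `method =
"BH"` alternative).  With positive population covariances most pairs never
enter $\mathcal S$, so the correction is far milder than Bonferroni over
all pairs.

## The simulator

`simulate_responses()` draws i.i.d. subjects under the multidimensional
logistic model
$P(X_i = 1 \mid \Theta) = \mathrm{logistic}(\sum_d \alpha_{id}\Theta_d + \beta_i)$
with independent standard-normal latent dimensions.  The study designs are
the package defaults, not tuning knobs:

* the **standard blocks** (`standard_case_bank()`): unit loadings, zero
  intercepts, simple structure with block sizes $(J_1, J_2, J_3)$;
* **random parameter sets** (`sample_parameter_set()`): intercepts
  $\beta_i \sim U(-1.5, 1.5)$ and free loadings
  $\alpha \sim U(0.5, 2.5)$, with structural zeros set by the
  zero-dimensional, unidimensional, or two-block design;
* the **zero-dimensional** case (all loadings zero) is the least
  favorable MH null — all layer covariances are exactly zero — and is
  therefore the design under which Type-I error is probed.

The generator emulates exactly these conditions and nothing more: latent
dimensions are uncorrelated (no higher-order factor structure), response
functions are logistic, and items are conditionally independent.  Passing
tests consequently says nothing about, e.g., locally dependent items or
correlated traits; on real data a CARP rejection rules out every
unidimensional monotone model but does not by itself identify which
assumption failed.

## The population oracle

`pattern_distribution()` computes the exact law of all $2^J$ response
patterns by tensor-product Gauss–Hermite quadrature (40 nodes per active
dimension by default; doubling the nodes moves no pattern probability by
more than $10^{-8}$).  From the pmf, `population_weights()` solves the
population normal equations and `conditional_correlation()` evaluates
focal-pair correlations in any union of score groups — the independent
oracle against which the simulator and the sample pipeline are tested.

`quantile_groups()` forms the $Q_m$ operator on a discrete score by a
greedy equal-mass rule: values are processed in ascending order, a group
accepts values only while its mass stays within its $1/m$ bound, and when
a group closes the next label advances with the cumulative mass (so labels
may be skipped and a single heavy value can hold a group alone).  The rule
keeps the extreme groups at mass $\le 1/m$ whenever possible, which is
what makes extreme-group conditioning sharp.  For two independent 5-item
Rasch blocks, the correlation of a cross-block pair inside the union of
the two extreme vigintile groups of $\hat X_{ij} - \hat X_{ji}$ evaluates
to $-.204$:

```{r}
pmf <- pattern_distribution(standard_case_bank(5, 5))
w <- population_weights(pmf, 1, 6)
d <- drop(pmf$patterns %*% (w$a_ij[-1] - w$a_ji[-1]))
g <- quantile_groups(d, pmf$probabilities, m = 20)
conditional_correlation(pmf, 1, 6, g, c(1, 20))
```

Alternative tie rules (e.g. assigning a boundary-straddling value to the
lower group) pull boundary mass into the extreme groups and attenuate this
correlation noticeably; the greedy rule is therefore declared once here
and used consistently.

## Study harnesses and problem sizes

`type1_study()` and `power_study()` reproduce the Monte-Carlo designs:
zero-/unidimensional parameter sets with 500–1000 replicates per set for
Type-I error (nominal $\alpha = .05$; mean rate about $.038$ at $N = 500$,
$\ell = .3$ — conservative because of the continuity correction and the
least-favorable-null variance), and the standard block designs at
$N = 5000$, $\ell = .2$ with 1000 replicates for power.  Replicate seeds
are derived as root seed plus replicate offset, so tables are
reproducible and independent of evaluation order.  The shipped test suite
and acceptance script run a grid of 3 item counts $\times$ 20 parameter
sets for the Type-I studies, a desk-scale version of the original
41 $\times$ 100 grid; the Monte-Carlo standard error at these sizes
($\approx .003$ per configuration, smaller after averaging) is quoted
alongside each comparison.

`ell_sweep()` plus `optimal_ell()` implement the training-fraction
calibration: power is estimated on a grid of $\ell$ values, a quadratic in
$\ell$ is fitted to the raw rates, and the vertex is reported.  The
quadratic is a smoothing device, not a model; a convex fit or a vertex
outside $(0,1)$ is reported as an error rather than clipped.

## Known limitations

* Only binary items; the polytomous extension of the inequalities is not
  implemented.
* One random split: repeated-split aggregation and compound statistics
  over multiple pairs (a $Z_{\mathrm{total}}$) are deliberately out of
  scope — the variance of a compound numerator over correlated pair
  statistics has no agreed estimator.
* The oracle enumerates patterns, so it is limited to $J \le 20$ and is
  practical well below that.
* Logistic response functions only, in both simulator and oracle.
* Focal-pair selection strategies based on exploratory factor analysis
  are not automated; power studies use the first item of each of the two
  focal blocks, which is exchangeable with any other cross-block choice
  in the standard designs.
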