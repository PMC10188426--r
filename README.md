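# carptest

Tests of unidimensionality for binary test items that can actually tell a
unidimensional scale from a multidimensional one.

## The problem

In nonparametric item response theory, a set of binary items is
*unidimensional* when it satisfies the monotone homogeneity (MH) model: one
latent variable, conditional independence, monotone item response
functions.  MH implies conditional association (CA), but the CA checks in
common use — nonnegative inter-item covariances, nonnegative partial
correlations, MTP₂-style conditions, manifest monotonicity — are equally
satisfied by *multidimensional* monotone factor models with independent
factors and simple structure.  Two independent Rasch blocks sail through
all of them.  `carptest` implements the CARP test (conditioning on added
regression predictions), which targets CA inequalities that
multidimensional structure does violate.

For a focal item pair (i, j), the CARP inequality is

    Cov[ X_i, X_j | Q_m( X̂_ij + X̂_ji ) ] ≥ 0,

where X̂_ij is the least-squares prediction of X_i from all items except
X_i and X_j (focal coefficients forced to 0), X̂_ji likewise for X_j, and
Q_m groups the summed predictions into m near-equal-probability layers.
The test estimates the weights and the layer boundaries on a random
training subsample (fraction ℓ), layers the held-out test subsample, and
applies the one-sided Mantel–Haenszel statistic

    Z = (n_11+ − e_+ + 0.5) / √v_+ ,

whose p-value is the lower-tail normal probability: small p means some
layer covariance is negative, which no unidimensional monotone model can
produce.  Because the conditioning variable is built entirely from the
training sample and excludes the focal items, the Type-I error rate is
controlled regardless of how well the regressions fit.

The package also provides Rosenbaum's CRS comparator (same statistic,
layered by the unweighted rest score, no split), screening of all item
pairs with a Bonferroni-on-screened-set multiplicity rule, the
multidimensional logistic simulator behind the published Type-I and power
studies, an exact population oracle (Gauss–Hermite quadrature over all 2^J
response patterns), and seeded Monte-Carlo study harnesses.

## Worked example

Ten items, two independent 5-item Rasch blocks — a textbook
multidimensional set that every covariance-sign check passes:

```r
library(carptest)
x <- simulate_responses(standard_case_bank(5, 5), 5000, seed = 42)

carp_pair_test(x, 1, 6, ell = 0.2, seed = 42)
#> CARP test, focal pair (1, 6)
#>   Z = -1.9658, one-sided p = 0.02466 (10 layer(s) used)

crs_pair_test(x, 1, 6)
#> CRS test, focal pair (1, 6)
#>   Z = -3.1632, one-sided p = 0.0007801 (9 layer(s) used)
```

The cross-block pair (item 1, item 6) shows a significantly negative
layered covariance (p = .025 at the default deciles), rejecting every
unidimensional monotone model for these items.  Scanning all 45 pairs with
the training-sample screen and Bonferroni correction over the screened set:

```r
carp_scan(x, ell = 0.2, seed = 42)
#> CARP scan: S = 20 screened pair(s), alpha = 0.05 (bonferroni)
#>   6 rejection(s):  (7,2) (8,2) (8,3) (8,4) (9,3) (10,2)
```

All six rejected pairs straddle the two blocks.  The exact population
analogue of what the test exploits can be computed with the oracle — the
correlation of a cross-block pair inside the two extreme vigintile groups
of the *difference* of predicted scores:

```r
pmf <- pattern_distribution(standard_case_bank(5, 5))
w <- population_weights(pmf, 1, 6)
d <- drop(pmf$patterns %*% (w$a_ij[-1] - w$a_ji[-1]))
g <- quantile_groups(d, pmf$probabilities, m = 20)
conditional_correlation(pmf, 1, 6, g, c(1, 20))
#> [1] -0.2043139
```

a strongly negative correlation between two items whose *marginal*
correlation is exactly zero.

A thin command-line front end over the same functions ships in
`inst/cli/carp.R` (`test`, `crs`, `scan`, `oracle` subcommands); see the
header of that file for usage.  The methods vignette
(`vignettes/carp-methodology.Rmd`) documents the model, the tuning
parameters (ℓ, m), the degenerate-input conventions, and what the
simulation designs do and do not emulate.

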