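#' Randomly split subjects into training and test samples
#'
#' @param n_subjects total sample size `N`.
#' @param ell training fraction in (0, 1); the training size is
#'   `L = round(ell * N)` (ties in rounding resolved downward).
#' @param seed optional integer seed.
#' @return Object of class `sample_split`: list with `train_indices`,
#'   `test_indices`, `L`, `M`, `ell`.
#' @examples
#' split_sample(10, 0.5, seed = 1)
#' @export
split_sample <- function(n_subjects, ell, seed = NULL) {
  if (length(ell) != 1L || is.na(ell) || ell <= 0 || ell >= 1) {
    carp_error("carp_invalid_parameter", "`ell` must lie strictly between 0 and 1")
  }
  n_subjects <- as.integer(n_subjects)
  L <- floor(ell * n_subjects + 0.5)
  if (abs(ell * n_subjects - floor(ell * n_subjects) - 0.5) < 1e-9) {
    L <- floor(ell * n_subjects)  # resolve exact .5 ties downward
  }
  L <- as.integer(L)
  if (L < 1L || L >= n_subjects) {
    carp_error("carp_invalid_parameter",
               sprintf("degenerate split: L = %d of N = %d", L, n_subjects))
  }
  if (!is.null(seed)) set.seed(seed)
  train <- sort(sample.int(n_subjects, L))
  structure(
    list(
      train_indices = train,
      test_indices = setdiff(seq_len(n_subjects), train),
      L = L,
      M = n_subjects - L,
      ell = ell
    ),
    class = "sample_split"
  )
}

#' Estimate focal-pair regression weights on the training sample
#'
#' Fits two ordinary least-squares regressions on the training sample:
#' item `i` predicted from all items except `i` and `j`, and likewise item
#' `j`.  The returned weight vectors have length `J + 1` (intercept first),
#' with the coefficients at the focal positions fixed to exactly 0 — this
#' is what makes the conditioning variable a function of the non-focal
#' items only.  Constant or collinear predictor columns are handled by the
#' minimum-norm least-squares solution.
#'
#' @param train binary training matrix (`L x J`).
#' @param i,j focal item indices (1-based, distinct).
#' @return Object of class `pair_weights`: list with `a_ij`, `a_ji`
#'   (length `J + 1`, intercept first) and `focal = c(i, j)`.
#' @export
fit_pair_regressions <- function(train, i, j) {
  check_binary_matrix(train)
  J <- ncol(train)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || i < 1L || j < 1L || i > J || j > J) {
    carp_error("carp_invalid_parameter", "focal indices must be distinct items in 1..J")
  }
  if (nrow(train) < 2L) {
    carp_error("carp_insufficient_data", "need at least 2 training rows")
  }
  others <- setdiff(seq_len(J), c(i, j))
  Zt <- cbind(1, train[, others, drop = FALSE])
  G <- crossprod(Zt)
  coef_i <- solve_least_squares(G, crossprod(Zt, train[, i]))
  coef_j <- solve_least_squares(G, crossprod(Zt, train[, j]))
  a_ij <- a_ji <- numeric(J + 1L)
  a_ij[c(1L, others + 1L)] <- coef_i
  a_ji[c(1L, others + 1L)] <- coef_j
  structure(list(a_ij = a_ij, a_ji = a_ji, focal = c(i, j)),
            class = "pair_weights")
}

#' Weighted rest score (sum of the two predicted scores)
#'
#' Computes, per subject, the sum of the two regression-predicted focal
#' scores, \eqn{\hat X_{ij} + \hat X_{ji} = \sum_k (a_{k.ij} + a_{k.ji}) X_k}
#' with \eqn{X_0 := 1}.  Because the focal coefficients are zero, this is a
#' weighted rest score.
#'
#' @param x binary matrix (`n x J`).
#' @param w a `pair_weights` object.
#' @return Numeric vector of length `n`.
#' @export
predicted_sum <- function(x, w) {
  if (!inherits(w, "pair_weights")) {
    carp_error("carp_invalid_input", "`w` must come from fit_pair_regressions()")
  }
  cw <- w$a_ij + w$a_ji
  if (ncol(x) != length(cw) - 1L) {
    carp_error("carp_invalid_input", "column count of `x` does not match the weights")
  }
  drop(x %*% cw[-1L]) + cw[1L]
}

#' Quantile separators of the training-sample score distribution
#'
#' Returns the `m - 1` separators \eqn{q_1 < \dots < q_{m-1}} at
#' probabilities `s/m` of the empirical distribution of the training
#' scores, using the left-continuous inverse of the empirical distribution
#' function (`quantile` type 1).  Duplicate separators caused by ties are
#' collapsed, so the effective number of layers may be smaller than `m`.
#'
#' @param train_scores numeric vector of training-sample scores.
#' @param m requested number of layers (`m >= 2`).
#' @return Object of class `quantile_separators`: list with `q` (strictly
#'   increasing separators) and `m` (effective layer count,
#'   `length(q) + 1`).
#' @export
quantile_separators <- function(train_scores, m = 10L) {
  m <- as.integer(m)
  if (m < 2L) carp_error("carp_invalid_parameter", "`m` must be at least 2")
  if (length(train_scores) < m) {
    carp_error("carp_invalid_parameter", "need at least `m` training scores")
  }
  if (diff(range(train_scores)) == 0) {
    carp_error("carp_degenerate_scores",
               "all training scores identical; no layering possible")
  }
  q <- unname(quantile(train_scores, probs = seq_len(m - 1L) / m, type = 1))
  q <- unique(q)
  # a separator equal to the maximum would create an empty top layer
  q <- q[q < max(train_scores)]
  if (length(q) < 1L) {
    carp_error("carp_degenerate_scores",
               "scores too concentrated to form at least 2 layers")
  }
  structure(list(q = q, m = length(q) + 1L), class = "quantile_separators")
}

#' Assign test-sample scores to conditioning layers
#'
#' Layer `s` is the half-open interval \eqn{q_{s-1} < x \le q_s} with
#' \eqn{q_0 = -\infty} and \eqn{q_m = \infty}; a score exactly equal to a
#' separator falls in the lower layer (right-closed intervals).
#'
#' @param test_scores numeric vector.
#' @param seps a `quantile_separators` object.
#' @return Integer vector of layer labels in `1..seps$m`.
#' @export
assign_layers <- function(test_scores, seps) {
  if (!inherits(seps, "quantile_separators")) {
    carp_error("carp_invalid_input", "`seps` must come from quantile_separators()")
  }
  findInterval(test_scores, seps$q, left.open = TRUE) + 1L
}

default_ell <- function(n) if (n <= 500) 0.5 else 0.3

#' CARP test of monotone homogeneity for a focal item pair
#'
#' Runs the full conditioning-on-added-regression-predictions (CARP)
#' procedure for the focal pair `(i, j)`:
#' \enumerate{
#'   \item split the `N` subjects into a training sample (fraction `ell`)
#'     and a test sample;
#'   \item on the training sample, estimate linear-regression weights that
#'     predict each focal item from the remaining items (focal
#'     coefficients fixed to 0);
#'   \item form the weighted rest score \eqn{\hat X_{ij} + \hat X_{ji}}
#'     and estimate its `m`-quantile separators on the training sample;
#'   \item assign test-sample subjects to quantile layers and test, with
#'     the one-sided Mantel-Haenszel statistic, that the focal covariance
#'     is nonnegative in every layer.
#' }
#' Under any monotone homogeneity model the layered covariances are
#' nonnegative (conditional association), so a small p-value is evidence
#' of multidimensionality.  Degenerate outcomes (scores too concentrated
#' to layer, or no informative layer) are returned as flagged no-decision
#' results, not as p = 1.
#'
#' @param x binary response matrix (`N x J`, `J >= 3`).
#' @param i,j focal item indices.
#' @param ell training fraction; default 0.5 for `N <= 500`, else 0.3.
#' @param m requested number of quantile layers (default 10, deciles).
#' @param seed optional integer seed controlling the random split.
#' @return Object of class `carp_test`: list with `z`, `p_value`, `mh`
#'   (the [mantel_haenszel_one_sided()] result), `weights`, `separators`,
#'   `split`, `focal`, `conditioning` (test-sample layer labels),
#'   `no_decision` and `method = "CARP"`.  For no-decision outcomes `z`
#'   and `p_value` are `NA` and `reason` records the cause.
#' @examples
#' x <- simulate_responses(standard_case_bank(2, 2, 8), 2000, seed = 7)
#' carp_pair_test(x, 1, 3, ell = 0.2, seed = 7)
#' @export
carp_pair_test <- function(x, i, j, ell = NULL, m = 10L, seed = NULL) {
  check_binary_matrix(x)
  if (ncol(x) < 3L) carp_error("carp_invalid_parameter", "need at least 3 items")
  n <- nrow(x)
  if (is.null(ell)) ell <- default_ell(n)
  if (!is.null(seed)) set.seed(seed)
  split <- split_sample(n, ell)
  if (split$L < ncol(x) + 2L) {
    carp_error("carp_invalid_parameter",
               "training sample too small for the pair regressions (need L >= J + 2)")
  }
  train <- x[split$train_indices, , drop = FALSE]
  test <- x[split$test_indices, , drop = FALSE]
  w <- fit_pair_regressions(train, i, j)

  out <- list(weights = w, split = split, focal = c(i, j), method = "CARP")
  res <- tryCatch({
    seps <- quantile_separators(predicted_sum(train, w), m)
    layer <- assign_layers(predicted_sum(test, w), seps)
    tab <- tabulate_layers(test[, i], test[, j], layer, seps$m)
    mh <- mantel_haenszel_one_sided(tab)
    list(separators = seps, conditioning = layer, mh = mh)
  }, carp_degenerate_scores = function(e) e, carp_degenerate_table = function(e) e)

  if (inherits(res, "condition")) {
    out <- c(out, list(z = NA_real_, p_value = NA_real_, mh = NULL,
                       separators = NULL, conditioning = NULL,
                       no_decision = TRUE, reason = conditionMessage(res)))
  } else {
    out <- c(out, res, list(z = res$mh$z, p_value = res$mh$p_value,
                            no_decision = FALSE, reason = NULL))
  }
  structure(out, class = "carp_test")
}

#' Rosenbaum's CRS test for a focal pair
#'
#' The conditioning-on-rest-scores comparator: the full sample (no
#' training/test split) is layered by the observed values of the
#' unweighted rest score \eqn{\sum_{k \ne i,j} X_k} and the same one-sided
#' Mantel-Haenszel statistic is applied.  This tests the conditional-
#' association inequality
#' \eqn{\mathrm{Cov}(X_i, X_j \mid \sum_{k \ne i,j} X_k) \ge 0}.
#'
#' @inheritParams carp_pair_test
#' @return Object of class `carp_test` with `method = "CRS"`.
#' @examples
#' x <- simulate_responses(standard_case_bank(2, 2, 8), 2000, seed = 7)
#' crs_pair_test(x, 1, 3)
#' @export
crs_pair_test <- function(x, i, j) {
  check_binary_matrix(x)
  J <- ncol(x)
  if (J < 3L) carp_error("carp_invalid_parameter", "need at least 3 items")
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || min(i, j) < 1L || max(i, j) > J) {
    carp_error("carp_invalid_parameter", "focal indices must be distinct items in 1..J")
  }
  rest <- rowSums(x[, -c(i, j), drop = FALSE])
  out <- list(weights = NULL, split = NULL, focal = c(i, j), method = "CRS")
  res <- tryCatch({
    tab <- tabulate_layers(x[, i], x[, j], rest + 1L, J - 1L)
    mh <- mantel_haenszel_one_sided(tab)
    list(separators = NULL, conditioning = rest + 1L, mh = mh)
  }, carp_degenerate_table = function(e) e)
  if (inherits(res, "condition")) {
    out <- c(out, list(z = NA_real_, p_value = NA_real_, mh = NULL,
                       separators = NULL, conditioning = NULL,
                       no_decision = TRUE, reason = conditionMessage(res)))
  } else {
    out <- c(out, res, list(z = res$mh$z, p_value = res$mh$p_value,
                            no_decision = FALSE, reason = NULL))
  }
  structure(out, class = "carp_test")
}

#' @export
print.carp_test <- function(x, ...) {
  cat(sprintf("%s test, focal pair (%d, %d)\n", x$method, x$focal[1], x$focal[2]))
  if (isTRUE(x$no_decision)) {
    cat("  no decision:", x$reason, "\n")
  } else {
    cat(sprintf("  Z = %.4f, one-sided p = %.4g (%d layer(s) used)\n",
                x$z, x$p_value, x$mh$layers_used))
  }
  invisible(x)
}
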