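#' Screen item pairs with negative conditional covariance in training data
#'
#' For every item pair `(i, j)` with `i > j`, estimates the CARP weights
#' and quantile separators on the training sample and evaluates the
#' Mantel-Haenszel numerator \eqn{n_{11+} - e_+} (no continuity
#' correction) on the same training subjects — a weighted sum of the
#' layered sample covariances.  Pairs with a negative numerator form the
#' screening set \eqn{S}.  Because the screening statistic is a function
#' of the training sample only, it is independent of test-sample p-values,
#' which is what licenses the Bonferroni correction with `|S|` instead of
#' `J(J-1)/2`.
#'
#' @param train binary training matrix.
#' @param m requested number of quantile layers (default 10).
#' @return Object of class `carp_screening`: list with `pairs` (two-column
#'   matrix of screened pairs, `i > j`), `size` (`S`), `statistics`
#'   (named numerator per pair, all pairs), and `degenerate` (pairs
#'   omitted because no layering or no informative layer was possible).
#' @export
screen_negative_pairs <- function(train, m = 10L) {
  check_binary_matrix(train)
  J <- ncol(train)
  if (J < 3L) carp_error("carp_invalid_parameter", "need at least 3 items")
  if (nrow(train) < 2L * (J + 2L)) {
    carp_error("carp_insufficient_data",
               "training sample too small to screen pairs (need >= 2*(J+2) rows)")
  }
  pairs <- which(upper.tri(matrix(0, J, J)), arr.ind = TRUE)  # col > row
  pairs <- cbind(i = pairs[, 2L], j = pairs[, 1L])            # i > j
  stat <- rep(NA_real_, nrow(pairs))
  degenerate <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    res <- tryCatch({
      w <- fit_pair_regressions(train, i, j)
      sc <- predicted_sum(train, w)
      seps <- quantile_separators(sc, m)
      tab <- tabulate_layers(train[, i], train[, j], assign_layers(sc, seps), seps$m)
      mh <- mantel_haenszel_one_sided(tab)
      mh$n11_plus - mh$e_plus
    }, carp_degenerate_scores = function(e) NULL,
       carp_degenerate_table = function(e) NULL)
    if (is.null(res)) degenerate[r] <- TRUE else stat[r] <- res
  }
  names(stat) <- paste(pairs[, 1L], pairs[, 2L], sep = ":")
  keep <- !degenerate & stat < 0
  structure(
    list(
      pairs = pairs[keep, , drop = FALSE],
      size = sum(keep),
      statistics = stat,
      degenerate = pairs[degenerate, , drop = FALSE]
    ),
    class = "carp_screening"
  )
}

#' Bonferroni decisions over the screened pairs
#'
#' Rejects the null for pair `(i, j)` iff the pair is in the screening set
#' and its test-sample p-value is at most `alpha / S`.  Pairs outside the
#' screening set are never rejected; when `S = 0`, nothing is rejected.
#' This controls the family-wise error rate at `alpha` because the
#' screening set is independent of the test-sample p-values.
#'
#' @param p_values data frame with columns `i`, `j`, `p` giving
#'   test-sample p-values for (at least) every screened pair.
#' @param screening a `carp_screening` object.
#' @param alpha family-wise significance level.
#' @param method `"bonferroni"` (default, the rule above) or `"BH"`
#'   (Benjamini-Hochberg false-discovery-rate control over the screened
#'   pairs, offered as a more powerful alternative).
#' @return Data frame with columns `i`, `j`, `p`, `threshold` (Bonferroni
#'   only) and `reject`.
#' @export
bonferroni_decisions <- function(p_values, screening, alpha = 0.05,
                                 method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (!inherits(screening, "carp_screening")) {
    carp_error("carp_invalid_input", "`screening` must come from screen_negative_pairs()")
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    carp_error("carp_invalid_parameter", "`alpha` must lie in (0, 1)")
  }
  S <- screening$size
  if (S == 0L) {
    return(data.frame(i = integer(), j = integer(), p = numeric(),
                      threshold = numeric(), reject = logical()))
  }
  key <- function(i, j) paste(i, j, sep = ":")
  have <- key(p_values$i, p_values$j)
  want <- key(screening$pairs[, 1L], screening$pairs[, 2L])
  if (!all(want %in% have)) {
    carp_error("carp_invalid_input",
               sprintf("missing p-value for screened pair(s): %s",
                       paste(setdiff(want, have), collapse = ", ")))
  }
  p <- p_values$p[match(want, have)]
  if (anyNA(p)) {
    carp_error("carp_invalid_input", "screened pairs must have non-missing p-values")
  }
  if (method == "bonferroni") {
    thr <- alpha / S
    reject <- p <= thr
  } else {
    thr <- NA_real_
    reject <- p.adjust(p, method = "BH") <= alpha
  }
  data.frame(
    i = screening$pairs[, 1L],
    j = screening$pairs[, 2L],
    p = p,
    threshold = thr,
    reject = reject
  )
}

#' Scan all item pairs: screen on training data, test on test data
#'
#' Convenience wrapper over the full aggregation procedure: split the
#' sample once; screen every pair on the training sample with
#' [screen_negative_pairs()]; for each screened pair, reuse the training
#' weights and separators to layer the test sample and compute the
#' one-sided Mantel-Haenszel p-value; apply [bonferroni_decisions()].
#'
#' @inheritParams carp_pair_test
#' @param alpha family-wise significance level.
#' @param method multiplicity rule, see [bonferroni_decisions()].
#' @return Object of class `carp_scan`: list with `screening`,
#'   `decisions` (data frame with per-pair `z`, `p`, `reject`),
#'   `no_decision` (screened pairs that were degenerate on the test
#'   sample; counted as non-rejections), `split`, `alpha`.
#' @examples
#' x <- simulate_responses(standard_case_bank(3, 3), 1500, seed = 11)
#' sc <- carp_scan(x, seed = 11)
#' sc$decisions[sc$decisions$reject, ]
#' @export
carp_scan <- function(x, ell = NULL, m = 10L, alpha = 0.05, seed = NULL,
                      method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  check_binary_matrix(x)
  n <- nrow(x)
  if (is.null(ell)) ell <- default_ell(n)
  if (!is.null(seed)) set.seed(seed)
  split <- split_sample(n, ell)
  train <- x[split$train_indices, , drop = FALSE]
  test <- x[split$test_indices, , drop = FALSE]
  screening <- screen_negative_pairs(train, m)

  S <- screening$size
  z <- p <- rep(NA_real_, S)
  nodec <- logical(S)
  for (r in seq_len(S)) {
    i <- screening$pairs[r, 1L]; j <- screening$pairs[r, 2L]
    res <- tryCatch({
      w <- fit_pair_regressions(train, i, j)
      seps <- quantile_separators(predicted_sum(train, w), m)
      layer <- assign_layers(predicted_sum(test, w), seps)
      mh <- mantel_haenszel_one_sided(
        tabulate_layers(test[, i], test[, j], layer, seps$m))
      c(mh$z, mh$p_value)
    }, carp_degenerate_scores = function(e) NULL,
       carp_degenerate_table = function(e) NULL)
    if (is.null(res)) nodec[r] <- TRUE else { z[r] <- res[1L]; p[r] <- res[2L] }
  }
  pv <- data.frame(i = screening$pairs[, 1L], j = screening$pairs[, 2L],
                   z = z, p = p)
  # degenerate test-sample evaluations count as non-rejections (p = 1)
  pv_for_rule <- pv
  pv_for_rule$p[nodec] <- 1
  decisions <- bonferroni_decisions(pv_for_rule, screening, alpha, method)
  decisions$z <- pv$z
  decisions$p[nodec] <- NA_real_
  structure(
    list(
      screening = screening,
      decisions = decisions,
      no_decision = pv[nodec, c("i", "j"), drop = FALSE],
      split = split,
      alpha = alpha,
      method = method
    ),
    class = "carp_scan"
  )
}

#' @export
print.carp_scan <- function(x, ...) {
  cat(sprintf("CARP scan: S = %d screened pair(s), alpha = %g (%s)\n",
              x$screening$size, x$alpha, x$method))
  nr <- sum(x$decisions$reject)
  cat(sprintf("  %d rejection(s)", nr))
  if (nr > 0) {
    cat(": ", paste(sprintf("(%d,%d)", x$decisions$i[x$decisions$reject],
                            x$decisions$j[x$decisions$reject]), collapse = " "))
  }
  cat("\n")
  invisible(x)
}
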