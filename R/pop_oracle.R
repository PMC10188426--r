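#' Exact pattern distribution under an item bank
#'
#' Enumerates all `2^J` binary response patterns and computes their
#' population probabilities
#' \deqn{P(x) = \int \prod_i P(X_i = x_i \mid \Theta)\, d\Phi_D(\Theta)}
#' by tensor-product Gauss-Hermite quadrature over the active latent
#' dimensions (dimensions whose loadings are all zero integrate out
#' analytically).  This is the independent population oracle used to
#' validate the simulator and to compute exact conditional correlations.
#'
#' @param bank an [item_bank()] with `J <= 20` items.
#' @param nodes quadrature nodes per dimension (default 40).
#' @return Object of class `pattern_pmf`: list with `probabilities`
#'   (length `2^J`), `patterns` (`2^J x J` 0/1 matrix; item 1 is the
#'   least-significant bit, so row `r` is the binary expansion of
#'   `r - 1`), `bank`, `quadrature_nodes`.
#' @examples
#' pmf <- pattern_distribution(standard_case_bank(3, 0, 0))
#' sum(pmf$probabilities)
#' @export
pattern_distribution <- function(bank, nodes = 40L) {
  if (!inherits(bank, "item_bank")) {
    carp_error("carp_invalid_parameter", "`bank` must be an item_bank object")
  }
  J <- bank$J
  if (J > 20L) {
    carp_error("carp_enumeration_bound", "pattern enumeration is limited to J <= 20")
  }
  nodes <- as.integer(nodes)
  if (nodes < 10L) carp_error("carp_invalid_parameter", "use at least 10 quadrature nodes")

  # patterns: row r = binary expansion of r - 1, item 1 least significant
  P <- 2L^J
  patterns <- matrix(0L, P, J, dimnames = list(NULL, paste0("item", seq_len(J))))
  r <- 0:(P - 1L)
  for (k in seq_len(J)) patterns[, k] <- bitwAnd(r, bitwShiftL(1L, k - 1L)) > 0L

  active <- which(colSums(bank$loadings > 0) > 0)
  if (length(active) == 0L) {
    p1 <- plogis(bank$intercepts)
    logp <- patterns %*% log(p1) + (1 - patterns) %*% log1p(-p1)
    prob <- drop(exp(logp))
  } else {
    gh <- pracma::gaussHermite(nodes)
    theta1 <- sqrt(2) * gh$x
    w1 <- gh$w / sqrt(pi)
    grids <- expand.grid(rep(list(seq_len(nodes)), length(active)))
    Q <- nrow(grids)
    theta <- matrix(theta1[as.matrix(grids)], Q, length(active))
    wq <- apply(matrix(w1[as.matrix(grids)], Q, length(active)), 1L, prod)
    eta <- theta %*% t(bank$loadings[, active, drop = FALSE]) +
      matrix(bank$intercepts, Q, J, byrow = TRUE)      # Q x J
    logp1 <- plogis(eta, log.p = TRUE)
    logp0 <- plogis(-eta, log.p = TRUE)                 # log(1 - p)
    prob <- numeric(P)
    chunk <- max(1L, floor(2e6 / P))
    for (start in seq(1L, Q, by = chunk)) {
      idx <- start:min(start + chunk - 1L, Q)
      # log prob of each pattern at each node: X * (logp1 - logp0) + sum(logp0)
      lp <- patterns %*% t(logp1[idx, , drop = FALSE] - logp0[idx, , drop = FALSE])
      lp <- lp + matrix(rowSums(logp0[idx, , drop = FALSE]), P, length(idx), byrow = TRUE)
      prob <- prob + drop(exp(lp) %*% wq[idx])
    }
  }
  structure(
    list(probabilities = prob, patterns = patterns, bank = bank,
         quadrature_nodes = nodes),
    class = "pattern_pmf"
  )
}

#' @export
print.pattern_pmf <- function(x, ...) {
  cat(sprintf("Pattern pmf: J = %d items, %d patterns, %d GH nodes/dim, total mass %.10f\n",
              x$bank$J, length(x$probabilities), x$quadrature_nodes,
              sum(x$probabilities)))
  invisible(x)
}

#' Population regression weights for a focal pair
#'
#' Solves the population normal equations for the least-squares
#' coefficients predicting each focal item from the non-focal items, with
#' moments taken exactly from the pattern pmf.  Focal coefficients are
#' fixed to 0, mirroring the sample-level [fit_pair_regressions()];
#' singular moment matrices fall back to the minimum-norm solution.
#'
#' @param pmf a `pattern_pmf` object.
#' @param i,j focal item indices.
#' @return A `pair_weights` object (population parameters, not sample
#'   statistics).
#' @export
population_weights <- function(pmf, i, j) {
  if (!inherits(pmf, "pattern_pmf")) {
    carp_error("carp_invalid_input", "`pmf` must come from pattern_distribution()")
  }
  J <- pmf$bank$J
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || min(i, j) < 1L || max(i, j) > J) {
    carp_error("carp_invalid_parameter", "focal indices must be distinct items in 1..J")
  }
  others <- setdiff(seq_len(J), c(i, j))
  Z <- cbind(1, pmf$patterns[, others, drop = FALSE])
  Zw <- Z * pmf$probabilities
  G <- crossprod(Z, Zw)                       # E[Z Z']
  a_ij <- a_ji <- numeric(J + 1L)
  a_ij[c(1L, others + 1L)] <- solve_least_squares(G, crossprod(Zw, pmf$patterns[, i]))
  a_ji[c(1L, others + 1L)] <- solve_least_squares(G, crossprod(Zw, pmf$patterns[, j]))
  structure(list(a_ij = a_ij, a_ji = a_ji, focal = c(i, j)),
            class = "pair_weights")
}

#' Equal-probability grouping of a discrete population score
#'
#' Partitions the response patterns into at most `m` groups of
#' approximately equal probability mass by a score that is a function of
#' the pattern.  All patterns sharing a score value (up to numerical
#' tolerance) are assigned to one group.  Distinct values are processed in
#' ascending order with a greedy equal-mass rule: a group accepts further
#' values only while its total mass stays within its `1/m` bound, and when
#' a group closes the next group's label is advanced according to the
#' cumulative mass already spent, so that group `s` always sits near the
#' mass interval `((s-1)/m, s/m]` and unused labels are skipped.  A single
#' value whose own mass exceeds `1/m` occupies a group by itself.  In
#' particular the extreme groups `1` and `m` never exceed mass `1/m`
#' unless a single extreme value already does.
#'
#' @param score numeric vector, one score per pattern.
#' @param prob pattern probabilities (same length).
#' @param m number of groups.
#' @return Integer vector of group labels in `1..m`, one per pattern.
#' @export
quantile_groups <- function(score, prob, m = 10L) {
  m <- as.integer(m)
  if (length(score) != length(prob)) {
    carp_error("carp_invalid_input", "`score` and `prob` must have equal length")
  }
  # collapse values equal up to numerical tolerance
  ord <- order(score)
  s_sorted <- score[ord]
  tol <- 1e-9 * max(1, diff(range(score)))
  new_val <- c(TRUE, diff(s_sorted) > tol)
  val_id_sorted <- cumsum(new_val)
  val_id <- integer(length(score))
  val_id[ord] <- val_id_sorted
  n_vals <- val_id_sorted[length(val_id_sorted)]
  mass <- vapply(split(prob, val_id), sum, numeric(1))
  total <- sum(mass)

  grp_of_val <- integer(n_vals)
  s <- 1L
  cum <- 0            # mass already assigned to closed groups + current group
  group_mass <- 0     # mass in the current group
  eps <- 1e-9
  for (v in seq_len(n_vals)) {
    mv <- mass[v] / total
    if (group_mass > 0 && cum + mv > s / m + eps) {
      # close the current group; label of the next advances with cumulative mass
      s <- min(m, max(s + 1L, floor(cum * m + eps) + 1L))
      group_mass <- 0
    }
    grp_of_val[v] <- s
    cum <- cum + mv
    group_mass <- group_mass + mv
  }
  grp_of_val[val_id]
}

#' Exact conditional correlation of a focal pair in a subpopulation
#'
#' Computes the population Pearson correlation of `(X_i, X_j)` restricted
#' to the subpopulation of patterns whose conditioning group lies in
#' `groups`, with all moments taken exactly from the pmf.
#'
#' @param pmf a `pattern_pmf` object.
#' @param i,j focal item indices.
#' @param conditioning integer vector of group labels, one per pattern
#'   (e.g. from [quantile_groups()]).
#' @param groups the subset of group labels defining the subpopulation.
#' @return The correlation (a single number).
#' @examples
#' # cross-block correlation in the extreme vigintiles of the difference
#' # of predicted scores, for two independent 5-item Rasch blocks
#' pmf <- pattern_distribution(standard_case_bank(5, 5))
#' w <- population_weights(pmf, 1, 6)
#' d <- drop(pmf$patterns %*% (w$a_ij[-1] - w$a_ji[-1])) + (w$a_ij[1] - w$a_ji[1])
#' g <- quantile_groups(d, pmf$probabilities, m = 20)
#' conditional_correlation(pmf, 1, 6, g, c(1, 20))
#' @export
conditional_correlation <- function(pmf, i, j, conditioning, groups) {
  if (!inherits(pmf, "pattern_pmf")) {
    carp_error("carp_invalid_input", "`pmf` must come from pattern_distribution()")
  }
  if (length(conditioning) != length(pmf$probabilities)) {
    carp_error("carp_invalid_input", "`conditioning` must label every pattern")
  }
  sel <- conditioning %in% groups
  mass <- sum(pmf$probabilities[sel])
  if (mass <= 0) {
    carp_error("carp_undefined_correlation", "subpopulation has zero probability")
  }
  p <- pmf$probabilities[sel] / mass
  xi <- pmf$patterns[sel, i]
  xj <- pmf$patterns[sel, j]
  mi <- sum(p * xi); mj <- sum(p * xj)
  vi <- sum(p * xi^2) - mi^2
  vj <- sum(p * xj^2) - mj^2
  if (vi <= 0 || vj <= 0) {
    carp_error("carp_undefined_correlation",
               "a focal item is degenerate in the subpopulation")
  }
  (sum(p * xi * xj) - mi * mj) / sqrt(vi * vj)
}

#' Population CARP covariance for a focal pair
#'
#' Mean-zero check quantity for the oracle: the vector of conditional
#' covariances \eqn{\mathrm{Cov}(X_i, X_j \mid Q_m(\hat X_{ij} + \hat X_{ji}) = s)}
#' computed exactly from the pmf using population weights and
#' equal-probability grouping.
#'
#' @inheritParams population_weights
#' @param m number of quantile groups (default 10).
#' @return Data frame with columns `group`, `mass`, `covariance`
#'   (`NA` when a group is empty).
#' @export
population_carp_covariances <- function(pmf, i, j, m = 10L) {
  w <- population_weights(pmf, i, j)
  sc <- drop(pmf$patterns %*% (w$a_ij[-1L] + w$a_ji[-1L])) + w$a_ij[1L] + w$a_ji[1L]
  g <- quantile_groups(sc, pmf$probabilities, m)
  out <- data.frame(group = seq_len(m), mass = NA_real_, covariance = NA_real_)
  for (s in seq_len(m)) {
    sel <- g == s
    mass <- sum(pmf$probabilities[sel])
    out$mass[s] <- mass
    if (mass > 0) {
      p <- pmf$probabilities[sel] / mass
      xi <- pmf$patterns[sel, i]; xj <- pmf$patterns[sel, j]
      out$covariance[s] <- sum(p * xi * xj) - sum(p * xi) * sum(p * xj)
    }
  }
  out
}

#' Population moments from a pattern pmf
#'
#' @param pmf a `pattern_pmf` object.
#' @return List with `means` (length `J`) and `cov` (`J x J` covariance
#'   matrix), computed exactly from the pmf.
#' @export
population_moments <- function(pmf) {
  X <- pmf$patterns
  p <- pmf$probabilities / sum(pmf$probabilities)
  mu <- drop(crossprod(X, p))
  M2 <- crossprod(X, X * p)
  list(means = mu, cov = M2 - tcrossprod(mu))
}
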