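test_that("split_sample partitions exactly at the rounded training size", {
  s <- split_sample(10, 0.5, seed = 1)
  expect_equal(s$L, 5L)
  expect_equal(s$M, 5L)
  expect_identical(sort(c(s$train_indices, s$test_indices)), 1:10)
  expect_length(intersect(s$train_indices, s$test_indices), 0)

  expect_equal(split_sample(500, 0.3, seed = 2)$L, 150L)
  # exact .5 rounding ties resolve downward
  expect_equal(split_sample(5, 0.5, seed = 3)$L, 2L)

  expect_identical(split_sample(100, 0.3, seed = 7), split_sample(100, 0.3, seed = 7))
  expect_error(split_sample(10, 0.01), class = "carp_invalid_parameter")
  expect_error(split_sample(10, 1.2), class = "carp_invalid_parameter")
})

test_that("pair regressions match ordinary least squares and zero the focal entries", {
  set.seed(10)
  x <- matrix(rbinom(200 * 6, 1, .5), 200, 6)
  w <- fit_pair_regressions(x, 2, 5)
  expect_identical(w$a_ij[c(3, 6)], c(0, 0))  # positions i=2, j=5 (after intercept)
  expect_identical(w$a_ji[c(3, 6)], c(0, 0))
  # independent oracle: R's lm on the same design
  fit <- lm(x[, 2] ~ x[, c(1, 3, 4, 6)])
  expect_equal(unname(w$a_ij[c(1, 2, 4, 5, 7)]), unname(coef(fit)), tolerance = 1e-8)
})

test_that("a perfectly predictive item gets weight one, noise items weight zero", {
  set.seed(11)
  n <- 400L
  xk <- rbinom(n, 1, .5)
  noise <- matrix(rbinom(n * 3, 1, .5), n, 3)
  x <- cbind(xk, noise[, 1], xk, noise[, 2], noise[, 3])  # item 3 == item 1
  w <- fit_pair_regressions(x, 3, 2)
  expect_equal(w$a_ij[2], 1, tolerance = 1e-8)          # weight on the copy
  expect_equal(unname(w$a_ij[c(1, 5, 6)]), rep(0, 3), tolerance = 1e-7)
})

test_that("constant predictor columns are absorbed by the intercept", {
  set.seed(12)
  x <- cbind(rbinom(100, 1, .5), rbinom(100, 1, .5), 1L, rbinom(100, 1, .5))
  w <- fit_pair_regressions(x, 1, 2)
  pred <- predicted_sum(x, fit_pair_regressions(x, 1, 2))
  expect_true(all(is.finite(pred)))
  expect_true(all(is.finite(w$a_ij)))
})

test_that("predicted_sum is the advertised linear functional", {
  set.seed(13)
  x <- matrix(rbinom(50 * 5, 1, .5), 50, 5)
  w <- fit_pair_regressions(x, 1, 2)
  # brute-force per-subject evaluation
  brute <- vapply(seq_len(50), function(n) {
    sum((w$a_ij[-1] + w$a_ji[-1]) * x[n, ]) + w$a_ij[1] + w$a_ji[1]
  }, numeric(1))
  expect_equal(predicted_sum(x, w), brute, tolerance = 1e-12)

  # all-zero weights with intercepts .3 each give a constant .6
  w0 <- structure(list(a_ij = c(0.3, rep(0, 5)), a_ji = c(0.3, rep(0, 5)),
                       focal = c(1L, 2L)), class = "pair_weights")
  expect_equal(predicted_sum(x, w0), rep(0.6, 50))

  # equal unit weights on non-focal items reduce to twice the rest score
  wu <- structure(list(a_ij = c(0, 0, 0, 1, 1, 1), a_ji = c(0, 0, 0, 1, 1, 1),
                       focal = c(1L, 2L)), class = "pair_weights")
  expect_equal(predicted_sum(x, wu), 2 * rowSums(x[, 3:5]))
})

test_that("quantile separators are the type-1 empirical quantiles", {
  seps <- quantile_separators(1:100, m = 10L)
  expect_equal(seps$q, seq(10, 90, by = 10))
  expect_equal(seps$m, 10L)
  # each induced training layer has exactly 10 members
  expect_equal(unname(table(assign_layers(1:100, seps))), rep(10L, 10L),
               ignore_attr = TRUE)

  few <- quantile_separators(rep(c(1, 2, 3), c(30, 40, 30)), m = 10L)
  expect_lte(few$m, 3L)

  expect_error(quantile_separators(rep(1, 50), m = 10L),
               class = "carp_degenerate_scores")
})

test_that("layer assignment uses right-closed intervals", {
  seps <- structure(list(q = c(0.5, 1.5), m = 3L), class = "quantile_separators")
  expect_equal(assign_layers(c(0, 1, 2), seps), c(1L, 2L, 3L))
  # a score exactly on a separator falls in the lower layer
  expect_equal(assign_layers(c(0.5, 1.5), seps), c(1L, 2L))
  expect_equal(assign_layers(c(-10, 10), seps), c(1L, 3L))
})

test_that("the CARP pipeline is deterministic and symmetric in the focal pair", {
  x <- simulate_responses(standard_case_bank(3, 3), 600, seed = 20)
  a <- carp_pair_test(x, 1, 4, ell = 0.5, seed = 77)
  b <- carp_pair_test(x, 1, 4, ell = 0.5, seed = 77)
  expect_identical(a$z, b$z)
  swapped <- carp_pair_test(x, 4, 1, ell = 0.5, seed = 77)
  expect_identical(a$z, swapped$z)
  expect_identical(a$p_value, swapped$p_value)
})

test_that("CRS is symmetric and layers by the raw rest score", {
  x <- simulate_responses(standard_case_bank(2, 2, 8), 800, seed = 21)
  a <- crs_pair_test(x, 1, 3)
  b <- crs_pair_test(x, 3, 1)
  expect_identical(a$z, b$z)
  expect_equal(a$conditioning, rowSums(x[, -c(1, 3)]) + 1L, ignore_attr = TRUE)
})

test_that("equal positive weights reproduce rest-score decile layering", {
  # quantile grouping is invariant under increasing transforms of the score;
  # dyadic weights keep the transform float-exact under blocked BLAS sums
  set.seed(22)
  x <- matrix(rbinom(1000 * 8, 1, runif(8, .3, .7)), 1000, 8, byrow = TRUE)
  rest <- rowSums(x[, 3:8])
  wu <- structure(list(a_ij = c(0.25, 0, 0, rep(0.5, 6)),
                       a_ji = c(0.25, 0, 0, rep(0.5, 6)),
                       focal = c(1L, 2L)), class = "pair_weights")
  sc <- predicted_sum(x, wu)          # = 0.5 + rest, increasing in rest
  seps_w <- quantile_separators(sc, 10L)
  seps_r <- quantile_separators(rest, 10L)
  expect_identical(assign_layers(sc, seps_w), assign_layers(rest, seps_r))
})

test_that("degenerate data yield a flagged no-decision, not a silent p-value", {
  # constant items: every predicted score identical -> no layering possible
  x <- cbind(rep(0L, 60), rep(1L, 60), rep(0L, 60), rep(1L, 60))
  res <- carp_pair_test(x, 1, 2, ell = 0.5, seed = 1)
  expect_true(res$no_decision)
  expect_true(is.na(res$p_value))
})

test_that("unidimensional data keep the CARP rejection rate well below alpha", {
  R <- 200L
  p <- numeric(R)
  bank <- sample_parameter_set(10, "uni", seed = 30)
  for (r in seq_len(R)) {
    set.seed(3000 + r)
    x <- simulate_responses(bank, 500)
    res <- carp_pair_test(x, 1, 2, ell = 0.3)
    p[r] <- if (res$no_decision) NA_real_ else res$p_value
  }
  expect_lt(rejection_rate(p, 0.05), 0.05)
})

test_that("zero-dimensional fair coins keep the CRS rejection rate near alpha", {
  R <- 400L
  bank <- item_bank(matrix(0, 6, 1), rep(0, 6))
  p <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(4000 + r)
    x <- simulate_responses(bank, 1000)
    res <- crs_pair_test(x, 1, 2)
    p[r] <- if (res$no_decision) NA_real_ else res$p_value
  }
  expect_lte(rejection_rate(p, 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / R))
})
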