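test_that("single-item marginals are exact under symmetry", {
  p0 <- pattern_distribution(item_bank(matrix(0, 1, 1), 0))
  expect_equal(p0$probabilities, c(0.5, 0.5), tolerance = 1e-12)
  # logistic response and N(0,1) latent are both symmetric about 0
  p1 <- pattern_distribution(item_bank(matrix(1, 1, 1), 0))
  expect_equal(p1$probabilities[2], 0.5, tolerance = 1e-10)
})

test_that("the pattern pmf sums to one and factorises across blocks", {
  pmf <- pattern_distribution(standard_case_bank(5, 5))
  expect_equal(sum(pmf$probabilities), 1, tolerance = 1e-8)
  expect_true(all(pmf$probabilities >= 0))
  # items on independent dimensions have zero population covariance
  mom <- population_moments(pmf)
  expect_equal(mom$cov[1, 6], 0, tolerance = 1e-8)
  expect_equal(mom$cov[3, 9], 0, tolerance = 1e-8)
})

test_that("pattern indexing puts item 1 in the least-significant bit", {
  pmf <- pattern_distribution(item_bank(matrix(0, 3, 1), c(-50, 0, 50)))
  # item 1 never solved, item 3 always solved: only patterns x1=0, x3=1 live
  live <- which(pmf$probabilities > 1e-6) - 1L
  expect_true(all(bitwAnd(live, 1L) == 0L))
  expect_true(all(bitwAnd(live, 4L) == 4L))
})

test_that("doubling the quadrature nodes leaves the pmf unchanged to 1e-8", {
  bank <- standard_case_bank(3, 3)
  a <- pattern_distribution(bank, nodes = 40)
  b <- pattern_distribution(bank, nodes = 80)
  expect_lt(max(abs(a$probabilities - b$probabilities)), 1e-8)
})

test_that("population weights respect exchangeability and independence", {
  pmf <- pattern_distribution(standard_case_bank(5, 5))
  w <- population_weights(pmf, 1, 6)
  within <- w$a_ij[1 + 2:5]     # same-block non-focal items
  across <- w$a_ij[1 + 7:10]    # other-block items
  expect_lt(diff(range(within)), 1e-8)
  expect_lt(max(abs(across)), 1e-8)
  expect_identical(w$a_ij[1 + c(1, 6)], c(0, 0))

  uni <- pattern_distribution(standard_case_bank(6, 0, 0))
  wu <- population_weights(uni, 1, 2)
  expect_lt(diff(range(wu$a_ij[1 + 3:6])), 1e-8)
})

test_that("population weights solve the J = 3 closed-form regression", {
  bank <- item_bank(matrix(c(1.2, 0.8, 1.7), 3, 1), c(0.3, -0.2, 0.1))
  pmf <- pattern_distribution(bank)
  w <- population_weights(pmf, 1, 2)
  # single predictor X3: slope = Cov(X1,X3)/Var(X3), intercept from the means
  mom <- population_moments(pmf)
  slope <- mom$cov[1, 3] / mom$cov[3, 3]
  expect_equal(w$a_ij[4], slope, tolerance = 1e-10)
  expect_equal(w$a_ij[1], mom$means[1] - slope * mom$means[3],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("quantile groups respect the greedy equal-mass rule", {
  # uniform mass on 10 values, m = 5: two values per group, all labels used
  g <- quantile_groups(1:10, rep(.1, 10), m = 5)
  expect_equal(g, rep(1:5, each = 2))
  # a heavy middle value occupies its own group; extremes stay light
  g2 <- quantile_groups(1:3, c(.05, .9, .05), m = 20)
  expect_equal(g2[1], 1L)
  expect_equal(g2[3], 20L)
  expect_true(g2[2] > 1L && g2[2] < 20L)
})

test_that("zero-dimensional items are uncorrelated under any conditioning", {
  bank <- item_bank(matrix(0, 5, 1), runif(5, -1, 1))
  pmf <- pattern_distribution(bank)
  w <- population_weights(pmf, 1, 2)
  sc <- drop(pmf$patterns %*% (w$a_ij[-1] + w$a_ji[-1]))
  # any grouping of the other items leaves the focal pair independent
  g <- quantile_groups(rowSums(pmf$patterns[, 3:5]), pmf$probabilities, m = 4)
  for (grp in list(1, 4, c(1, 4), 1:4)) {
    expect_equal(conditional_correlation(pmf, 1, 2, g, grp), 0, tolerance = 1e-10)
  }
})

test_that("unidimensional banks satisfy conditional association in every group union", {
  bank <- standard_case_bank(8, 0, 0)
  pmf <- pattern_distribution(bank)
  w <- population_weights(pmf, 1, 2)
  sc <- drop(pmf$patterns %*% (w$a_ij[-1] + w$a_ji[-1]))
  g <- quantile_groups(sc, pmf$probabilities, m = 10)
  labs <- sort(unique(g))
  # every union of decile groups (as a bit pattern over the used labels)
  for (mask in 1:(2^length(labs) - 1)) {
    grp <- labs[bitwAnd(mask, bitwShiftL(1L, seq_along(labs) - 1L)) > 0L]
    corr <- tryCatch(conditional_correlation(pmf, 1, 2, g, grp),
                     carp_undefined_correlation = function(e) NA_real_)
    if (!is.na(corr)) expect_gte(corr, -1e-6)
  }
})

test_that("population CARP covariances are nonnegative for unidimensional banks", {
  for (s in 1:3) {
    bank <- sample_parameter_set(7, "uni", seed = 100 + s)
    pmf <- pattern_distribution(bank)
    cc <- population_carp_covariances(pmf, 1, 2, m = 10)
    expect_true(all(cc$covariance >= -1e-8, na.rm = TRUE))
  }
})

test_that("cross-block mean conditional covariance given the rest score is nonpositive", {
  pmf <- pattern_distribution(standard_case_bank(5, 5))
  rest <- rowSums(pmf$patterns[, -c(1, 6)])
  total <- 0
  for (v in unique(rest)) {
    sel <- rest == v
    mass <- sum(pmf$probabilities[sel])
    if (mass > 0) {
      p <- pmf$probabilities[sel] / mass
      xi <- pmf$patterns[sel, 1]; xj <- pmf$patterns[sel, 6]
      total <- total + mass * (sum(p * xi * xj) - sum(p * xi) * sum(p * xj))
    }
  }
  expect_lte(total, 1e-8)
})

test_that("the enumeration bound is enforced", {
  expect_error(pattern_distribution(standard_case_bank(11, 11, 0)),
               class = "carp_enumeration_bound")
})
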