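#' Configuration for a Monte-Carlo study
#'
#' Bundles the design and scale of a seeded simulation study.  Each
#' replicate derives its own seed from the root seed plus a replicate
#' offset, so results do not depend on evaluation order.
#'
#' @param design `"zero"` (all loadings 0), `"uni"` (one dimension,
#'   loadings ~ U(0.5, 2.5)), or `"blocks"` (standard simple-structure
#'   bank with unit loadings and zero intercepts given by `blocks`).
#' @param N subjects per simulated sample.
#' @param J items; may be a vector of values for `"zero"`/`"uni"` grids.
#' @param blocks block sizes `c(J1, J2, J3)` for `design = "blocks"`.
#' @param ell training fraction (default: 0.5 if `N <= 500` else 0.3).
#' @param m number of quantile layers.
#' @param replicates samples per configuration.
#' @param parameter_sets random parameter draws per `J`
#'   (`"zero"`/`"uni"` designs only).
#' @param alpha nominal significance level.
#' @param seed root integer seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(design = c("zero", "uni", "blocks"), N = 500, J = 10,
                         blocks = NULL, ell = NULL, m = 10L, replicates = 1000L,
                         parameter_sets = 1L, alpha = 0.05, seed = 1L) {
  design <- match.arg(design)
  if (replicates < 1L) carp_error("carp_invalid_parameter", "need at least 1 replicate")
  if (alpha <= 0 || alpha >= 1) carp_error("carp_invalid_parameter", "`alpha` must lie in (0,1)")
  if (design == "blocks") {
    if (is.null(blocks) || length(blocks) != 3L || sum(blocks > 0) < 2L) {
      carp_error("carp_invalid_parameter",
                 "`blocks` must give c(J1, J2, J3) with at least two nonzero blocks")
    }
    J <- sum(blocks)
  }
  if (is.null(ell)) ell <- default_ell(N)
  structure(
    list(design = design, N = as.integer(N), J = as.integer(J), blocks = blocks,
         ell = ell, m = as.integer(m), replicates = as.integer(replicates),
         parameter_sets = as.integer(parameter_sets), alpha = alpha,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

# rejection rate of one test over R replicates from one bank;
# no-decision outcomes count as non-rejections (conservative)
run_replicates <- function(bank, cfg, focal, base_seed, crs = FALSE) {
  rej_carp <- rej_crs <- 0L
  nodec_carp <- nodec_crs <- 0L
  for (r in seq_len(cfg$replicates)) {
    set.seed(base_seed + r)
    x <- simulate_responses(bank, cfg$N)
    res <- carp_pair_test(x, focal[1], focal[2], ell = cfg$ell, m = cfg$m)
    if (res$no_decision) nodec_carp <- nodec_carp + 1L
    else if (res$p_value < cfg$alpha) rej_carp <- rej_carp + 1L
    if (crs) {
      res2 <- crs_pair_test(x, focal[1], focal[2])
      if (res2$no_decision) nodec_crs <- nodec_crs + 1L
      else if (res2$p_value < cfg$alpha) rej_crs <- rej_crs + 1L
    }
  }
  list(carp = rej_carp / cfg$replicates, crs = rej_crs / cfg$replicates,
       nodec_carp = nodec_carp, nodec_crs = nodec_crs)
}

#' Type-I-error study under a null (MH-satisfying) design
#'
#' For each value of `J` and each randomly drawn parameter set, simulates
#' `replicates` samples under the zero- or unidimensional logistic model,
#' applies the CARP test to the focal pair (1, 2) and records the
#' rejection rate at `alpha`.  Under these designs monotone homogeneity
#' holds, so rates above `alpha` indicate anticonservatism.
#'
#' @param cfg a [study_config()] with `design` `"zero"` or `"uni"`.
#' @return Object of class `rejection_table`: data frame with one row per
#'   `(J, parameter set)` holding `rate`, `se`, `no_decisions`; the
#'   attribute `"summary"` holds min/quartiles/mean/max of the rates per
#'   `J`.
#' @examples
#' cfg <- study_config("zero", N = 500, J = 10, ell = 0.3,
#'                     replicates = 20, parameter_sets = 2, seed = 1)
#' type1_study(cfg)
#' @export
type1_study <- function(cfg) {
  if (!inherits(cfg, "study_config") || !cfg$design %in% c("zero", "uni")) {
    carp_error("carp_invalid_parameter", "`cfg` must be a zero- or unidimensional study_config")
  }
  rows <- expand.grid(J = cfg$J, set = seq_len(cfg$parameter_sets))
  rows <- rows[order(rows$J, rows$set), , drop = FALSE]
  rows$rate <- rows$se <- rows$no_decisions <- NA_real_
  for (k in seq_len(nrow(rows))) {
    cfg_seed <- cfg$seed + 100003L * (k - 1L)
    bank <- sample_parameter_set(rows$J[k], cfg$design, seed = cfg_seed)
    res <- run_replicates(bank, cfg, focal = c(1L, 2L), base_seed = cfg_seed)
    rows$rate[k] <- res$carp
    rows$se[k] <- sqrt(res$carp * (1 - res$carp) / cfg$replicates)
    rows$no_decisions[k] <- res$nodec_carp
  }
  summ <- do.call(rbind, lapply(split(rows$rate, rows$J), function(r) {
    c(min = min(r), quantile(r, c(.25, .5, .75)), mean = mean(r), max = max(r))
  }))
  structure(rows, summary = summ, config = cfg,
            class = c("rejection_table", "data.frame"))
}

#' Power study under a multidimensional standard design
#'
#' Simulates `replicates` samples from the standard simple-structure bank
#' with block sizes `cfg$blocks` (unit loadings, zero intercepts) and runs
#' both the CARP test and the CRS comparator on the cross-block focal
#' pair (first item of block 1, first item of block 2), recording both
#' rejection rates at `alpha`.
#'
#' @param cfg a [study_config()] with `design = "blocks"`.
#' @return Object of class `rejection_table`: one-row data frame with
#'   `carp`, `crs` rejection rates, their standard errors, and
#'   no-decision counts.
#' @examples
#' cfg <- study_config("blocks", blocks = c(2, 2, 8), N = 1000, ell = 0.3,
#'                     replicates = 20, seed = 1)
#' power_study(cfg)
#' @export
power_study <- function(cfg) {
  if (!inherits(cfg, "study_config") || cfg$design != "blocks") {
    carp_error("carp_invalid_parameter", "`cfg` must be a block-design study_config")
  }
  bank <- standard_case_bank(cfg$blocks[1], cfg$blocks[2], cfg$blocks[3])
  focal <- c(1L, cfg$blocks[1] + 1L)
  res <- run_replicates(bank, cfg, focal, base_seed = cfg$seed, crs = TRUE)
  out <- data.frame(
    J = cfg$J, J1 = cfg$blocks[1], J2 = cfg$blocks[2], J3 = cfg$blocks[3],
    carp = res$carp,
    carp_se = sqrt(res$carp * (1 - res$carp) / cfg$replicates),
    crs = res$crs,
    crs_se = sqrt(res$crs * (1 - res$crs) / cfg$replicates),
    no_decisions_carp = res$nodec_carp,
    no_decisions_crs = res$nodec_crs
  )
  structure(out, config = cfg, class = c("rejection_table", "data.frame"))
}

#' Sweep the training fraction and fit its power-optimal value
#'
#' `ell_sweep()` reruns a block-design power study over a grid of training
#' fractions; `optimal_ell()` fits a quadratic to power as a function of
#' the training fraction and returns the vertex, the estimated
#' power-maximising value of the fraction.
#'
#' @param cfg a [study_config()] with `design = "blocks"`.
#' @param ell_grid training fractions to evaluate.
#' @return `ell_sweep()`: named numeric vector of CARP rejection rates,
#'   names the grid values.  `optimal_ell()`: the vertex `-b/(2c)` of the
#'   fitted quadratic `a + b*ell + c*ell^2`; an error of class
#'   `carp_no_maximum` if the fit is convex or the vertex falls outside
#'   (0, 1).
#' @examples
#' optimal_ell(c(`0.2` = .30, `0.4` = .42, `0.6` = .38))
#' @export
ell_sweep <- function(cfg, ell_grid = seq(0.1, 0.9, by = 0.1)) {
  rates <- vapply(ell_grid, function(l) {
    cfg2 <- cfg
    cfg2$ell <- l
    power_study(cfg2)$carp
  }, numeric(1))
  names(rates) <- format(ell_grid)
  rates
}

#' @rdname ell_sweep
#' @param power_by_ell named numeric vector: names are training fractions,
#'   values the corresponding power estimates (at least 3 distinct
#'   fractions).
#' @export
optimal_ell <- function(power_by_ell) {
  ell <- as.numeric(names(power_by_ell))
  if (length(unique(ell)) < 3L || anyNA(ell)) {
    carp_error("carp_invalid_parameter",
               "need power values at >= 3 distinct training fractions, named by fraction")
  }
  fit <- lm(y ~ ell + I(ell^2), data = data.frame(ell = ell, y = as.numeric(power_by_ell)))
  b <- coef(fit)[["ell"]]
  cc <- coef(fit)[["I(ell^2)"]]
  if (!is.finite(cc) || cc >= 0) {
    carp_error("carp_no_maximum", "quadratic fit is not concave; no interior maximum")
  }
  vertex <- -b / (2 * cc)
  if (vertex <= 0 || vertex >= 1) {
    carp_error("carp_no_maximum",
               sprintf("quadratic maximum %.3f falls outside (0, 1)", vertex))
  }
  vertex
}

#' @export
print.rejection_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Rejection table (%s design, N = %d, ell = %.2f, R = %d, alpha = %g)\n",
              cfg$design, cfg$N, cfg$ell, cfg$replicates, cfg$alpha))
  print.data.frame(x, row.names = FALSE, digits = 4)
  summ <- attr(x, "summary")
  if (!is.null(summ)) {
    cat("rate summary by J:\n")
    print(round(summ, 4))
  }
  invisible(x)
}
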