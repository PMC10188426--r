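# Shared fixtures for the test suite.  All data are generated in code.

# a small random layered 2x2xm table with healthy margins
random_layer_table <- function(seed, m = 4L, n_per_layer = 60L) {
  set.seed(seed)
  n <- m * n_per_layer
  layer <- rep(seq_len(m), each = n_per_layer)
  x_i <- rbinom(n, 1, runif(m, .3, .7)[layer])
  x_j <- rbinom(n, 1, runif(m, .3, .7)[layer])
  list(x_i = x_i, x_j = x_j, layer = layer, m = m)
}

# rejection rate helper: no-decision outcomes count as non-rejections
rejection_rate <- function(p_values, alpha = 0.05) {
  mean(!is.na(p_values) & p_values < alpha)
}
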