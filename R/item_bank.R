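#' Item bank for the multidimensional logistic latent-trait model
#'
#' An item bank holds the data-generating parameters of the simulator: a
#' `J x D` matrix of nonnegative discrimination loadings and a length-`J`
#' vector of intercepts (in logit units).  Given a latent vector
#' \eqn{\Theta} of `D` independent standard normals, item `i` is scored 1
#' with probability
#' \deqn{P(X_i = 1 \mid \Theta) = \mathrm{logistic}(\sum_d \alpha_{id} \Theta_d + \beta_i).}
#'
#' The "zero-dimensional" case — all loadings zero, so that items are
#' mutually independent — is represented by an all-zero loading matrix.
#' The effective dimensionality `D` is the number of dimensions that carry
#' at least one nonzero loading.
#'
#' @param loadings numeric `J x D` matrix of nonnegative loadings
#'   (a plain vector is taken as a single column).
#' @param intercepts numeric vector of length `J`.
#' @param dim_assignment optional integer vector of length `J` giving, for
#'   simple-structure banks, the dimension each item loads on.
#' @return An object of class `item_bank` with elements `loadings`,
#'   `intercepts`, `dim_assignment`, `J` and `D`.
#' @examples
#' bank <- item_bank(matrix(1, 3, 1), intercepts = c(-1, 0, 1))
#' bank$D
#' @export
item_bank <- function(loadings, intercepts, dim_assignment = NULL) {
  if (!is.matrix(loadings)) loadings <- matrix(loadings, ncol = 1L)
  storage.mode(loadings) <- "double"
  J <- nrow(loadings)
  if (anyNA(loadings) || any(loadings < 0)) {
    carp_error("carp_invalid_parameter", "all loadings must be nonnegative and non-missing")
  }
  if (length(intercepts) != J || anyNA(intercepts)) {
    carp_error("carp_invalid_parameter", "`intercepts` must be a length-J vector without NAs")
  }
  if (!is.null(dim_assignment)) {
    if (length(dim_assignment) != J) {
      carp_error("carp_invalid_parameter", "`dim_assignment` must have one entry per item")
    }
    for (i in seq_len(J)) {
      nz <- which(loadings[i, ] > 0)
      if (length(nz) > 1L || (length(nz) == 1L && nz != dim_assignment[i])) {
        carp_error("carp_invalid_parameter",
                   "simple-structure banks need at most one nonzero loading per item, matching `dim_assignment`")
      }
    }
  }
  structure(
    list(
      loadings = loadings,
      intercepts = as.numeric(intercepts),
      dim_assignment = dim_assignment,
      J = J,
      D = sum(colSums(loadings > 0) > 0)
    ),
    class = "item_bank"
  )
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: J = %d items, D = %d active dimension(s)\n", x$J, x$D))
  cat("intercepts: ", paste(format(x$intercepts, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Standard simple-structure bank with unit loadings
#'
#' Builds the "standard" block design used throughout the simulation
#' studies: the first `J1` items load 1 on dimension 1, the next `J2` on
#' dimension 2, the next `J3` on dimension 3; all other loadings are 0 and
#' all intercepts are 0.  With `J1 = J2` and `J3 = 0` this is the standard
#' two-dimensional case (two independent Rasch blocks).
#'
#' @param J1,J2,J3 nonnegative block sizes; their sum must be at least 3.
#' @return An [item_bank()].
#' @examples
#' standard_case_bank(5, 5)          # standard two-dimensional case, J = 10
#' standard_case_bank(2, 2, 8)       # three-dimensional, J = 12
#' @export
standard_case_bank <- function(J1, J2 = 0L, J3 = 0L) {
  sizes <- c(J1, J2, J3)
  if (anyNA(sizes) || any(sizes < 0) || sum(sizes) < 3) {
    carp_error("carp_invalid_parameter", "block sizes must be nonnegative with J1 + J2 + J3 >= 3")
  }
  J <- sum(sizes)
  loadings <- matrix(0, J, 3L)
  assign <- rep(1:3, times = sizes)
  loadings[cbind(seq_len(J), assign)] <- 1
  # keep only the leading columns up to the last nonzero block
  keep <- max(which(sizes > 0))
  item_bank(loadings[, seq_len(keep), drop = FALSE], intercepts = rep(0, J),
            dim_assignment = assign)
}

#' Randomly drawn item parameters under a block design
#'
#' Draws an item bank with intercepts \eqn{\beta_i \sim U(-1.5, 1.5)} and
#' nonzero loadings \eqn{\alpha \sim U(0.5, 2.5)}, with the structural
#' zeros dictated by `design`:
#' \describe{
#'   \item{`"zero"`}{all loadings 0 (mutually independent items);}
#'   \item{`"uni"`}{one dimension, all items load on it;}
#'   \item{`"two-block"`}{two dimensions; the first `J1` items load only on
#'     dimension 1, the rest only on dimension 2.}
#' }
#'
#' @param J number of items (at least 3).
#' @param design `"zero"`, `"uni"`, or `"two-block"`.
#' @param seed optional integer seed for reproducibility.
#' @param J1 size of the first block when `design = "two-block"`
#'   (defaults to `J %/% 2`).
#' @return An [item_bank()].
#' @examples
#' sample_parameter_set(10, "zero", seed = 1)
#' @export
sample_parameter_set <- function(J, design = c("zero", "uni", "two-block"),
                                 seed = NULL, J1 = NULL) {
  design <- match.arg(design)
  if (J < 3) carp_error("carp_invalid_parameter", "J must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  beta <- runif(J, -1.5, 1.5)
  if (design == "zero") {
    return(item_bank(matrix(0, J, 1L), beta))
  }
  if (design == "uni") {
    return(item_bank(matrix(runif(J, 0.5, 2.5), J, 1L), beta,
                     dim_assignment = rep(1L, J)))
  }
  if (is.null(J1)) J1 <- J %/% 2L
  if (J1 < 1 || J1 >= J) {
    carp_error("carp_invalid_parameter", "two-block designs need 1 <= J1 < J")
  }
  loadings <- matrix(0, J, 2L)
  assign <- rep(c(1L, 2L), c(J1, J - J1))
  loadings[cbind(seq_len(J), assign)] <- runif(J, 0.5, 2.5)
  item_bank(loadings, beta, dim_assignment = assign)
}

#' Simulate binary responses under an item bank
#'
#' Draws `n_subjects` i.i.d. subjects: a latent vector of independent
#' standard normals per subject, then conditionally independent Bernoulli
#' item scores with logistic response probabilities.  All latent draws are
#' consumed before any item draws, so the same `(bank, n_subjects, seed)`
#' always yields a bit-identical matrix.
#'
#' @param bank an [item_bank()].
#' @param n_subjects number of rows to simulate (at least 1).
#' @param seed optional integer seed.
#' @return Integer `n_subjects x J` matrix with entries 0/1 and columns
#'   named `item1 ... itemJ`.
#' @examples
#' x <- simulate_responses(standard_case_bank(5, 5), 100, seed = 1)
#' colMeans(x)
#' @export
simulate_responses <- function(bank, n_subjects, seed = NULL) {
  if (!inherits(bank, "item_bank")) {
    carp_error("carp_invalid_parameter", "`bank` must be an item_bank object")
  }
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1) {
    carp_error("carp_invalid_parameter", "`n_subjects` must be a positive count")
  }
  n_subjects <- as.integer(n_subjects)
  if (!is.null(seed)) set.seed(seed)
  J <- bank$J
  D <- ncol(bank$loadings)
  eta <- matrix(bank$intercepts, n_subjects, J, byrow = TRUE)
  if (D > 0 && any(bank$loadings > 0)) {
    theta <- matrix(rnorm(n_subjects * D), n_subjects, D)
    eta <- eta + theta %*% t(bank$loadings)
  }
  p <- plogis(eta)
  x <- matrix(0L, n_subjects, J, dimnames = list(NULL, paste0("item", seq_len(J))))
  x[matrix(runif(n_subjects * J), n_subjects, J) < p] <- 1L
  x
}

#' Read and write item banks and response matrices
#'
#' Banks are serialised as JSON (`loadings`, `intercepts`); response
#' matrices as delimited text with an `item1..itemJ` header.
#'
#' @param bank an [item_bank()].
#' @param path file path.
#' @return `read_item_bank()` returns an [item_bank()];
#'   `read_responses()` an integer matrix.
#' @export
write_item_bank <- function(bank, path) {
  jsonlite::write_json(
    list(loadings = bank$loadings, intercepts = bank$intercepts),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  item_bank(as.matrix(obj$loadings), obj$intercepts)
}

#' @rdname write_item_bank
#' @param x a binary response matrix.
#' @param sep field separator (`","` or `"\t"`).
#' @export
write_responses <- function(x, path, sep = ",") {
  check_binary_matrix(x)
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_responses <- function(path, sep = ",") {
  x <- as.matrix(utils::read.table(path, header = TRUE, sep = sep))
  storage.mode(x) <- "integer"
  check_binary_matrix(x)
  x
}
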