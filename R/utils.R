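# Internal helpers shared across modules.

carp_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "carp_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
check_binary_matrix <- function(x) {
  if (!is.matrix(x) || !(is.numeric(x) || is.logical(x))) {
    carp_error("carp_invalid_input", "`x` must be a numeric matrix of 0/1 item scores")
  }
  if (anyNA(x) || !all(x == 0L | x == 1L)) {
    carp_error("carp_invalid_input", "item scores must be 0 or 1 with no missing values")
  }
  invisible(x)
}

# Least-squares solve of the normal equations G a = b.  Uses a Cholesky
# factorisation in the full-rank case and falls back to the minimum-norm
# (pseudoinverse) solution when G is singular, so constant or collinear
# predictor columns always yield a well-defined coefficient vector.
solve_least_squares <- function(G, b) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(ch)) {
    return(drop(backsolve(ch, forwardsolve(t(ch), b))))
  }
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, length(b)))
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
}
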