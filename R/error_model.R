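#' Type-specific substitution error model
#'
#' A 4x4 matrix of base substitution rates `e(a -> b)`: the probability that
#' a sequenced base whose true identity is `a` is read as `b`. Rows are true
#' alleles, columns observed bases, both in A, C, G, T order. The diagonal is
#' defined as `1 - sum` of the off-diagonal entries of its row, so every row
#' is a probability distribution over observed bases.
#'
#' @param rates A 4x4 numeric matrix of rates. Off-diagonal entries must lie
#'   in `[0, 0.5)`; the diagonal is recomputed from the row sums and any
#'   supplied diagonal values are ignored.
#' @return An object of class `error_model`: the validated 4x4 matrix with
#'   dimnames `A, C, G, T`.
#' @examples
#' uniform_error_model(0.0025)
#' @export
error_model <- function(rates) {
  rates <- as.matrix(rates)
  stopifnot(is.numeric(rates), all(dim(rates) == c(4L, 4L)))
  dimnames(rates) <- list(true = ALLELES, observed = ALLELES)
  off <- rates
  diag(off) <- 0
  if (any(off < 0) || any(off >= 0.5)) {
    stop("off-diagonal error rates must lie in [0, 0.5)", call. = FALSE)
  }
  diag(rates) <- 1 - rowSums(off)
  structure(rates, class = c("error_model", "matrix", "array"))
}

#' @rdname error_model
#' @param rate Single per-substitution-type rate applied to every
#'   off-diagonal entry (default 0.0025, i.e. 0.25% for all error types).
#' @export
uniform_error_model <- function(rate = 0.0025) {
  m <- matrix(rate, 4L, 4L)
  error_model(m)
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> type-specific substitution rates e(true -> observed)\n")
  print(unclass(signif(x, 4)))
  invisible(x)
}

#' Tidy an error model into a long tibble
#'
#' @param x An `error_model`.
#' @param ... Unused.
#' @return A tibble with columns `true`, `observed`, `rate`, one row per
#'   ordered allele pair (16 rows).
#' @exportS3Method generics::tidy
tidy.error_model <- function(x, ...) {
  tibble(
    true = rep(ALLELES, times = 4L),
    observed = rep(ALLELES, each = 4L),
    rate = as.vector(unclass(x))
  )
}
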