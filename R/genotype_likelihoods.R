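#' Genotype likelihoods from base counts and a type-specific error model
#'
#' For a diallelic site with major allele `M` and candidate minor allele
#' `m`, the likelihood of carrying `g` copies of `m` given the filtered
#' base counts is the product over observed bases `b` of
#' `(g/2) * P(b | m) + (1 - g/2) * P(b | M)`, with `P(b | a)` a row of the
#' [error_model]. Likelihoods are accumulated in log space and returned
#' rescaled so the largest of the three equals 1; an individual with zero
#' depth gets the flat triple `(1, 1, 1)`.
#'
#' @param counts Base counts: a named numeric vector with entries
#'   `A`, `C`, `G`, `T` (one individual), or a data frame with columns
#'   `nA`, `nC`, `nG`, `nT` (one row per individual).
#' @param major,minor Single characters in `A`, `C`, `G`, `T`;
#'   `major != minor`.
#' @param err An [error_model].
#' @return A tibble with one row per individual and columns `L0`, `L1`,
#'   `L2`: scaled likelihoods of 0, 1, 2 copies of the minor allele.
#' @examples
#' genotype_likelihoods(c(A = 5, C = 0, G = 0, T = 0), "A", "C",
#'                      uniform_error_model(0))
#' @export
genotype_likelihoods <- function(counts, major, minor, err) {
  stopifnot(major %in% ALLELES, minor %in% ALLELES, major != minor,
            inherits(err, "error_model"))
  if (is.numeric(counts) && !is.matrix(counts)) {
    counts <- tibble(nA = counts[["A"]], nC = counts[["C"]],
                     nG = counts[["G"]], nT = counts[["T"]])
  }
  mats <- lapply(c(A = "nA", C = "nC", G = "nG", T = "nT"),
                 function(col) matrix(as.numeric(counts[[col]]), ncol = 1))
  ll <- gl_log_matrices(mats, rep(major, nrow(counts)),
                        rep(minor, nrow(counts)), err)
  sc <- scale_gl(ll)
  tibble(L0 = as.vector(sc$L0), L1 = as.vector(sc$L1), L2 = as.vector(sc$L2))
}

# Unscaled log-likelihood matrices (sites x individuals) for g = 0, 1, 2
# copies of the per-site minor allele. `counts` is a list of four
# sites x individuals matrices named A, C, G, T; `major`, `minor` are
# per-site allele vectors. Exact in log space: a pure sum of
# count * log(prob) terms.
gl_log_matrices <- function(counts, major, minor, err) {
  pM <- unclass(err)[major, , drop = FALSE]  # sites x 4 observed-base probs
  pm <- unclass(err)[minor, , drop = FALSE]
  out <- vector("list", 3L)
  for (gi in 1:3) {
    g <- gi - 1L
    p <- (g / 2) * pm + (1 - g / 2) * pM
    lp <- log(p)  # may be -Inf when p = 0; zero-count terms are zeroed below
    acc <- matrix(0, nrow(counts$A), ncol(counts$A))
    for (bi in 1:4) {
      cb <- counts[[ALLELES[bi]]]
      term <- cb * lp[, bi]  # lp column recycles down the site dimension
      term[cb == 0L] <- 0
      acc <- acc + term
    }
    out[[gi]] <- acc
  }
  names(out) <- c("l0", "l1", "l2")
  out
}

# Rescale log-likelihood matrices to linear space with per-cell max = 1.
# `shift` optionally supplies a shared per-cell constant (e.g. the max over
# several candidate minors) so scaled likelihoods stay comparable across
# candidates.
scale_gl <- function(ll, shift = NULL) {
  if (is.null(shift)) shift <- pmax(ll$l0, ll$l1, ll$l2)
  list(
    L0 = exp(ll$l0 - shift),
    L1 = exp(ll$l1 - shift),
    L2 = exp(ll$l2 - shift),
    shift = shift
  )
}

#' Genotype-likelihood set for a panel of sites
#'
#' Computes scaled genotype likelihoods for every site of a [base_counts]
#' object at the site's designated major/minor alleles.
#'
#' @param bcm A [base_counts] object.
#' @param sites A data frame with one row per site of `bcm`, carrying
#'   `major` and `minor` columns (e.g. the output of [discover_snps()]).
#' @param err An [error_model].
#' @return An object of class `gl_set`: list with scaled likelihood
#'   matrices `L0`, `L1`, `L2` (sites x individuals), the site table and
#'   individual ids. [as_tibble()] gives the long `(site, individual,
#'   L0, L1, L2)` form.
#' @export
compute_gl <- function(bcm, sites, err) {
  stopifnot(inherits(bcm, "base_counts"), nrow(sites) == nrow(bcm$sites))
  ll <- gl_log_matrices(bcm$counts, sites$major, sites$minor, err)
  sc <- scale_gl(ll)
  structure(
    list(L0 = sc$L0, L1 = sc$L1, L2 = sc$L2,
         sites = as_tibble(sites), individuals = bcm$individuals),
    class = "gl_set"
  )
}

#' @export
print.gl_set <- function(x, ...) {
  cat("<gl_set> ", nrow(x$sites), " sites x ", length(x$individuals),
      " individuals\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble gl_set
as_tibble.gl_set <- function(x, ...) {
  ns <- nrow(x$sites)
  ni <- length(x$individuals)
  tibble(
    chrom = rep(x$sites$chrom, times = ni),
    pos = rep(x$sites$pos, times = ni),
    indiv = rep(x$individuals, each = ns),
    L0 = as.vector(x$L0), L1 = as.vector(x$L1), L2 = as.vector(x$L2)
  )
}
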