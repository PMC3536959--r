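#' Estimate type-specific error rates from putative polymorphic sites
#'
#' Iterative (EM-style) estimation of the 4x4 substitution error matrix
#' directly from the data. Each site has a major allele (most-supported
#' base, allele-order tie-break) and, for putative polymorphic sites, a
#' minor allele (second-most-supported base). Given the current error
#' model, minor-allele frequencies are re-estimated by [ml_maf] EM; each
#' observed base then carries a posterior over its true allele
#' (major vs minor, weighted by the individual's posterior minor dosage),
#' and the expected true-vs-observed counts are tabulated with a +1
#' pseudocount per cell to keep all rates positive and downstream
#' log-likelihoods finite. Rows are renormalised and the scheme iterates
#' until the largest off-diagonal change is below `tol`.
#'
#' Sites not in `putative_sites` are treated as monomorphic: every base
#' there is attributed to the major allele, so off-major bases count as
#' errors.
#'
#' @param bcm A [base_counts] object.
#' @param putative_sites Integer indices (rows of `bcm$sites`) of putative
#'   polymorphic sites. May be empty: errors are then estimated from
#'   off-major bases alone.
#' @param err0 Starting [error_model] (default uniform 0.25%).
#' @param tol Convergence tolerance on the off-diagonal rates
#'   (default 1e-6).
#' @param max_iter Maximum outer iterations (default 100).
#' @param em_iter EM iterations per outer pass for the frequency updates.
#' @return An [error_model] with attributes `n_iter` and `converged`.
#' @export
estimate_error_model <- function(bcm, putative_sites = integer(0),
                                 err0 = uniform_error_model(0.0025),
                                 tol = 1e-6, max_iter = 100, em_iter = 50) {
  stopifnot(inherits(bcm, "base_counts"), nrow(bcm$sites) >= 1)
  ns <- nrow(bcm$sites)
  pc <- pooled_counts(bcm)
  major <- site_major_allele(bcm)
  mi_major <- match(major, ALLELES)
  pc_minor <- pc
  pc_minor[cbind(seq_len(ns), mi_major)] <- -1
  minor <- ALLELES[apply(pc_minor, 1, which.max)]
  mi_minor <- match(minor, ALLELES)

  poly <- rep(FALSE, ns)
  poly[putative_sites] <- TRUE
  depth_tot <- pmax(rowSums(pc), 1)
  f <- ifelse(poly, pmax(pc[cbind(seq_len(ns), mi_minor)] / depth_tot, 1e-4), 0)

  err <- err0
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    ll <- gl_log_matrices(bcm$counts, major, minor, err)
    sc <- scale_gl(ll)
    if (any(poly)) {
      fit <- em_maf_mat(sc$L0, sc$L1, sc$L2, f0 = pmax(f, 1e-4),
                        max_iter = em_iter)
      f <- ifelse(poly, fit$f, 0)
    }
    # genotype posteriors per site x individual
    w0 <- sc$L0 * (1 - f)^2
    w1 <- sc$L1 * (2 * f * (1 - f))
    w2 <- sc$L2 * f^2
    s <- pmax(w0 + w1 + w2, 1e-300)
    p1 <- w1 / s
    p2 <- w2 / s

    pM <- unclass(err)[major, , drop = FALSE]  # sites x 4
    pm <- unclass(err)[minor, , drop = FALSE]
    C <- matrix(0, 4, 4, dimnames = list(ALLELES, ALLELES))
    for (bi in 1:4) {
      cb <- bcm$counts[[ALLELES[bi]]]
      # posterior that an observed `bi` base is a read of the true minor
      # allele, mixed over the genotype posterior: under g=0 it is 0,
      # under g=2 it is 1, under g=1 it is pm / (pm + pM)
      rho_het <- pm[, bi] / pmax(pm[, bi] + pM[, bi], 1e-300)
      rho <- p1 * rho_het + p2
      cm <- cb * rho
      c_minor <- rowSums(cm)
      c_major <- rowSums(cb) - c_minor
      for (ai in 1:4) {
        C[ai, bi] <- sum(c_minor[mi_minor == ai]) +
          sum(c_major[mi_major == ai])
      }
    }
    new_rates <- (C + 1) / rowSums(C + 1)
    # alleles never observed as a true allele carry no information:
    # keep their current rates rather than the flat pseudocount row
    empty <- rowSums(C) == 0
    new_rates[empty, ] <- unclass(err)[empty, ]
    off <- new_rates
    diag(off) <- 0
    old_off <- unclass(err)
    diag(old_off) <- 0
    delta <- max(abs(off - old_off))
    err <- error_model(new_rates)
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= max_iter) break
  }
  attr(err, "n_iter") <- n_iter
  attr(err, "converged") <- converged
  err
}
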