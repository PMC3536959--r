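#' Maximum-likelihood minor-allele frequency under Hardy-Weinberg
#'
#' EM estimation of the minor-allele frequency `f` from per-individual
#' genotype likelihoods, maximising
#' `L(f) = prod_i sum_g L_i(g) * HWE(g; f)` with
#' `HWE = (1-f)^2, 2f(1-f), f^2`. The E-step weights are
#' `w_i(g) ∝ L_i(g) * HWE(g; f)` and the M-step is
#' `f' = (1/2N) * sum_i sum_g g * w_i(g)`. The log-likelihood is
#' non-decreasing at every step. Iteration stops when `|Δf| < tol`.
#'
#' `f` is the frequency of the designated candidate allele and is allowed
#' to exceed 0.5 during estimation; relabelling is applied post hoc by the
#' site-level wrappers.
#'
#' @param gls A data frame (or matrix) with columns `L0`, `L1`, `L2`: one
#'   row per individual, likelihoods of 0/1/2 copies of the candidate
#'   minor allele (any positive per-individual scaling is allowed).
#' @param init Starting frequency; default is the naive likelihood-weighted
#'   dosage mean, floored at 1e-4.
#' @param tol Convergence tolerance on `|Δf|` (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @return An object of class `maf_fit`: list with elements `f`, `loglik`
#'   (up to the per-individual scaling constant), `n_iter`, `converged`,
#'   `non_identifiable` (all likelihood triples flat) and `n`.
#' @examples
#' ml_maf(tibble::tibble(L0 = 0, L1 = 1, L2 = 0))  # one certain het -> 0.5
#' @export
ml_maf <- function(gls, init = NULL, tol = 1e-6, max_iter = 200) {
  gls <- as.data.frame(gls)
  stopifnot(all(c("L0", "L1", "L2") %in% names(gls)), nrow(gls) >= 1)
  L0 <- matrix(gls$L0, nrow = 1)
  L1 <- matrix(gls$L1, nrow = 1)
  L2 <- matrix(gls$L2, nrow = 1)
  if (is.null(init)) {
    s <- gls$L0 + gls$L1 + gls$L2
    init <- max(mean((gls$L1 + 2 * gls$L2) / (2 * s)), 1e-4)
  }
  fit <- em_maf_mat(L0, L1, L2, f0 = init, tol = tol, max_iter = max_iter)
  structure(
    list(f = fit$f, loglik = fit$loglik, n_iter = fit$n_iter,
         converged = fit$converged, non_identifiable = fit$flat,
         n = ncol(L0)),
    class = "maf_fit"
  )
}

#' @export
print.maf_fit <- function(x, ...) {
  cat("<maf_fit> f = ", signif(x$f, 5), ", loglik = ", signif(x$loglik, 7),
      " (", x$n, " individuals, ", x$n_iter, " EM iterations)\n", sep = "")
  if (any(x$non_identifiable)) cat("  flagged non-identifiable\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maf_fit <- function(x, ...) {
  tibble(term = "maf", estimate = unname(x$f))
}

#' @exportS3Method generics::glance
glance.maf_fit <- function(x, ...) {
  tibble(maf = unname(x$f), loglik = unname(x$loglik), n = x$n,
         n_iter = x$n_iter, converged = all(x$converged),
         non_identifiable = any(x$non_identifiable))
}

# Vectorised EM over sites: L0/L1/L2 are sites x individuals scaled
# likelihood matrices, f0 a per-site (or scalar) start. Returns per-site
# f, loglik, iteration count, convergence and flat-likelihood flags.
em_maf_mat <- function(L0, L1, L2, f0, tol = 1e-6, max_iter = 200) {
  ns <- nrow(L0)
  ni <- ncol(L0)
  flat <- rowSums(L0 == L1 & L1 == L2) == ni
  f <- rep_len(pmin(pmax(f0, 1e-4), 1 - 1e-4), ns)
  n_iter <- 0L
  converged <- rep(FALSE, ns)
  repeat {
    n_iter <- n_iter + 1L
    w0 <- L0 * (1 - f)^2
    w1 <- L1 * (2 * f * (1 - f))
    w2 <- L2 * f^2
    s <- pmax(w0 + w1 + w2, 1e-300)
    f_new <- rowSums((w1 + 2 * w2) / s) / (2 * ni)
    delta <- abs(f_new - f)
    f <- f_new
    f[flat] <- rep_len(pmin(pmax(f0, 1e-4), 1 - 1e-4), ns)[flat]
    converged <- converged | delta < tol
    if (all(delta < tol) || n_iter >= max_iter) break
  }
  list(f = f, loglik = gl_loglik_at(L0, L1, L2, f), n_iter = n_iter,
       converged = delta < tol, flat = flat)
}

# Per-site log-likelihood of the HWE mixture at fixed frequency f
# (up to the per-individual likelihood scaling constants).
gl_loglik_at <- function(L0, L1, L2, f) {
  s <- L0 * (1 - f)^2 + L1 * (2 * f * (1 - f)) + L2 * f^2
  rowSums(log(pmax(s, 1e-300)))
}

#' Site frequency with minor-allele uncertainty
#'
#' Estimates the minor-allele frequency of one site while treating the
#' identity of the minor allele as unknown: with the major allele fixed at
#' the most-supported base, the total likelihood sums
#' `(1/3) * L_m(f_m)` over the three candidate minor alleles, each
#' evaluated at its own EM optimum. The reported frequency and minor
#' allele come from the maximal component; exact ties are broken by
#' allele order (A < C < G < T) and flagged. If the best estimate exceeds
#' 0.5 the alleles are relabelled (`f -> 1 - f`) and flagged.
#'
#' @param counts Base counts for the site: a data frame with columns
#'   `nA`, `nC`, `nG`, `nT`, one row per individual.
#' @param major The major allele; defaults to the most-supported base in
#'   the pooled counts (allele-order tie-break).
#' @param err An [error_model].
#' @inheritParams ml_maf
#' @return A one-row tibble of class `site_frequency`: `major`, `minor`,
#'   `f_hat`, `loglik` (minor-sum total), `tie`, `relabelled`,
#'   `non_identifiable`, plus a nested `components` tibble with the three
#'   per-minor EM optima.
#' @export
ml_maf_minor_sum <- function(counts, major = NULL, err = uniform_error_model(),
                             tol = 1e-6, max_iter = 200) {
  counts <- as.data.frame(counts)
  mats <- lapply(c(A = "nA", C = "nC", G = "nG", T = "nT"),
                 function(col) matrix(as.numeric(counts[[col]]), nrow = 1))
  names(mats) <- ALLELES
  if (is.null(major)) {
    pooled <- vapply(mats, sum, numeric(1))
    major <- ALLELES[which.max(pooled)]
  }
  res <- minor_sum_mat(mats, major, err, tol = tol, max_iter = max_iter)
  out <- tibble(
    major = res$major, minor = res$minor, f_hat = res$f_hat,
    loglik = res$loglik, tie = res$tie, relabelled = res$relabelled,
    non_identifiable = res$non_identifiable,
    components = list(tibble(minor = res$cand_minor[1, ],
                             f = res$cand_f[1, ],
                             loglik = res$cand_ll[1, ]))
  )
  class(out) <- c("site_frequency", class(out))
  out
}

# Vectorised minor-sum estimator. `counts` is the list of 4 sites x
# individuals matrices, `major` a per-site allele vector. Candidate minors
# are evaluated with a shared per-cell scaling constant so their
# log-likelihoods are directly comparable.
minor_sum_mat <- function(counts, major, err, tol = 1e-6, max_iter = 200) {
  ns <- nrow(counts$A)
  major <- rep_len(major, ns)
  cand <- t(vapply(major, function(m) setdiff(ALLELES, m), character(3)))
  if (ns == 1L) cand <- matrix(cand, nrow = 1)

  lls <- lapply(1:3, function(k) {
    gl_log_matrices(counts, major, cand[, k], err)
  })
  shift <- Reduce(pmax, unlist(lls, recursive = FALSE))
  depth <- counts$A + counts$C + counts$G + counts$T
  total_reads <- rowSums(depth)

  cand_f <- matrix(NA_real_, ns, 3)
  cand_ll <- matrix(NA_real_, ns, 3)
  flat <- rep(TRUE, ns)
  for (k in 1:3) {
    sc <- scale_gl(lls[[k]], shift = shift)
    # naive start: pooled read fraction of the candidate allele
    cr <- vapply(seq_len(ns), function(i) {
      sum(counts[[cand[i, k]]][i, ])
    }, numeric(1))
    f0 <- ifelse(total_reads > 0, cr / pmax(total_reads, 1), 1e-4)
    fit <- em_maf_mat(sc$L0, sc$L1, sc$L2, f0 = f0, tol = tol,
                      max_iter = max_iter)
    cand_f[, k] <- fit$f
    cand_ll[, k] <- fit$loglik
    flat <- flat & fit$flat
  }

  best <- max.col(cand_ll, ties.method = "first")
  tie <- vapply(seq_len(ns), function(i) {
    sum(abs(cand_ll[i, ] - cand_ll[i, best[i]]) < 1e-9) > 1L
  }, logical(1))
  idx <- cbind(seq_len(ns), best)
  f_hat <- cand_f[idx]
  minor <- cand[idx]
  # minor-sum total: log( (1/3) * sum_m exp(ll_m) ), logsumexp-stabilised
  mx <- cand_ll[idx]
  loglik <- mx + log(rowSums(exp(cand_ll - mx)) / 3)

  relabelled <- !flat & f_hat > 0.5
  new_major <- ifelse(relabelled, minor, major)
  new_minor <- ifelse(relabelled, major, minor)
  f_out <- ifelse(relabelled, 1 - f_hat, f_hat)
  f_out[flat] <- f_hat[flat]

  list(major = new_major, minor = new_minor, f_hat = f_out, loglik = loglik,
       tie = tie, relabelled = relabelled, non_identifiable = flat,
       cand_minor = cand, cand_f = cand_f, cand_ll = cand_ll,
       total_depth = total_reads)
}

#' Two-pass SNP discovery from base counts
#'
#' Pass 1 estimates every site's minor-allele frequency with a uniform
#' error model (0.25% for all error types) and flags putative polymorphic
#' sites as those with estimated frequency above `putative_threshold`
#' (default 0.25%). The putative sites feed [estimate_error_model()]; the
#' final pass re-estimates frequencies for all sites with the learned
#' type-specific error model.
#'
#' @param bcm A [base_counts] object.
#' @param err0 Initial uniform [error_model] (default 0.25% per error type).
#' @param putative_threshold Frequency above which a site is considered
#'   putatively polymorphic (default 0.0025; 0 flags every covered site).
#' @param estimate_errors If `FALSE`, skip error-model estimation and use
#'   `err0` in the final pass.
#' @inheritParams ml_maf
#' @return A tibble of class `snp_discovery` with one row per site:
#'   `chrom`, `pos`, `major`, `minor`, `f_hat`, `total_depth`, `loglik`,
#'   `putative`, `tie`, `relabelled`, `non_identifiable`. The learned
#'   error model is attached as attribute `"error_model"`.
#' @export
discover_snps <- function(bcm, err0 = uniform_error_model(0.0025),
                          putative_threshold = 0.0025,
                          estimate_errors = TRUE,
                          tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(bcm, "base_counts"))
  major <- site_major_allele(bcm)
  pass1 <- minor_sum_mat(bcm$counts, major, err0, tol = tol,
                         max_iter = max_iter)
  covered <- pass1$total_depth > 0
  putative <- covered & !pass1$non_identifiable &
    pmin(pass1$f_hat, 1 - pass1$f_hat) > putative_threshold
  err <- err0
  if (estimate_errors && any(putative)) {
    err <- estimate_error_model(bcm, which(putative), err0 = err0)
  }
  pass2 <- minor_sum_mat(bcm$counts, major, err, tol = tol,
                         max_iter = max_iter)
  out <- tibble(
    chrom = bcm$sites$chrom, pos = bcm$sites$pos,
    major = pass2$major, minor = pass2$minor,
    f_hat = pass2$f_hat, total_depth = pass2$total_depth,
    loglik = pass2$loglik, putative = putative,
    tie = pass2$tie, relabelled = pass2$relabelled,
    non_identifiable = pass2$non_identifiable
  )
  attr(out, "error_model") <- err
  class(out) <- c("snp_discovery", class(out))
  out
}

#' Stage-1 site inclusion filter
#'
#' Keeps sites with estimated minor-allele frequency strictly above
#' `maf_min` (default 1%) and total depth summed across individuals
#' strictly above `mean_depth_min` reads per individual (default 0.5x,
#' i.e. 1,000x total for 2,000 individuals). Strict inequalities at both
#' thresholds so reported counts are reproducible.
#'
#' @param sites A site table with columns `f_hat` and `total_depth`
#'   (e.g. from [discover_snps()]).
#' @param n_individuals Number of sequenced individuals.
#' @param maf_min Minor-allele frequency floor (default 0.01).
#' @param mean_depth_min Mean per-individual depth floor (default 0.5).
#' @return The filtered tibble.
#' @export
site_inclusion_filter <- function(sites, n_individuals, maf_min = 0.01,
                                  mean_depth_min = 0.5) {
  stopifnot(all(c("f_hat", "total_depth") %in% names(sites)))
  maf <- pmin(sites$f_hat, 1 - sites$f_hat)
  keep <- maf > maf_min & sites$total_depth > mean_depth_min * n_individuals
  dplyr::filter(sites, keep)
}
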