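# Naive per-site frequency start: likelihood-weighted mean dosage / 2.
naive_f0 <- function(L0, L1, L2) {
  s <- pmax(L0 + L1 + L2, 1e-300)
  pmin(pmax(rowMeans((L1 + 2 * L2) / (2 * s)), 1e-4), 1 - 1e-4)
}

#' Read-level case-control likelihood-ratio test
#'
#' Tests each site for an allele-frequency difference between cases and
#' controls directly on the genotype likelihoods, without calling
#' genotypes: `T = 2 * [l(f_case) + l(f_control) - l(f_all)]`, each
#' log-likelihood maximised by the [ml_maf] EM, compared to a chi-squared
#' distribution with 1 df. No covariates enter the test. Tiny negative
#' statistics from finite EM tolerance are clamped to zero;
#' non-identifiable sites (all likelihood triples flat) get `p = 1` and a
#' flag.
#'
#' @param gl A `gl_set` from [compute_gl()].
#' @param status Binary vector (1 = case, 0 = control) aligned with
#'   `gl$individuals`; both groups must be non-empty.
#' @inheritParams ml_maf
#' @return A tibble of class `site_assoc` with per-site `chrom`, `pos`,
#'   `major`, `minor`, `f_all`, `f_case`, `f_control`, `chisq`, `p`,
#'   `non_identifiable`.
#' @export
lrt_case_control <- function(gl, status, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(gl, "gl_set"),
            length(status) == length(gl$individuals))
  case <- which(status == 1)
  ctrl <- which(status == 0)
  stopifnot(length(case) > 0, length(ctrl) > 0)

  fit_grp <- function(ix) {
    L0 <- gl$L0[, ix, drop = FALSE]
    L1 <- gl$L1[, ix, drop = FALSE]
    L2 <- gl$L2[, ix, drop = FALSE]
    em_maf_mat(L0, L1, L2, f0 = naive_f0(L0, L1, L2),
               tol = tol, max_iter = max_iter)
  }
  all_fit <- fit_grp(c(case, ctrl))
  case_fit <- fit_grp(case)
  ctrl_fit <- fit_grp(ctrl)

  T_stat <- 2 * (case_fit$loglik + ctrl_fit$loglik - all_fit$loglik)
  T_stat[T_stat < 0] <- 0
  flat <- all_fit$flat
  p <- pchisq(T_stat, df = 1, lower.tail = FALSE)
  T_stat[flat] <- 0
  p[flat] <- 1

  out <- tibble(
    chrom = gl$sites$chrom, pos = gl$sites$pos,
    major = gl$sites$major, minor = gl$sites$minor,
    f_all = all_fit$f, f_case = case_fit$f, f_control = ctrl_fit$f,
    chisq = T_stat, p = p, non_identifiable = flat
  )
  class(out) <- c("site_assoc", class(out))
  out
}

#' Per-site bias filters for sequencing case-control data
#'
#' Operationalises stringent pre-association SNP filtering against
#' artefacts that could correlate with case-control status. Three
#' switchable per-site tests, each flagging at `flag_threshold`
#' (default p < 1e-4):
#' \describe{
#'   \item{depth}{tie-corrected rank-sum (normal approximation) of
#'     per-individual filtered depth, cases vs controls;}
#'   \item{missing}{chi-squared association of zero-depth status with
#'     case-control status;}
#'   \item{batch}{chi-squared association of error-like read support
#'     (bases matching neither site allele) with a batch label, a proxy
#'     for error-rate shifts over sequencing time.}
#' }
#' Sites failing any enabled test should be excluded from association.
#'
#' @param bcm A [base_counts] object.
#' @param status Binary case indicator per individual.
#' @param batch Optional batch labels per individual; if absent the batch
#'   test is skipped with a warning.
#' @param sites Optional site table with a `minor` column (e.g. from
#'   [discover_snps()]); defaults to the second-most-supported pooled base.
#' @param flag_threshold Per-test flagging p-value (default 1e-4).
#' @param tests Which of `"depth"`, `"missing"`, `"batch"` to run.
#' @return A tibble per site: `chrom`, `pos`, `p_depth`, `p_missing`,
#'   `p_batch`, matching `flag_*` columns and `flag_any`.
#' @export
bias_filters <- function(bcm, status, batch = NULL, sites = NULL,
                         flag_threshold = 1e-4,
                         tests = c("depth", "missing", "batch")) {
  stopifnot(inherits(bcm, "base_counts"),
            length(status) == length(bcm$individuals))
  tests <- match.arg(tests, several.ok = TRUE)
  ns <- nrow(bcm$sites)
  D <- depth_matrix(bcm)
  case <- status == 1

  p_depth <- rep(NA_real_, ns)
  if ("depth" %in% tests) {
    p_depth <- ranksum_rows(D, case)
  }
  p_missing <- rep(NA_real_, ns)
  if ("missing" %in% tests) {
    z <- D == 0
    p_missing <- chisq2x2_rows(
      a = rowSums(z[, case, drop = FALSE]),
      b = rowSums(!z[, case, drop = FALSE]),
      c = rowSums(z[, !case, drop = FALSE]),
      d = rowSums(!z[, !case, drop = FALSE])
    )
  }
  p_batch <- rep(NA_real_, ns)
  if ("batch" %in% tests) {
    if (is.null(batch)) {
      warning("no batch labels supplied; batch bias test skipped")
    } else {
      minor <- if (!is.null(sites) && "minor" %in% names(sites)) {
        sites$minor
      } else {
        pc <- pooled_counts(bcm)
        pc[cbind(seq_len(ns), match(site_major_allele(bcm), ALLELES))] <- -1
        ALLELES[apply(pc, 1, which.max)]
      }
      p_batch <- batch_support_test(bcm, minor, batch)
    }
  }
  flag <- function(p) !is.na(p) & p < flag_threshold
  tibble(
    chrom = bcm$sites$chrom, pos = bcm$sites$pos,
    p_depth = p_depth, p_missing = p_missing, p_batch = p_batch,
    flag_depth = flag(p_depth), flag_missing = flag(p_missing),
    flag_batch = flag(p_batch),
    flag_any = flag(p_depth) | flag(p_missing) | flag(p_batch)
  )
}

# Row-wise two-sample rank-sum test (normal approximation, tie-corrected).
ranksum_rows <- function(X, in_group1) {
  n <- ncol(X)
  n1 <- sum(in_group1)
  n2 <- n - n1
  R <- t(apply(X, 1, rank))
  W <- rowSums(R[, in_group1, drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tie_term <- apply(X, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(v > 0, (W - mu) / sqrt(v), 0)
  2 * pnorm(-abs(z))
}

# Row-wise 2x2 chi-squared test (no continuity correction); degenerate
# margins give p = 1.
chisq2x2_rows <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den > 0, num / den, 0)
  ifelse(den > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
}

# Per-site chi-squared test of (error-like reads vs allele-matching reads)
# x batch. "Error-like" means bases matching neither site allele: unlike
# minor-allele support these are independent at read level (no genotype
# clustering), so the chi-squared null is calibrated, and they respond
# directly to a batch-specific error-rate shift.
batch_support_test <- function(bcm, minor, batch) {
  batch <- as.factor(batch)
  levs <- levels(batch)
  ns <- nrow(bcm$sites)
  major <- site_major_allele(bcm)
  off_counts <- matrix(0, ns, length(levs))
  on_counts <- matrix(0, ns, length(levs))
  off_mat <- matrix(0, ns, length(bcm$individuals))
  for (a in ALLELES) {
    sel <- major != a & minor != a
    if (any(sel)) {
      off_mat[sel, ] <- off_mat[sel, , drop = FALSE] +
        bcm$counts[[a]][sel, , drop = FALSE]
    }
  }
  D <- depth_matrix(bcm)
  for (j in seq_along(levs)) {
    ix <- batch == levs[j]
    off_counts[, j] <- rowSums(off_mat[, ix, drop = FALSE])
    on_counts[, j] <- rowSums(D[, ix, drop = FALSE]) - off_counts[, j]
  }
  minor_counts <- off_counts
  other_counts <- on_counts
  row_m <- rowSums(minor_counts)
  row_o <- rowSums(other_counts)
  tot <- row_m + row_o
  p <- rep(1, ns)
  ok <- tot > 0 & row_m > 0 & row_o > 0
  if (any(ok)) {
    stat <- rep(0, ns)
    for (j in seq_along(levs)) {
      col_tot <- minor_counts[, j] + other_counts[, j]
      e_m <- row_m * col_tot / tot
      e_o <- row_o * col_tot / tot
      stat <- stat + ifelse(e_m > 0, (minor_counts[, j] - e_m)^2 / e_m, 0) +
        ifelse(e_o > 0, (other_counts[, j] - e_o)^2 / e_o, 0)
    }
    p[ok] <- pchisq(stat[ok], df = length(levs) - 1, lower.tail = FALSE)
  }
  p
}

#' Genomic-control correction of association statistics
#'
#' The inflation factor is `lambda = median(chisq) / qchisq(0.5, 1)`. If
#' `lambda > 1` every statistic is deflated by `lambda` and the p-values
#' recomputed; `lambda <= 1` leaves results unchanged.
#'
#' @param results A data frame with a chi-squared statistic column
#'   (1 df) and a p-value column.
#' @param chisq_col,p_col Column names (defaults `"chisq"`, `"p"`).
#' @return An object of class `gc_result`: list with `results` (the input
#'   tibble plus `chisq_gc` and `p_gc`), `lambda_gc`, `n_sites` and
#'   `method = "median"`.
#' @export
genomic_control <- function(results, chisq_col = "chisq", p_col = "p") {
  stopifnot(chisq_col %in% names(results), nrow(results) >= 1)
  chisq <- results[[chisq_col]]
  lambda <- median(chisq, na.rm = TRUE) / qchisq(0.5, df = 1)
  out <- as_tibble(results)
  if (lambda > 1) {
    out$chisq_gc <- chisq / lambda
    out$p_gc <- pchisq(out$chisq_gc, df = 1, lower.tail = FALSE)
  } else {
    out$chisq_gc <- chisq
    out$p_gc <- if (p_col %in% names(results)) results[[p_col]] else
      pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  structure(
    list(results = out, lambda_gc = lambda,
         n_sites = sum(!is.na(chisq)), method = "median"),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat("<gc_result> lambda_GC = ", signif(x$lambda_gc, 4), " over ",
      x$n_sites, " sites (median method)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gc_result <- function(x, ...) {
  tibble(lambda_gc = x$lambda_gc, n_sites = x$n_sites, method = x$method)
}

#' Select SNPs for stage-2 genotyping
#'
#' Union of three criteria: (1) nominal case-control association
#' (`p < 0.05`) in the sequencing data; (2) annotation in one of the four
#' prioritised categories (nonsense, non-synonymous, splice, UTR)
#' regardless of p-value; (3) synonymous variants inside loci previously
#' associated with the traits of interest. Each site is tagged with every
#' reason it satisfies; sites without annotation are eligible via
#' criterion (1) only.
#'
#' @param results A data frame with per-SNP `p`, optional `annotation`
#'   (one of nonsense, non-synonymous, splice, UTR, synonymous, intron,
#'   near-gene, intergenic; `NA` allowed) and optional logical
#'   `known_locus`.
#' @param p_threshold Criterion-1 threshold (default 0.05).
#' @param coding_categories Criterion-2 annotation set.
#' @return The tibble with logical columns `crit_assoc`,
#'   `crit_annotation`, `crit_known_synonymous` and `selected`. Tabulate
#'   the exclusive selection-reason bookkeeping with
#'   [stage2_reason_counts()].
#' @export
select_stage2 <- function(results, p_threshold = 0.05,
                          coding_categories = c("nonsense", "non-synonymous",
                                                "splice", "UTR")) {
  stopifnot("p" %in% names(results))
  out <- as_tibble(results)
  ann <- if ("annotation" %in% names(out)) out$annotation else
    rep(NA_character_, nrow(out))
  known <- if ("known_locus" %in% names(out)) out$known_locus else
    rep(FALSE, nrow(out))
  known[is.na(known)] <- FALSE
  out$crit_assoc <- !is.na(out$p) & out$p < p_threshold
  out$crit_annotation <- !is.na(ann) & ann %in% coding_categories
  out$crit_known_synonymous <- !is.na(ann) & ann == "synonymous" & known
  out$selected <- out$crit_assoc | out$crit_annotation |
    out$crit_known_synonymous
  out
}

#' @rdname select_stage2
#' @param selected Output of [select_stage2()].
#' @return `stage2_reason_counts()`: a tibble of mutually exclusive
#'   bookkeeping counts (`assoc_only`, `annotation_only`,
#'   `assoc_and_annotation`, `known_synonymous_only`, `total_selected`).
#' @export
stage2_reason_counts <- function(selected) {
  r1 <- selected$crit_assoc
  r2 <- selected$crit_annotation
  r3 <- selected$crit_known_synonymous
  # exclusive partition: association and annotation take precedence, the
  # known-locus synonymous criterion only counts SNPs not already selected
  tibble(
    reason = c("assoc_only", "annotation_only", "assoc_and_annotation",
               "known_synonymous_only", "total_selected"),
    n = c(sum(r1 & !r2), sum(r2 & !r1), sum(r1 & r2),
          sum(r3 & !r1 & !r2), sum(selected$selected))
  )
}
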