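#' Per-SNP genotype quality control
#'
#' Applies the standard array-QC filters with strict inequalities:
#' minor-allele frequency > `maf_min` (default 0.5%), genotype call rate
#' > `call_rate_min` (default 95%) and Hardy-Weinberg exact-test
#' p > `hwe_min` (default 1e-7). Monomorphic SNPs are flagged and fail
#' the MAF filter.
#'
#' @param genotypes A SNPs-by-individuals matrix of minor-allele dosages
#'   in `{0, 1, 2, NA}` (or a `cohort`).
#' @param maf_min,call_rate_min,hwe_min Filter thresholds.
#' @return A tibble of class `snp_qc_report`: `snp`, `maf`, `call_rate`,
#'   `hwe_p`, `monomorphic`, `pass`, `reason` (comma-separated failing
#'   filters, `NA` if passed).
#' @export
snp_qc <- function(genotypes, maf_min = 0.005, call_rate_min = 0.95,
                   hwe_min = 1e-7) {
  G <- genotype_matrix(genotypes)
  stopifnot(all(G %in% c(0L, 1L, 2L, NA)))
  n <- ncol(G)
  n_called <- rowSums(!is.na(G))
  call_rate <- n_called / n
  n_het <- rowSums(G == 1L, na.rm = TRUE)
  n_hom_minor <- rowSums(G == 2L, na.rm = TRUE)
  n_hom_major <- n_called - n_het - n_hom_minor
  freq <- ifelse(n_called > 0, (n_het + 2 * n_hom_minor) / (2 * n_called), 0)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- mapply(hwe_exact, n_hom_major, n_het, n_hom_minor)
  monomorphic <- n_het + n_hom_minor == 0 | n_hom_major + n_het == 0

  fail_maf <- !(maf > maf_min)
  fail_cr <- !(call_rate > call_rate_min)
  fail_hwe <- !(hwe_p > hwe_min)
  reason <- mapply(function(m, cr, h) {
    r <- c(if (m) "maf", if (cr) "call_rate", if (h) "hwe")
    if (length(r) == 0) NA_character_ else paste(r, collapse = ",")
  }, fail_maf, fail_cr, fail_hwe)

  out <- tibble(
    snp = rownames(G) %||% sprintf("snp%05d", seq_len(nrow(G))),
    maf = maf, call_rate = call_rate, hwe_p = hwe_p,
    monomorphic = monomorphic,
    pass = !(fail_maf | fail_cr | fail_hwe), reason = reason
  )
  class(out) <- c("snp_qc_report", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

genotype_matrix <- function(x) {
  if (inherits(x, "cohort")) x$genotypes else as.matrix(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the
#' heterozygote count under HWE follows the distribution
#' `P(n_het) \propto n! / (n_AA! n_Aa! n_aa!) * 2^n_het`; the two-sided
#' p-value sums the probabilities of all heterozygote counts no more
#' probable than the observed one. Sites with zero minor alleles return
#' `p = 1`.
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts (non-negative).
#' @return The exact p-value.
#' @examples
#' hwe_exact(50, 0, 50)  # extreme heterozygote deficit
#' @export
hwe_exact <- function(n_hom_major, n_het, n_hom_minor) {
  stopifnot(n_hom_major >= 0, n_het >= 0, n_hom_minor >= 0)
  n <- n_hom_major + n_het + n_hom_minor
  n_minor <- 2 * n_hom_minor + n_het
  n_minor <- min(n_minor, 2 * n - n_minor)  # fold to the rarer allele
  if (n == 0 || n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(h | allele counts) up to a constant
  lp <- hets * log(2) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma(n - (n_minor + hets) / 2 + 1)
  lp <- lp - max(lp)
  prob <- exp(lp) / sum(exp(lp))
  obs <- match(min(n_het, n_minor), hets)
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

#' Rank-based inverse-normal transform
#'
#' Maps values through their ranks to standard-normal quantiles:
#' `qnorm((rank - 0.5) / n)` over the non-missing values, with ties
#' resolved by average rank. Missing values are propagated. This makes
#' heterogeneous quantitative traits comparable and regression residuals
#' approximately normal; results on the transformed scale are invariant
#' to any monotone transform of the raw trait that preserves the tie
#' structure.
#'
#' @param x Numeric vector, possibly with `NA`.
#' @return The transformed vector, same length and missingness as `x`.
#' @export
rank_inverse_normal <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2) stop("need at least 2 non-missing values", call. = FALSE)
  if (length(unique(x[obs])) == 1) {
    stop("constant vector cannot be rank-normalised", call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- qnorm((r - 0.5) / n)
  out
}

#' First principal component of the genotype covariance
#'
#' Computes the individual-by-individual covariance of mean-centred
#' genotypes (pairwise-complete over missing calls) and returns the
#' leading eigenvector as a per-individual ancestry covariate. The sign
#' is fixed so the largest-magnitude loading is positive, making the
#' component deterministic across runs. For large panels the covariance
#' is built from a seeded random subset of at most `max_snps` SNPs.
#'
#' @param genotypes SNPs-by-individuals dosage matrix (or `cohort`).
#' @param max_snps SNP subset size for scalability (default 10,000).
#' @param seed Seed for the SNP subsample (default 1).
#' @return A tibble with `individual` and `pc1` (unit-norm scores).
#' @export
pca_first_component <- function(genotypes, max_snps = 10000, seed = 1) {
  G <- genotype_matrix(genotypes)
  stopifnot(nrow(G) >= 2, ncol(G) >= 2)
  if (nrow(G) > max_snps) {
    set.seed(seed)
    G <- G[sort(sample.int(nrow(G), max_snps)), , drop = FALSE]
  }
  M <- G - rowMeans(G, na.rm = TRUE)
  obs <- !is.na(M)
  M[!obs] <- 0
  cov_ij <- crossprod(M)                    # sum of products over shared SNPs
  n_ij <- crossprod(obs * 1)                # pairwise-complete SNP counts
  if (any(n_ij == 0)) stop("individuals share no observed SNPs", call. = FALSE)
  C <- cov_ij / n_ij
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[1] <= 1e-12) {
    stop("genotype covariance has rank 0", call. = FALSE)
  }
  v <- eg$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  tibble(individual = colnames(G) %||% sprintf("ind%05d", seq_len(ncol(G))),
         pc1 = v)
}

#' Additive single-SNP regression association
#'
#' Fits, per SNP, a linear (continuous trait) or logistic (binary trait)
#' regression of the phenotype on the minor-allele dosage plus
#' covariates, by least squares / iteratively reweighted least squares,
#' and reports the Wald test on the genotype term. Analyses are
#' complete-case per SNP. Optional conditioning SNPs enter as additional
#' dosage covariates (a SNP conditioned on itself is collinear, flagged
#' with a missing p-value, as is any separated or non-converged logistic
#' fit).
#'
#' @param genotypes SNPs-by-individuals dosage matrix (or `cohort`).
#' @param phenotype Numeric vector per individual. Binary 0/1 phenotypes
#'   get logistic regression (log-additive model); anything else linear
#'   regression. Rank-normalise quantitative traits first
#'   ([rank_inverse_normal()]).
#' @param covariates Optional data frame of per-individual covariates
#'   (e.g. `pc1` and `sex`).
#' @param condition_on Optional character vector of SNP ids (rownames of
#'   `genotypes`) to condition every fit on.
#' @param model `"auto"` (default), `"linear"` or `"logistic"`.
#' @return A tibble of class `cohort_assoc`: per SNP `snp`, `beta`, `se`,
#'   `p`, `n`, `direction` (`"+"`/`"-"`), `converged`.
#' @export
assoc_additive <- function(genotypes, phenotype, covariates = NULL,
                           condition_on = NULL, model = "auto") {
  G <- genotype_matrix(genotypes)
  model <- match.arg(model, c("auto", "linear", "logistic"))
  stopifnot(length(phenotype) == ncol(G))
  vals <- unique(na.omit(phenotype))
  binary <- if (model == "auto") all(vals %in% c(0, 1)) else
    model == "logistic"
  X_cov <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  cond_mat <- NULL
  if (!is.null(condition_on)) {
    ix <- match(condition_on, rownames(G))
    if (anyNA(ix)) stop("unknown SNP id in condition_on", call. = FALSE)
    cond_mat <- t(G[ix, , drop = FALSE])
    colnames(cond_mat) <- paste0("cond_", condition_on)
  }

  snps <- rownames(G) %||% sprintf("snp%05d", seq_len(nrow(G)))
  fit_one <- function(i) {
    # conditioning dosages precede g so that perfect collinearity drops
    # the genotype term (flagged) rather than the conditioning term
    df <- data.frame(y = phenotype)
    if (!is.null(X_cov)) df <- cbind(df, X_cov)
    if (!is.null(cond_mat)) df <- cbind(df, as.data.frame(cond_mat))
    df$g <- G[i, ]
    df <- df[complete.cases(df), , drop = FALSE]
    n_used <- nrow(df)
    bad <- function() tibble(snp = snps[i], beta = NA_real_, se = NA_real_,
                             p = NA_real_, n = n_used,
                             direction = NA_character_, converged = FALSE)
    if (n_used < 3 || length(unique(df$g)) < 2) return(bad())
    fit <- tryCatch({
      if (binary) {
        suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      } else {
        lm(y ~ ., data = df)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) return(bad())
    cf <- summary(fit)$coefficients
    if (!("g" %in% rownames(cf)) || is.na(cf["g", 2])) return(bad())
    conv <- if (binary) isTRUE(fit$converged) && cf["g", 2] < 100 else TRUE
    if (!conv) return(bad())
    beta <- cf["g", 1]
    se <- cf["g", 2]
    tibble(snp = snps[i], beta = beta, se = se,
           p = 2 * pnorm(-abs(beta / se)), n = n_used,
           direction = if (beta >= 0) "+" else "-", converged = TRUE)
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(G)), fit_one))
  class(out) <- c("cohort_assoc", class(out))
  out
}

#' Enrichment of true associations among selected SNPs
#'
#' Storey-type estimate of the fraction of truly associated tests from
#' the departure of the p-value distribution from uniform:
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)` at `lambda = 0.5`, clipped
#' to `[0, 1]`; `pi1 = 1 - pi0`; the expected number of true
#' associations is `round(pi1 * m)`.
#'
#' @param p Vector of p-values in (0, 1].
#' @param lambda Tail cut-point (default 0.5).
#' @return An object of class `enrichment_report`: list with `m`, `pi1`
#'   and `expected_true`.
#' @examples
#' # the arithmetic behind "3.1% of 1,681 SNPs -> 52 expected true"
#' report <- enrichment_pi1(runif(100))
#' @export
enrichment_pi1 <- function(p, lambda = 0.5) {
  stopifnot(length(p) >= 1, all(p > 0 & p <= 1), lambda > 0, lambda < 1)
  m <- length(p)
  pi0 <- min(max(sum(p > lambda) / ((1 - lambda) * m), 0), 1)
  enrichment_report(1 - pi0, m)
}

#' @rdname enrichment_pi1
#' @param pi1 Estimated fraction of truly associated tests, in `[0, 1]`.
#' @param m Number of tests.
#' @export
enrichment_report <- function(pi1, m) {
  stopifnot(pi1 >= 0, pi1 <= 1, m >= 1)
  structure(
    list(m = as.integer(m), pi1 = pi1, expected_true = round(pi1 * m)),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report> pi1 = ", signif(x$pi1, 3), " of ", x$m,
      " SNPs; ", x$expected_true, " expected true associations\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.enrichment_report <- function(x, ...) {
  tibble(m = x$m, pi1 = x$pi1, expected_true = x$expected_true)
}
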