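#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))` from the
#' haplotype frequencies of a phased 0/1 panel.
#'
#' @param panel Haplotypes-by-sites matrix with entries 0/1 (two rows per
#'   diploid individual), or a data frame thereof.
#' @param site_a,site_b Column indices or names of the two sites.
#' @return The r-squared; `NA` with a warning if either site is
#'   monomorphic in the panel.
#' @export
ld_r2 <- function(panel, site_a, site_b) {
  panel <- as.matrix(panel)
  stopifnot(all(panel %in% c(0, 1)))
  a <- panel[, site_a]
  b <- panel[, site_b]
  p_a <- mean(a)
  p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warning("monomorphic site in LD panel; r^2 undefined")
    return(NA_real_)
  }
  p_ab <- mean(a * b)
  (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Default per-trait stage-3 selection thresholds
#'
#' `p < 1e-3` for type 2 diabetes, obesity, BMI, waist circumference,
#' fasting glucose and fasting insulin; `p < 1e-4` for all other traits.
#' Lipid traits (total cholesterol, HDL-cholesterol, triacylglycerol)
#' additionally use a 250 kb exclusion window around known associated
#' SNPs.
#'
#' @return A named numeric vector of thresholds.
#' @export
stage3_thresholds <- function() {
  c(type_2_diabetes = 1e-3, obesity = 1e-3, bmi = 1e-3,
    waist_circumference = 1e-3, fasting_glucose = 1e-3,
    fasting_insulin = 1e-3,
    hypertension = 1e-4, systolic_bp = 1e-4, diastolic_bp = 1e-4,
    total_cholesterol = 1e-4, hdl_cholesterol = 1e-4,
    triacylglycerol = 1e-4)
}

LIPID_TRAITS <- c("total_cholesterol", "hdl_cholesterol", "triacylglycerol")

#' Select SNPs for stage-3 replication
#'
#' Per trait, keeps associations below the trait's p-value threshold,
#' then drops any SNP in LD (`r^2 > 0.2`, estimated on a phased panel)
#' with a known genome-wide significant lead SNP for the same trait; for
#' lipid traits, additionally drops SNPs within `lipid_flank` (default
#' 250 kb) of a known associated SNP. A SNP absent from the panel skips
#' the LD check with a warning and is kept.
#'
#' @param results Data frame of per-(SNP, trait) associations with
#'   columns `snp`, `chrom`, `pos`, `trait`, `p`.
#' @param known_loci Data frame of known lead SNPs: `trait`, `snp`,
#'   `chrom`, `pos`. May be empty.
#' @param panel Optional phased haplotype matrix with columns named by
#'   SNP id, for the r-squared checks.
#' @param thresholds Named per-trait p thresholds
#'   (default [stage3_thresholds()]; unknown traits fall back to 1e-4).
#' @param r2_max LD exclusion threshold (default 0.2).
#' @param lipid_traits Traits using the window rule.
#' @param lipid_flank Window half-width in bp (default 250,000).
#' @return A list: `associations` (selected (SNP, trait) rows with a
#'   `reason` column for exclusions applied), `snps` (unique selected SNP
#'   ids).
#' @export
select_stage3 <- function(results, known_loci = NULL, panel = NULL,
                          thresholds = stage3_thresholds(), r2_max = 0.2,
                          lipid_traits = LIPID_TRAITS,
                          lipid_flank = 250000) {
  stopifnot(all(c("snp", "trait", "p") %in% names(results)))
  out <- as_tibble(results)
  thr <- thresholds[out$trait]
  thr[is.na(thr)] <- 1e-4  # "all other traits"
  out$threshold <- unname(thr)
  out$below_threshold <- !is.na(out$p) & out$p < out$threshold
  out$ld_excluded <- FALSE
  out$window_excluded <- FALSE

  if (!is.null(known_loci) && nrow(known_loci) > 0) {
    for (i in which(out$below_threshold)) {
      kl <- known_loci[known_loci$trait == out$trait[i], , drop = FALSE]
      if (nrow(kl) == 0) next
      if (!is.null(panel)) {
        if (!(out$snp[i] %in% colnames(panel))) {
          warning("SNP ", out$snp[i],
                  " absent from LD panel; LD check skipped")
        } else {
          for (lead in kl$snp) {
            if (!(lead %in% colnames(panel))) next
            r2 <- suppressWarnings(ld_r2(panel, out$snp[i], lead))
            if (!is.na(r2) && r2 > r2_max) {
              out$ld_excluded[i] <- TRUE
              break
            }
          }
        }
      }
      if (out$trait[i] %in% lipid_traits &&
          all(c("chrom", "pos") %in% names(out))) {
        hit <- kl$chrom == out$chrom[i] &
          abs(kl$pos - out$pos[i]) <= lipid_flank
        if (any(hit)) out$window_excluded[i] <- TRUE
      }
    }
  }
  out$selected <- out$below_threshold & !out$ld_excluded &
    !out$window_excluded
  list(
    associations = out,
    snps = unique(out$snp[out$selected])
  )
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Fixed-effects combination for quantitative traits: each cohort
#' contributes a signed z-score `z_i = qnorm(1 - p_i / 2) * sign_i`
#' relative to the shared reference allele, and the combined statistic is
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))` with two-sided p-value
#' `2 * (1 - pnorm(|Z|))`.
#'
#' @param df Data frame of per-cohort results with columns `p`,
#'   `direction` (`"+"`/`"-"` or signed numeric) and `n`, plus optional
#'   `snp` / `trait` grouping columns.
#' @return A tibble of class `meta_result` per (snp, trait) group:
#'   `z`, `p`, `n_total`, `n_cohorts`, `direction`.
#' @export
meta_samplesize <- function(df) {
  stopifnot(all(c("p", "direction", "n") %in% names(df)))
  sgn <- parse_direction(df$direction)
  p <- df$p
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  df <- as_tibble(df)
  # upper-tail form stays finite for p near the double-precision floor
  df$.z <- qnorm(p / 2, lower.tail = FALSE) * sgn
  group_cols <- intersect(c("snp", "trait"), names(df))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      z = sum(sqrt(.data$n) * .data$.z) / sqrt(sum(.data$n)),
      n_total = sum(.data$n),
      n_cohorts = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p = 2 * pnorm(-abs(.data$z)),
      direction = ifelse(.data$z >= 0, "+", "-")
    )
  class(out) <- c("meta_result", class(out))
  out
}

parse_direction <- function(d) {
  if (is.character(d)) {
    stopifnot(all(d %in% c("+", "-")))
    ifelse(d == "+", 1, -1)
  } else {
    s <- sign(d)
    ifelse(s == 0, 1, s)
  }
}

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Combination for binary traits reported as log-odds effects: the
#' pooled estimate weights each cohort by the inverse squared standard
#' error, `beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = sqrt(1 / sum(1 / se_i^2))`, with a Wald p-value and the odds
#' ratio `exp(beta)` with 95% CI `exp(beta +- 1.96 se)`. Cochran's Q
#' heterogeneity statistic is reported per group but never used for
#' exclusion.
#'
#' @param df Data frame of per-cohort results with columns `beta` and
#'   `se` (all `se > 0`), plus optional `snp` / `trait` grouping columns.
#' @return A tibble of class `meta_result` per group: `beta`, `se`, `p`,
#'   `or`, `or_lo`, `or_hi`, `n_cohorts`, `q`, `q_p`, `direction`.
#' @export
meta_inverse_variance <- function(df) {
  stopifnot(all(c("beta", "se") %in% names(df)), all(df$se > 0))
  df <- as_tibble(df)
  group_cols <- intersect(c("snp", "trait"), names(df))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      .w = list(1 / .data$se^2),
      .b = list(.data$beta),
      n_cohorts = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      beta = purrr::map2_dbl(.data$.b, .data$.w,
                             ~ sum(.x * .y) / sum(.y)),
      se = purrr::map_dbl(.data$.w, ~ sqrt(1 / sum(.x))),
      q = purrr::pmap_dbl(list(.data$.b, .data$.w, .data$beta),
                          function(b, w, bb) sum(w * (b - bb)^2)),
      q_p = pchisq(.data$q, df = pmax(.data$n_cohorts - 1, 1),
                   lower.tail = FALSE),
      p = 2 * pnorm(-abs(.data$beta / .data$se)),
      or = exp(.data$beta),
      or_lo = exp(.data$beta - 1.96 * .data$se),
      or_hi = exp(.data$beta + 1.96 * .data$se),
      direction = ifelse(.data$beta >= 0, "+", "-")
    ) |>
    dplyr::select(-".w", -".b")
  class(out) <- c("meta_result", class(out))
  out
}

#' Bonferroni significance threshold for SNPs x traits
#'
#' `alpha / (n_snps * n_traits)`, reported at full precision and rounded
#' to 2 significant figures. Conservative: SNP and trait correlations are
#' ignored.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_snps,n_traits Numbers of SNPs and traits tested.
#' @return A one-row tibble with `threshold` and `threshold_2sf`.
#' @examples
#' bonferroni_threshold(0.05, 70182, 12)  # 5.9e-8 at 2 s.f.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_snps, n_traits) {
  stopifnot(alpha > 0, n_snps > 0, n_traits > 0)
  thr <- alpha / (n_snps * n_traits)
  tibble(threshold = thr, threshold_2sf = signif(thr, 2))
}
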