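#' Cohort simulation configurations
#'
#' `pop_config()` describes the discovery-cohort design: a case-control
#' panel (default 1,000 cases and 1,000 controls) with diallelic sites at
#' minor-allele frequencies drawn uniformly from `maf_range` (default 1%
#' to 50%, matching the common-variant discovery floor), an optional
#' fraction of causal sites acting on a logistic liability with the given
#' per-site odds ratios, and a population disease prevalence used to
#' anchor the logistic intercept.
#'
#' @param n_cases,n_controls Case/control quota (defaults 1,000 / 1,000).
#' @param n_sites Number of diallelic sites (default 1,000).
#' @param maf_range Minor-allele frequency range, within (0, 0.5].
#' @param causal_fraction Fraction of sites flagged causal, in `[0, 1]`.
#' @param odds_ratios Per-causal-site allelic odds ratios (> 0), recycled
#'   to the number of causal sites.
#' @param disease_prevalence Population case probability, in (0, 1).
#' @param seed Integer seed; all randomness in the generators flows from
#'   the seeds carried in the configs.
#' @return A `pop_config` list.
#' @export
pop_config <- function(n_cases = 1000, n_controls = 1000, n_sites = 1000,
                       maf_range = c(0.01, 0.5), causal_fraction = 0,
                       odds_ratios = 1.1, disease_prevalence = 0.08,
                       seed = NULL) {
  stopifnot(
    n_cases >= 0, n_controls >= 0, n_sites >= 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    causal_fraction >= 0, causal_fraction <= 1,
    all(odds_ratios > 0),
    disease_prevalence > 0, disease_prevalence < 1
  )
  structure(
    list(n_cases = n_cases, n_controls = n_controls, n_sites = n_sites,
         maf_range = maf_range, causal_fraction = causal_fraction,
         odds_ratios = odds_ratios, disease_prevalence = disease_prevalence,
         seed = seed),
    class = "pop_config"
  )
}

#' @rdname pop_config
#' @param effect_sizes Additive effects per causal site, in trait-SD
#'   units on the latent scale; a named vector (names = site ids) or a
#'   vector recycled over the causal sites.
#' @param heritability_target Proportion of trait variance explained by
#'   the genetic values, in `[0, 1)`. Must be 0 only when all effects are 0.
#' @param noise Noise distribution for the environmental term
#'   (only "normal" is provided).
#' @export
trait_config <- function(effect_sizes = 0, heritability_target = 0.1,
                         noise = "normal") {
  stopifnot(heritability_target >= 0, heritability_target < 1)
  noise <- match.arg(noise, "normal")
  if (heritability_target == 0 && any(effect_sizes != 0)) {
    stop("heritability_target = 0 is inconsistent with nonzero effects",
         call. = FALSE)
  }
  structure(
    list(effect_sizes = effect_sizes,
         heritability_target = heritability_target, noise = noise),
    class = "trait_config"
  )
}

#' @rdname pop_config
#' @param mean_depth Mean filtered reads per site per individual
#'   (default 8, the post-quality-filter depth of a medium-pass exome
#'   design).
#' @param depth_law `"poisson"` (default) or `"fixed"` (exact
#'   `round(mean_depth * q_pass_rate)` reads everywhere, for exact oracle
#'   tests).
#' @param error_model An [error_model] for read substitution errors
#'   (default uniform 0.25% per error type).
#' @param q_pass_rate Fraction of raw bases surviving the quality filter,
#'   in (0, 1]. Default 1: `mean_depth` is interpreted as already
#'   post-filter.
#' @export
read_sim_config <- function(mean_depth = 8, depth_law = c("poisson", "fixed"),
                            error_model = uniform_error_model(0.0025),
                            q_pass_rate = 1) {
  depth_law <- match.arg(depth_law)
  stopifnot(mean_depth >= 0, q_pass_rate > 0, q_pass_rate <= 1,
            inherits(error_model, "error_model"))
  structure(
    list(mean_depth = mean_depth, depth_law = depth_law,
         error_model = error_model, q_pass_rate = q_pass_rate),
    class = "read_sim_config"
  )
}

#' Simulate cohort genotypes under Hardy-Weinberg equilibrium
#'
#' Draws per-site minor-allele frequencies uniformly from
#' `cfg$maf_range`, assigns major/minor alleles, and samples genotypes
#' (minor-allele dosage 0/1/2) i.i.d. from HWE proportions for
#' `n_cases + n_controls` individuals. A `causal_fraction` of sites is
#' flagged causal and carries the configured odds ratios. Deterministic
#' under a fixed `cfg$seed`.
#'
#' @param cfg A [pop_config].
#' @param miss_rate Fraction of genotype calls set missing (default 0;
#'   the sequencing data model represents absent data as depth-0 sites
#'   instead).
#' @return An object of class `cohort`: list with `genotypes` (sites x
#'   individuals integer matrix of minor-allele dosages, `NA` = missing),
#'   `sites` (tibble: `site`, `chrom`, `pos`, `major`, `minor`, `maf`,
#'   `causal`, `odds_ratio`) and `phenotypes` (tibble: `individual`,
#'   `sex` coded 0/1).
#' @export
simulate_genotypes <- function(cfg, miss_rate = 0) {
  stopifnot(inherits(cfg, "pop_config"), miss_rate >= 0, miss_rate < 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ns <- cfg$n_sites
  ni <- cfg$n_cases + cfg$n_controls

  maf <- runif(ns, cfg$maf_range[1], cfg$maf_range[2])
  chrom <- sort(sample(1:22, ns, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(ns), chrom), function(ix) {
    sort(sample.int(5e7, length(ix)))
  }), use.names = FALSE)
  major <- sample(ALLELES, ns, replace = TRUE)
  minor <- vapply(major, function(a) sample(setdiff(ALLELES, a), 1),
                  character(1))
  n_causal <- round(cfg$causal_fraction * ns)
  causal <- rep(FALSE, ns)
  if (n_causal > 0) causal[sample.int(ns, n_causal)] <- TRUE
  or <- rep(1, ns)
  or[causal] <- rep_len(cfg$odds_ratios, n_causal)

  G <- draw_hwe_genotypes(maf, ni)
  if (miss_rate > 0 && length(G) > 0) {
    G[runif(length(G)) < miss_rate] <- NA_integer_
  }
  sites <- tibble(
    site = sprintf("snp%05d", seq_len(ns)),
    chrom = chrom, pos = pos, major = unname(major), minor = unname(minor),
    maf = maf, causal = causal, odds_ratio = or
  )
  phenotypes <- tibble(
    individual = sprintf("ind%05d", seq_len(ni)),
    sex = rbinom(ni, 1, 0.5)
  )
  new_cohort(G, sites, phenotypes)
}

new_cohort <- function(G, sites, phenotypes) {
  rownames(G) <- sites$site
  colnames(G) <- phenotypes$individual
  structure(list(genotypes = G, sites = sites, phenotypes = phenotypes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$sites), " sites x ", nrow(x$phenotypes),
      " individuals\n", sep = "")
  cat("  phenotype columns:",
      paste(setdiff(names(x$phenotypes), "individual"), collapse = ", "),
      "\n")
  invisible(x)
}

# sites x n matrix of HWE genotypes at the given per-site frequencies.
draw_hwe_genotypes <- function(maf, n) {
  ns <- length(maf)
  G <- matrix(rbinom(ns * n, 2L, rep(maf, n)), nrow = ns, ncol = n)
  storage.mode(G) <- "integer"
  G
}

#' Ascertain a case-control cohort from a logistic disease model
#'
#' Case status follows `logit P(case) = alpha + sum_j log(OR_j) * g_j`
#' over the causal sites, with the intercept `alpha` solved so the
#' population case probability equals `cfg$disease_prevalence`. The
#' cohort is then ascertained by rejection sampling: population
#' individuals are drawn (genotypes from the site table's true
#' frequencies under HWE) and kept until exactly `n_cases` cases and
#' `n_controls` controls are collected. Ascertainment of an
#' extreme-design panel inflates observed case-control frequency
#' differences relative to the population odds ratios, which is the
#' study-design behaviour being emulated.
#'
#' @param cohort A `cohort` from [simulate_genotypes()] (used for its
#'   site table; its individuals are replaced by the ascertained panel).
#' @param cfg The same [pop_config].
#' @param batch_size Individuals drawn per rejection-sampling round.
#' @return A `cohort` whose `phenotypes` carry a binary `status` column
#'   (1 = case) and whose genotypes are the ascertained individuals'.
#' @export
simulate_case_control <- function(cohort, cfg, batch_size = 4000) {
  stopifnot(inherits(cohort, "cohort"), inherits(cfg, "pop_config"))
  sites <- cohort$sites
  beta <- log(sites$odds_ratio[sites$causal])
  maf_causal <- sites$maf[sites$causal]
  alpha <- solve_logit_intercept(beta, maf_causal, cfg$disease_prevalence)

  need_case <- cfg$n_cases
  need_ctrl <- cfg$n_controls
  kept_G <- vector("list", 0)
  kept_status <- integer(0)
  guard <- 0L
  while (need_case > 0 || need_ctrl > 0) {
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("infeasible configuration: case/control quotas not reachable",
           call. = FALSE)
    }
    G <- draw_hwe_genotypes(sites$maf, batch_size)
    eta <- alpha +
      if (length(beta) > 0) colSums(G[sites$causal, , drop = FALSE] * beta)
      else 0
    status <- rbinom(batch_size, 1L, stats::plogis(eta))
    take_case <- which(status == 1L)[seq_len(min(need_case, sum(status == 1L)))]
    take_ctrl <- which(status == 0L)[seq_len(min(need_ctrl, sum(status == 0L)))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take) > 0) {
      kept_G[[length(kept_G) + 1L]] <- G[, take, drop = FALSE]
      kept_status <- c(kept_status, status[take])
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
  }
  G <- do.call(cbind, kept_G)
  ni <- ncol(G)
  phenotypes <- tibble(
    individual = sprintf("ind%05d", seq_len(ni)),
    sex = rbinom(ni, 1, 0.5),
    status = kept_status
  )
  new_cohort(G, sites, phenotypes)
}

# Intercept of the logistic liability so that the population mean of
# plogis(alpha + sum beta_j g_j) equals the target prevalence. The
# genetic score distribution is evaluated by Monte Carlo over HWE
# genotypes at the causal sites (deterministic given the RNG stream).
solve_logit_intercept <- function(beta, maf, prevalence, n_mc = 20000) {
  if (length(beta) == 0 || all(beta == 0)) {
    return(stats::qlogis(prevalence))
  }
  S <- colSums(draw_hwe_genotypes(maf, n_mc) * beta)
  uniroot(function(a) mean(stats::plogis(a + S)) - prevalence,
          lower = -50, upper = 50, tol = 1e-10)$root
}

#' Simulate an additive quantitative trait
#'
#' `y = sum_j beta_j g_j + e`, with the environmental noise variance
#' scaled so the realised narrow-sense heritability (variance of the
#' genetic values over total variance) matches
#' `cfg$heritability_target`. With all effects zero the trait is pure
#' standard-normal noise.
#'
#' @param cohort A `cohort`.
#' @param cfg A [trait_config]. `effect_sizes` may be named by site id;
#'   unnamed values are recycled over the cohort's causal sites (or all
#'   sites if none are flagged causal).
#' @param name Column name for the trait (default `"trait"`).
#' @return The cohort with the trait added to `phenotypes`.
#' @export
simulate_quantitative_trait <- function(cohort, cfg, name = "trait") {
  stopifnot(inherits(cohort, "cohort"), inherits(cfg, "trait_config"))
  ni <- nrow(cohort$phenotypes)
  beta <- rep(0, nrow(cohort$sites))
  es <- cfg$effect_sizes
  if (!is.null(names(es)) && any(nzchar(names(es)))) {
    ix <- match(names(es), cohort$sites$site)
    if (anyNA(ix)) stop("unknown site id in effect_sizes", call. = FALSE)
    beta[ix] <- es
  } else if (any(es != 0)) {
    target <- if (any(cohort$sites$causal)) which(cohort$sites$causal)
              else seq_len(nrow(cohort$sites))
    beta[target] <- rep_len(es, length(target))
  }
  G <- cohort$genotypes
  G0 <- G
  G0[is.na(G0)] <- 0L
  gv <- if (any(beta != 0)) colSums(G0 * beta) else rep(0, ni)
  var_g <- var(gv)
  h2 <- cfg$heritability_target
  if (any(beta != 0) && var_g > 0 && h2 > 0) {
    sigma_e <- sqrt(var_g * (1 - h2) / h2)
  } else {
    sigma_e <- 1
  }
  y <- gv + rnorm(ni, 0, sigma_e)
  cohort$phenotypes[[name]] <- y
  cohort
}

#' Simulate error-prone low-depth read counts
#'
#' The data-generating counterpart of the genotype-likelihood model: for
#' every site x individual, the filtered depth is drawn from the depth
#' law at mean `mean_depth * q_pass_rate`; each read's true allele is the
#' minor allele with probability `g/2` (otherwise the major allele); and
#' the observed base is drawn from the error-model row of the true
#' allele. Missing genotypes yield depth 0.
#'
#' @param cohort A `cohort` with alleles in its site table.
#' @param cfg A [read_sim_config].
#' @return A [base_counts] object.
#' @export
simulate_reads <- function(cohort, cfg = read_sim_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(cfg, "read_sim_config"))
  G <- cohort$genotypes
  ns <- nrow(G)
  ni <- ncol(G)
  lambda <- cfg$mean_depth * cfg$q_pass_rate
  D <- if (cfg$depth_law == "poisson") {
    matrix(rpois(ns * ni, lambda), ns, ni)
  } else {
    matrix(round(lambda), ns, ni)
  }
  D[is.na(G)] <- 0L
  G0 <- G
  G0[is.na(G0)] <- 0L

  # split depth into true-minor and true-major reads
  t_minor <- matrix(rbinom(ns * ni, as.vector(D), as.vector(G0) / 2), ns, ni)
  t_major <- D - t_minor

  e <- unclass(cfg$error_model)
  counts <- lapply(ALLELES, function(a) matrix(0L, ns, ni))
  names(counts) <- ALLELES
  for (role in c("major", "minor")) {
    true_allele <- cohort$sites[[role]]
    n_true <- if (role == "major") t_major else t_minor
    probs <- e[true_allele, , drop = FALSE]  # sites x 4 observed-base probs
    remaining <- n_true
    cum <- rep(0, ns)
    for (bi in 1:3) {
      p_b <- probs[, bi]
      cond <- pmin(pmax(p_b / pmax(1 - cum, 1e-300), 0), 1)
      draw <- matrix(
        rbinom(ns * ni, as.vector(remaining), rep(cond, ni)), ns, ni)
      counts[[ALLELES[bi]]] <- counts[[ALLELES[bi]]] + draw
      remaining <- remaining - draw
      cum <- cum + p_b
    }
    counts$T <- counts$T + remaining
  }
  base_counts(counts, sites = cohort$sites[, c("chrom", "pos")],
              individuals = cohort$phenotypes$individual,
              q_threshold = 20)
}
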