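#' Pipeline run configuration
#'
#' One self-describing list holding every stage toggle, threshold and
#' seed for [run_pipeline()]. All thresholds default to the method's
#' canonical values; the configuration round-trips losslessly through
#' JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Single integer; every source of randomness in the run
#'   flows from it.
#' @param n_cases,n_controls,n_sites,maf_range,causal_fraction,odds_ratios,disease_prevalence
#'   Cohort design, see [pop_config()]. Defaults are demo-scale
#'   (200 + 200 individuals, 500 sites).
#' @param heritability,effect_size Quantitative-trait generator settings.
#' @param mean_depth,depth_law,error_rate,q_pass_rate Read simulator
#'   settings ([read_sim_config()]; `error_rate` is the uniform
#'   per-substitution-type rate).
#' @param putative_threshold,maf_min,mean_depth_min Discovery settings.
#' @param bias_flag_threshold Stage-1 bias-filter flag p-value.
#' @param stage2_p Stage-2 nominal selection threshold.
#' @param qc_maf_min,qc_call_rate_min,qc_hwe_min Stage-2 genotype QC.
#' @param alpha Family-wise error rate for the final threshold.
#' @param n_replication_cohorts,replication_n Stage-3 replication design
#'   (each cohort is half cases, half controls).
#' @param stages Named logical vector toggling pipeline stages.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       n_cases = 200, n_controls = 200, n_sites = 500,
                       maf_range = c(0.01, 0.5), causal_fraction = 0.02,
                       odds_ratios = 1.5, disease_prevalence = 0.08,
                       heritability = 0.05, effect_size = 0.2,
                       mean_depth = 8, depth_law = "poisson",
                       error_rate = 0.0025, q_pass_rate = 1,
                       putative_threshold = 0.0025,
                       maf_min = 0.01, mean_depth_min = 0.5,
                       bias_flag_threshold = 1e-4,
                       stage2_p = 0.05,
                       qc_maf_min = 0.005, qc_call_rate_min = 0.95,
                       qc_hwe_min = 1e-7,
                       alpha = 0.05,
                       n_replication_cohorts = 2, replication_n = 1000,
                       stages = c(simulate = TRUE, discover = TRUE,
                                  assoc_gl = TRUE, select_stage2 = TRUE,
                                  assoc_geno = TRUE, select_stage3 = TRUE,
                                  meta = TRUE)) {
  cfg <- list(
    seed = as.integer(seed),
    n_cases = n_cases, n_controls = n_controls, n_sites = n_sites,
    maf_range = maf_range, causal_fraction = causal_fraction,
    odds_ratios = odds_ratios, disease_prevalence = disease_prevalence,
    heritability = heritability, effect_size = effect_size,
    mean_depth = mean_depth, depth_law = depth_law,
    error_rate = error_rate, q_pass_rate = q_pass_rate,
    putative_threshold = putative_threshold,
    maf_min = maf_min, mean_depth_min = mean_depth_min,
    bias_flag_threshold = bias_flag_threshold,
    stage2_p = stage2_p,
    qc_maf_min = qc_maf_min, qc_call_rate_min = qc_call_rate_min,
    qc_hwe_min = qc_hwe_min,
    alpha = alpha,
    n_replication_cohorts = n_replication_cohorts,
    replication_n = replication_n,
    stages = as.list(stages)
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path File path for the JSON serialisation.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

#' Run the full multi-stage pipeline
#'
#' Executes, as toggled in the config: cohort + read simulation, SNP
#' discovery with error-model estimation, read-level case-control
#' association with bias filtering and genomic control, stage-2 SNP
#' selection, genotype-based association (rank-normalised quantitative
#' trait, PC1 + sex covariates) with enrichment analysis, stage-3
#' selection and fixed-effects meta-analysis against simulated
#' replication cohorts. Writes all stage outputs as TSV (plus a minimal
#' VCF of discovered sites) under `out_dir` together with a
#' machine-readable JSON run manifest (versions, seed, thresholds,
#' per-stage counts). A stage failure aborts with the stage name;
#' partial outputs are preserved.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    package = "exomassoc",
    package_version = as.character(packageVersion("exomassoc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    stages = list()
  )
  st <- function(name) isTRUE(cfg$stages[[name]])
  env <- new.env()

  if (st("simulate")) on_stage("simulate", {
    pcfg <- pop_config(
      n_cases = cfg$n_cases, n_controls = cfg$n_controls,
      n_sites = cfg$n_sites, maf_range = cfg$maf_range,
      causal_fraction = cfg$causal_fraction,
      odds_ratios = cfg$odds_ratios,
      disease_prevalence = cfg$disease_prevalence, seed = cfg$seed
    )
    cohort <- simulate_genotypes(pcfg)
    cohort <- simulate_case_control(cohort, pcfg)
    cohort <- simulate_quantitative_trait(
      cohort, trait_config(effect_sizes = cfg$effect_size,
                           heritability_target = cfg$heritability))
    rcfg <- read_sim_config(
      mean_depth = cfg$mean_depth, depth_law = cfg$depth_law,
      error_model = uniform_error_model(cfg$error_rate),
      q_pass_rate = cfg$q_pass_rate)
    bcm <- simulate_reads(cohort, rcfg)
    write_cohort_tsv(cohort, file.path(out_dir, "genotypes.tsv"),
                     file.path(out_dir, "phenotypes.tsv"))
    write_basecount_tsv(bcm, file.path(out_dir, "basecounts.tsv"))
    env$cohort <- cohort
    env$bcm <- bcm
    manifest$stages$simulate <- list(
      n_sites = nrow(cohort$sites),
      n_individuals = nrow(cohort$phenotypes),
      n_cases = sum(cohort$phenotypes$status == 1),
      n_controls = sum(cohort$phenotypes$status == 0)
    )
  })

  if (st("discover")) on_stage("discover", {
    disc <- discover_snps(env$bcm,
                          err0 = uniform_error_model(cfg$error_rate),
                          putative_threshold = cfg$putative_threshold)
    env$discovery <- disc
    write_results(dplyr::select(disc, -dplyr::any_of("components")),
                  file.path(out_dir, "discovery.tsv"))
    write_vcf(dplyr::filter(disc, .data$putative),
              file.path(out_dir, "discovered.vcf"))
    manifest$stages$discover <- list(
      n_sites = nrow(disc),
      n_putative = sum(disc$putative)
    )
  })

  if (st("assoc_gl")) on_stage("assoc_gl", {
    n_ind <- length(env$bcm$individuals)
    included <- site_inclusion_filter(env$discovery, n_ind,
                                      maf_min = cfg$maf_min,
                                      mean_depth_min = cfg$mean_depth_min)
    keep_ix <- match(paste(included$chrom, included$pos),
                     paste(env$bcm$sites$chrom, env$bcm$sites$pos))
    bcm_inc <- subset_base_counts(env$bcm, keep_ix)
    status <- env$cohort$phenotypes$status
    bias <- bias_filters(bcm_inc, status,
                         sites = included,
                         flag_threshold = cfg$bias_flag_threshold,
                         tests = c("depth", "missing"))
    pass_bias <- !bias$flag_any
    gl <- compute_gl(subset_base_counts(bcm_inc, which(pass_bias)),
                     included[pass_bias, ],
                     attr(env$discovery, "error_model"))
    assoc <- lrt_case_control(gl, status)
    gc <- genomic_control(assoc)
    env$assoc_gl <- gc$results
    env$lambda_gc <- gc$lambda_gc
    write_results(gc$results, file.path(out_dir, "assoc_gl.tsv"))
    manifest$stages$assoc_gl <- list(
      n_included = nrow(included),
      n_bias_flagged = sum(bias$flag_any),
      n_tested = nrow(gc$results),
      lambda_gc = gc$lambda_gc
    )
  })

  if (st("select_stage2")) on_stage("select_stage2", {
    res <- env$assoc_gl
    # demo annotation labels drawn with exome-like category weights
    set.seed(cfg$seed + 1L)
    res$annotation <- sample(
      c("nonsense", "non-synonymous", "splice", "UTR", "synonymous",
        "near-gene", "intron", "intergenic"),
      nrow(res), replace = TRUE,
      prob = c(0.003, 0.29, 0.004, 0.04, 0.29, 0.003, 0.364, 0.006))
    res$known_locus <- FALSE
    # criterion 1 applies to the GC-corrected p-values
    sel <- select_stage2(dplyr::mutate(res, p = .data$p_gc),
                         p_threshold = cfg$stage2_p)
    env$stage2 <- sel
    write_results(sel, file.path(out_dir, "stage2_selection.tsv"))
    counts <- stage2_reason_counts(sel)
    manifest$stages$select_stage2 <- list(
      n_selected = sum(sel$selected),
      reasons = as.list(setNames(counts$n, counts$reason))
    )
  })

  if (st("assoc_geno")) on_stage("assoc_geno", {
    sel <- dplyr::filter(env$stage2, .data$selected)
    keep <- match(paste(sel$chrom, sel$pos),
                  paste(env$cohort$sites$chrom, env$cohort$sites$pos))
    G <- env$cohort$genotypes[keep, , drop = FALSE]
    qc <- snp_qc(G, maf_min = cfg$qc_maf_min,
                 call_rate_min = cfg$qc_call_rate_min,
                 hwe_min = cfg$qc_hwe_min)
    G <- G[qc$pass, , drop = FALSE]
    pheno <- env$cohort$phenotypes
    pc1 <- pca_first_component(env$cohort$genotypes, seed = cfg$seed)
    covs <- data.frame(pc1 = pc1$pc1, sex = pheno$sex)
    res_bin <- assoc_additive(G, pheno$status, covariates = covs)
    res_bin$trait <- "type_2_diabetes"
    y <- rank_inverse_normal(pheno$trait)
    res_qt <- assoc_additive(G, y, covariates = covs)
    res_qt$trait <- "bmi"
    res <- dplyr::bind_rows(res_bin, res_qt)
    pos_tbl <- tibble(snp = rownames(G),
                      chrom = env$cohort$sites$chrom[match(
                        rownames(G), env$cohort$sites$site)],
                      pos = env$cohort$sites$pos[match(
                        rownames(G), env$cohort$sites$site)])
    res <- dplyr::left_join(res, pos_tbl, by = "snp")
    env$assoc_geno <- res
    env$qc <- qc
    # enrichment over the nominally associated (criterion 1) SNPs
    crit1 <- sel$crit_assoc[qc$pass]
    p_enrich <- res_bin$p[crit1]
    p_enrich <- p_enrich[!is.na(p_enrich)]
    enrich <- if (length(p_enrich) > 0) enrichment_pi1(p_enrich) else NULL
    write_results(res, file.path(out_dir, "assoc_geno.tsv"))
    write_results(qc, file.path(out_dir, "snp_qc.tsv"))
    manifest$stages$assoc_geno <- list(
      n_qc_pass = sum(qc$pass),
      n_tests = nrow(res),
      enrichment = if (is.null(enrich)) NULL else
        list(m = enrich$m, pi1 = enrich$pi1,
             expected_true = enrich$expected_true)
    )
  })

  if (st("select_stage3")) on_stage("select_stage3", {
    sel3 <- select_stage3(env$assoc_geno, known_loci = NULL)
    env$stage3 <- sel3
    write_results(sel3$associations,
                  file.path(out_dir, "stage3_selection.tsv"))
    manifest$stages$select_stage3 <- list(
      n_associations = sum(sel3$associations$selected),
      n_snps = length(sel3$snps)
    )
  })

  if (st("meta")) on_stage("meta", {
    snps <- env$stage3$snps
    disc_bin <- dplyr::filter(env$assoc_geno,
                              .data$trait == "type_2_diabetes",
                              .data$snp %in% snps, !is.na(.data$p))
    if (nrow(disc_bin) == 0) {
      manifest$stages$meta <- list(n_meta_snps = 0, n_significant = 0)
    } else {
      keep <- match(disc_bin$snp, env$cohort$sites$site)
      per_cohort <- list(dplyr::mutate(
        dplyr::select(disc_bin, "snp", "beta", "se"), cohort = "discovery"))
      set.seed(cfg$seed + 2L)
      for (k in seq_len(cfg$n_replication_cohorts)) {
        rep_cfg <- pop_config(
          n_cases = cfg$replication_n / 2,
          n_controls = cfg$replication_n / 2,
          n_sites = length(keep),
          maf_range = cfg$maf_range,
          disease_prevalence = cfg$disease_prevalence)
        rep_cohort <- new_cohort(
          draw_hwe_genotypes(env$cohort$sites$maf[keep], 0),
          env$cohort$sites[keep, ],
          tibble(individual = character(), sex = integer()))
        rep_cohort <- simulate_case_control(rep_cohort, rep_cfg)
        r <- assoc_additive(rep_cohort$genotypes,
                            rep_cohort$phenotypes$status)
        r$snp <- disc_bin$snp
        per_cohort[[k + 1]] <- dplyr::mutate(
          dplyr::select(r, "snp", "beta", "se"),
          cohort = paste0("replication", k))
      }
      all_cohorts <- dplyr::bind_rows(per_cohort)
      all_cohorts <- dplyr::filter(all_cohorts, !is.na(.data$beta))
      meta <- meta_inverse_variance(all_cohorts)
      thr <- bonferroni_threshold(cfg$alpha,
                                  n_snps = nrow(env$assoc_geno) / 2,
                                  n_traits = 2)$threshold
      meta$significant <- meta$p < thr
      env$meta <- meta
      write_results(meta, file.path(out_dir, "meta.tsv"))
      manifest$stages$meta <- list(
        n_meta_snps = nrow(meta),
        threshold = thr,
        n_significant = sum(meta$significant)
      )
    }
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Subset a base_counts object to the given site rows.
subset_base_counts <- function(bcm, rows) {
  base_counts(
    lapply(bcm$counts, function(m) m[rows, , drop = FALSE]),
    sites = bcm$sites[rows, , drop = FALSE],
    individuals = bcm$individuals,
    q_threshold = bcm$q_threshold
  )
}
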