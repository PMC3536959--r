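test_that("the read-level LRT honours its null identities", {
  sim <- make_test_cohort(n = 40, n_sites = 20, seed = 41)
  disc <- discover_snps(sim$bcm, estimate_errors = FALSE)
  gl <- compute_gl(sim$bcm, disc, uniform_error_model(0.0025))

  # duplicating the panel as cases and controls gives T = 0, p = 1
  gl_dup <- gl
  gl_dup$L0 <- cbind(gl$L0, gl$L0)
  gl_dup$L1 <- cbind(gl$L1, gl$L1)
  gl_dup$L2 <- cbind(gl$L2, gl$L2)
  gl_dup$individuals <- c(gl$individuals, paste0(gl$individuals, "_b"))
  res <- lrt_case_control(gl_dup, rep(c(1, 0), each = 40))
  expect_true(all(res$chisq < 1e-6))
  expect_true(all(res$p > 1 - 1e-6))

  # permuting group labels leaves T unchanged
  status <- rep(c(1, 0), 20)
  r1 <- lrt_case_control(gl, status)
  r2 <- lrt_case_control(gl, 1 - status)
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-8)

  # rescaling one individual's likelihood triple by a positive constant
  # leaves T invariant
  gl_scaled <- gl
  gl_scaled$L0[, 3] <- gl$L0[, 3] * 7.5
  gl_scaled$L1[, 3] <- gl$L1[, 3] * 7.5
  gl_scaled$L2[, 3] <- gl$L2[, 3] * 7.5
  r3 <- lrt_case_control(gl_scaled, status)
  expect_equal(r1$chisq, r3$chisq, tolerance = 1e-8)

  # non-identifiable (depth-0 everywhere) site: p = 1 and flagged
  gl0 <- gl
  gl0$L0[5, ] <- 1
  gl0$L1[5, ] <- 1
  gl0$L2[5, ] <- 1
  r4 <- lrt_case_control(gl0, status)
  expect_true(r4$non_identifiable[5])
  expect_equal(r4$p[5], 1)
})

test_that("LRT power grows with frequency difference and depth", {
  power_at <- function(f_case, depth) {
    cfg <- pop_config(n_cases = 60, n_controls = 60, n_sites = 40,
                      maf_range = c(0.15, 0.15), seed = 53)
    co <- simulate_genotypes(cfg)
    st <- rep(c(1, 0), each = 60)
    set.seed(54)
    co$genotypes[, st == 1] <- matrix(
      rbinom(40 * 60, 2, f_case), 40, 60)
    bcm <- simulate_reads(co, read_sim_config(mean_depth = depth))
    disc <- discover_snps(bcm, estimate_errors = FALSE)
    res <- lrt_case_control(compute_gl(bcm, disc, uniform_error_model(0.0025)),
                            st)
    mean(res$p < 0.05)
  }
  expect_gt(power_at(0.45, 8), power_at(0.25, 8))
  expect_gte(power_at(0.45, 12), power_at(0.45, 2))
})

test_that("bias filters catch a batch error-rate artefact and stay quiet on nulls", {
  n_half <- 350
  cfg <- pop_config(n_cases = n_half, n_controls = n_half, n_sites = 60,
                    maf_range = c(0.1, 0.3), seed = 61)
  co <- simulate_genotypes(cfg)
  batch <- rep(c("early", "late"), each = n_half)
  bcm_a <- simulate_reads(co, read_sim_config(
    mean_depth = 8, error_model = uniform_error_model(0.002)))
  set.seed(62)
  bcm_b <- simulate_reads(co, read_sim_config(
    mean_depth = 8, error_model = uniform_error_model(0.01)))
  first <- seq_len(n_half)
  biased <- base_counts(
    setNames(lapply(c("A", "C", "G", "T"), function(a) {
      cbind(bcm_a$counts[[a]][, first], bcm_b$counts[[a]][, -first])
    }), c("A", "C", "G", "T")),
    sites = bcm_a$sites, individuals = bcm_a$individuals)

  flags <- bias_filters(biased, status = rep(c(1, 0), n_half), batch = batch)
  expect_gte(mean(flags$flag_batch), 0.9)

  # unbiased data: flag rate no more than ~2x nominal, and equal depths
  # produce no depth flags
  null_flags <- bias_filters(bcm_a, status = rep(c(1, 0), n_half),
                             batch = batch)
  expect_lte(mean(null_flags$flag_any), 0.05)
  fixed <- simulate_reads(co, read_sim_config(mean_depth = 8,
                                              depth_law = "fixed"))
  depth_flags <- bias_filters(fixed, status = rep(c(1, 0), n_half),
                              tests = "depth")
  expect_false(any(depth_flags$flag_depth))

  expect_warning(
    bias_filters(bcm_a, status = rep(c(1, 0), n_half), tests = "batch"),
    "batch")
})

test_that("null LRT p-values are uniform across seeds", {
  failures <- 0
  for (seed in 1:3) {
    cfg <- pop_config(n_cases = 100, n_controls = 100, n_sites = 600,
                      maf_range = c(0.2, 0.2), seed = 400 + seed)
    co <- simulate_genotypes(cfg)
    bcm <- simulate_reads(co, read_sim_config(mean_depth = 8))
    disc <- discover_snps(bcm, estimate_errors = FALSE)
    res <- lrt_case_control(
      compute_gl(bcm, disc, uniform_error_model(0.0025)),
      rep(c(1, 0), 100))
    ks <- suppressWarnings(ks.test(res$p, "punif"))
    if (ks$p.value <= 0.001) failures <- failures + 1
  }
  expect_lte(failures, 1)
})

test_that("genomic control matches its definitional identities", {
  null_median <- qchisq(0.5, df = 1)
  res <- tibble::tibble(chisq = rep(null_median, 11),
                        p = pchisq(rep(null_median, 11), 1,
                                   lower.tail = FALSE))
  gc <- genomic_control(res)
  expect_equal(gc$lambda_gc, 1, tolerance = 1e-12)
  expect_equal(gc$results$p_gc, res$p)

  # doubling every statistic doubles lambda; correction is applied
  gc2 <- genomic_control(dplyr::mutate(res, chisq = chisq * 2))
  expect_equal(gc2$lambda_gc, 2, tolerance = 1e-12)
  expect_equal(gc2$results$chisq_gc, res$chisq)

  # deflation is never applied when lambda <= 1
  res_low <- tibble::tibble(chisq = rep(null_median / 2, 5), p = 0.5)
  gc3 <- genomic_control(res_low)
  expect_equal(gc3$results$chisq_gc, res_low$chisq)
})

test_that("stage-2 selection applies the three criteria as a tagged union", {
  res <- tibble::tibble(
    snp = paste0("s", 1:6),
    p = c(0.04, 0.9, 0.9, 0.04, 0.9, NA),
    annotation = c("intergenic", "non-synonymous", "synonymous",
                   "nonsense", "synonymous", "UTR"),
    known_locus = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  sel <- select_stage2(res)
  # nominal intergenic hit: criterion 1 only
  expect_true(sel$selected[1] && sel$crit_assoc[1] &&
                !sel$crit_annotation[1] && !sel$crit_known_synonymous[1])
  # coding annotation regardless of p
  expect_true(sel$selected[2] && sel$crit_annotation[2])
  # synonymous in a known locus at p = 0.9: criterion 3 only
  expect_true(sel$selected[3] && sel$crit_known_synonymous[3] &&
                !sel$crit_assoc[3])
  # both 1 and 2
  expect_true(sel$crit_assoc[4] && sel$crit_annotation[4])
  # synonymous outside known loci, p = 0.9: not selected
  expect_false(sel$selected[5])
  # missing p with coding annotation still selected via criterion 2
  expect_true(sel$selected[6])

  counts <- stage2_reason_counts(sel)
  expect_equal(counts$n[counts$reason == "total_selected"], 5)
})
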