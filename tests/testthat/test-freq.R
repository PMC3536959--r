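test_that("EM frequency estimates match closed forms", {
  # all individuals certainly homozygous major
  gls <- tibble::tibble(L0 = rep(1, 20), L1 = 0, L2 = 0)
  expect_lt(ml_maf(gls)$f, 1e-3)
  # one certain heterozygote
  expect_equal(ml_maf(tibble::tibble(L0 = 0, L1 = 1, L2 = 0))$f, 0.5,
               tolerance = 1e-6)
  # flat likelihoods: non-identifiable, estimate pinned at the start value
  flat <- tibble::tibble(L0 = rep(1, 5), L1 = 1, L2 = 1)
  fit <- ml_maf(flat, init = 0.21)
  expect_true(fit$non_identifiable)
  expect_equal(fit$f, 0.21)
})

test_that("EM optimum agrees with grid search on random small instances", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    f_true <- runif(1, 0.02, 0.6)
    g <- rbinom(n, 2, f_true)
    depth <- rpois(n, 6)
    err <- 0.01
    # simple two-allele read model likelihoods
    n_minor <- rbinom(n, depth, g / 2 * (1 - err) + (1 - g / 2) * err)
    L <- sapply(0:2, function(gg) {
      p <- gg / 2 * (1 - err) + (1 - gg / 2) * err
      p^n_minor * (1 - p)^(depth - n_minor)
    })
    L <- L / pmax(apply(L, 1, max), 1e-300)
    fit <- ml_maf(tibble::tibble(L0 = L[, 1], L1 = L[, 2], L2 = L[, 3]))
    f_grid <- oracle_grid_maf(L[, 1], L[, 2], L[, 3])
    expect_lt(abs(fit$f - f_grid), 1e-3)
  }
})

test_that("EM log-likelihood is non-decreasing along its iterations", {
  set.seed(5)
  sim <- make_test_cohort(n = 40, n_sites = 6, seed = 17)
  disc <- discover_snps(sim$bcm, estimate_errors = FALSE)
  gl <- compute_gl(sim$bcm, disc, uniform_error_model(0.0025))
  for (i in seq_len(nrow(disc))) {
    L0 <- gl$L0[i, , drop = FALSE]
    L1 <- gl$L1[i, , drop = FALSE]
    L2 <- gl$L2[i, , drop = FALSE]
    f <- 0.01
    ll_prev <- -Inf
    for (it in 1:50) {
      step <- exomassoc:::em_maf_mat(L0, L1, L2, f0 = f, max_iter = 1)
      ll <- exomassoc:::gl_loglik_at(L0, L1, L2, step$f)
      expect_gte(ll, ll_prev - 1e-9)
      ll_prev <- ll
      f <- step$f
    }
  }
})

test_that("frequency estimates are equivariant under allele relabelling", {
  counts <- tibble::tibble(nA = c(5, 3, 0, 4), nC = c(3, 5, 8, 4),
                           nG = 0, nT = 0)
  err <- uniform_error_model(0.005)
  gl_ac <- genotype_likelihoods(counts, "A", "C", err)
  gl_ca <- genotype_likelihoods(counts, "C", "A", err)
  f_ac <- ml_maf(gl_ac)$f
  f_ca <- ml_maf(gl_ca)$f
  expect_equal(f_ac, 1 - f_ca, tolerance = 1e-4)
})

test_that("minor-sum estimator resolves dominance, ties and recovery", {
  err <- uniform_error_model(0.0025)
  # reads support only A and C: the C component dominates and matches the
  # single-minor estimate
  counts <- tibble::tibble(nA = c(6, 8, 4, 7, 8), nC = c(2, 0, 4, 1, 0),
                           nG = 0, nT = 0)
  res <- ml_maf_minor_sum(counts, err = err)
  expect_equal(res$minor, "C")
  single <- ml_maf(genotype_likelihoods(counts, "A", "C", err))
  expect_equal(res$f_hat, single$f, tolerance = 1e-4)
  comp <- res$components[[1]]
  expect_lt(max(comp$loglik[comp$minor != "C"]),
            comp$loglik[comp$minor == "C"] - 5)

  # constructed symmetric support for C and G: tie, allele order wins
  counts_tie <- tibble::tibble(nA = c(6, 6), nC = c(2, 0), nG = c(0, 2),
                               nT = 0)
  res_tie <- ml_maf_minor_sum(counts_tie, err = err)
  expect_true(res_tie$tie)
  expect_equal(res_tie$minor, "C")
})

test_that("minor-sum frequency recovery is accurate at low frequency", {
  cfg <- pop_config(n_cases = 250, n_controls = 250, n_sites = 60,
                    maf_range = c(0.05, 0.05), seed = 23)
  co <- simulate_genotypes(cfg)
  bcm <- simulate_reads(co, read_sim_config(mean_depth = 8))
  disc <- discover_snps(bcm, estimate_errors = FALSE)
  err_mean <- mean(abs(disc$f_hat - 0.05))
  expect_lt(err_mean, 0.012)
})

test_that("discovery flags behave at the threshold extremes", {
  sim <- make_test_cohort(n = 60, n_sites = 30, seed = 31,
                          maf = c(0.2, 0.4))
  # monomorphic error-free site is not flagged
  co_mono <- simulate_genotypes(pop_config(n_cases = 30, n_controls = 30,
                                           n_sites = 5,
                                           maf_range = c(1e-12, 1e-12),
                                           seed = 32))
  bcm_mono <- simulate_reads(co_mono, read_sim_config(
    mean_depth = 8, error_model = uniform_error_model(0)))
  disc_mono <- discover_snps(bcm_mono, estimate_errors = FALSE)
  expect_false(any(disc_mono$putative))

  # threshold 0 flags every covered site
  disc_all <- discover_snps(sim$bcm, putative_threshold = 0,
                            estimate_errors = FALSE)
  covered <- disc_all$total_depth > 0
  expect_true(all(disc_all$putative[covered & !disc_all$non_identifiable]))
})

test_that("frequency RMSE shrinks with sequencing depth", {
  rmse <- vapply(c(2, 8, 30), function(d) {
    cfg <- pop_config(n_cases = 100, n_controls = 100, n_sites = 100,
                      maf_range = c(0.1, 0.3), seed = 77)
    co <- simulate_genotypes(cfg)
    bcm <- simulate_reads(co, read_sim_config(mean_depth = d))
    disc <- discover_snps(bcm, estimate_errors = FALSE)
    sqrt(mean((disc$f_hat - co$sites$maf)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("stage-1 inclusion thresholds are strict", {
  sites <- tibble::tibble(
    f_hat = c(0.009, 0.010, 0.011, 0.3, 0.3),
    total_depth = c(2000, 2000, 2000, 1000, 1001)
  )
  kept <- site_inclusion_filter(sites, n_individuals = 2000)
  # f = 0.009 and f = 0.010 excluded (strict >), depth exactly at the
  # 0.5x-per-individual bound excluded
  expect_equal(nrow(kept), 2)
  expect_equal(kept$f_hat, c(0.011, 0.3))
  expect_equal(kept$total_depth, c(2000, 1001))
})
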