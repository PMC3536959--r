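test_that("genotype simulation respects HWE structure and determinism", {
  cfg <- pop_config(n_cases = 5000, n_controls = 5000, n_sites = 3,
                    maf_range = c(0.5, 0.5), seed = 101)
  co <- simulate_genotypes(cfg)
  n <- ncol(co$genotypes)
  # sample MAF within 3 binomial SEs of 0.5; het fraction near 2f(1-f)
  se <- sqrt(0.5 * 0.5 / (2 * n))
  for (i in 1:3) {
    f_hat <- mean(co$genotypes[i, ]) / 2
    expect_lt(abs(f_hat - 0.5), 3 * se)
    expect_lt(abs(mean(co$genotypes[i, ] == 1) - 0.5), 0.03)
  }
  # same seed twice -> identical output
  co2 <- simulate_genotypes(cfg)
  expect_identical(co$genotypes, co2$genotypes)
  expect_identical(co$sites, co2$sites)
})

test_that("degenerate and empty configurations are handled", {
  cfg0 <- pop_config(n_cases = 5, n_controls = 5, n_sites = 0, seed = 1)
  co0 <- simulate_genotypes(cfg0)
  expect_equal(nrow(co0$sites), 0)
  expect_equal(dim(co0$genotypes), c(0L, 10L))
  # a (near-)zero-frequency site yields (almost) all reference genotypes
  cfg <- pop_config(n_cases = 50, n_controls = 50, n_sites = 5,
                    maf_range = c(1e-12, 1e-12), seed = 2)
  co <- simulate_genotypes(cfg)
  expect_true(all(co$genotypes == 0))
})

test_that("genotype frequencies pass a HWE goodness-of-fit sweep", {
  # chi-square GOF at n = 10,000 across 50 seeds; allow at most 2
  # nominal-level failures at p > 0.001
  failures <- 0
  for (seed in 1:50) {
    cfg <- pop_config(n_cases = 5000, n_controls = 5000, n_sites = 1,
                      maf_range = c(0.3, 0.3), seed = seed)
    g <- simulate_genotypes(cfg)$genotypes[1, ]
    obs <- tabulate(g + 1, 3)
    f <- mean(g) / 2
    expected <- 10000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
    stat <- sum((obs - expected)^2 / expected)
    if (pchisq(stat, df = 1, lower.tail = FALSE) <= 0.001) {
      failures <- failures + 1
    }
  }
  expect_lte(failures, 2)
})

test_that("case-control ascertainment follows the logistic disease model", {
  # one causal site at OR 2: case MAF should exceed control MAF in almost
  # all replicates
  wins <- 0
  n_rep <- 40
  for (seed in seq_len(n_rep)) {
    cfg <- pop_config(n_cases = 150, n_controls = 150, n_sites = 1,
                      maf_range = c(0.3, 0.3), causal_fraction = 1,
                      odds_ratios = 2, disease_prevalence = 0.1,
                      seed = 1000 + seed)
    co <- simulate_case_control(simulate_genotypes(cfg), cfg)
    st <- co$phenotypes$status
    expect_equal(sum(st == 1), 150)
    expect_equal(sum(st == 0), 150)
    f_case <- mean(co$genotypes[1, st == 1]) / 2
    f_ctrl <- mean(co$genotypes[1, st == 0]) / 2
    if (f_case > f_ctrl) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("null odds ratios give equal case/control frequencies on average", {
  cfg <- pop_config(n_cases = 2000, n_controls = 2000, n_sites = 20,
                    maf_range = c(0.2, 0.4), disease_prevalence = 0.5,
                    seed = 33)
  co <- simulate_case_control(simulate_genotypes(cfg), cfg)
  st <- co$phenotypes$status
  diff <- rowMeans(co$genotypes[, st == 1]) - rowMeans(co$genotypes[, st == 0])
  expect_lt(abs(mean(diff)), 0.02)
  # prevalence 0.5 with no effects -> logistic intercept 0
  expect_equal(exomassoc:::solve_logit_intercept(numeric(0), numeric(0), 0.5),
               0)
})

test_that("quantitative trait generator hits its heritability target", {
  cfg <- pop_config(n_cases = 2500, n_controls = 2500, n_sites = 1,
                    maf_range = c(0.3, 0.3), causal_fraction = 1, seed = 7)
  co <- simulate_genotypes(cfg)
  # single causal site, h2 = 0.1: OLS recovers the simulated effect
  beta <- 0.5
  co <- simulate_quantitative_trait(
    co, trait_config(effect_sizes = beta, heritability_target = 0.1))
  fit <- summary(lm(co$phenotypes$trait ~ co$genotypes[1, ]))$coefficients
  expect_lt(abs(fit[2, 1] - beta), 3 * fit[2, 2])
  h2 <- var(beta * co$genotypes[1, ]) / var(co$phenotypes$trait)
  expect_lt(abs(h2 - 0.1), 0.03)

  # all-zero effects: pure noise
  co0 <- simulate_quantitative_trait(
    co, trait_config(effect_sizes = 0, heritability_target = 0),
    name = "null_trait")
  expect_lt(abs(cor(co0$phenotypes$null_trait, co0$genotypes[1, ])), 0.05)

  # inconsistent contract rejected
  expect_error(trait_config(effect_sizes = 0.3, heritability_target = 0),
               "inconsistent")
})

test_that("read simulator reproduces the configured error process", {
  # zero error + homozygous major -> only major-allele reads
  cfg <- pop_config(n_cases = 20, n_controls = 20, n_sites = 10,
                    maf_range = c(1e-12, 1e-12), seed = 5)
  co <- simulate_genotypes(cfg)
  bcm <- simulate_reads(co, read_sim_config(mean_depth = 10,
                                            error_model = uniform_error_model(0)))
  for (i in seq_len(10)) {
    a <- co$sites$major[i]
    other <- setdiff(c("A", "C", "G", "T"), a)
    expect_true(all(vapply(other, function(b) sum(bcm$counts[[b]][i, ]),
                           numeric(1)) == 0))
  }

  # e(A -> C) = 0.01 at AA sites: pooled C fraction near 0.01
  rates <- matrix(0, 4, 4)
  rates[1, 2] <- 0.01
  co_a <- co
  co_a$sites$major <- "A"
  co_a$sites$minor <- "C"
  cfg_big <- pop_config(n_cases = 500, n_controls = 500, n_sites = 50,
                        maf_range = c(1e-12, 1e-12), seed = 6)
  co_big <- simulate_genotypes(cfg_big)
  co_big$sites$major <- "A"
  co_big$sites$minor <- "C"
  bcm_err <- simulate_reads(co_big, read_sim_config(
    mean_depth = 8, error_model = error_model(rates)))
  frac_c <- sum(bcm_err$counts$C) / sum(depth_matrix(bcm_err))
  expect_lt(abs(frac_c - 0.01), 0.002)

  # zero depth -> all-zero counts and flat likelihoods downstream
  bcm0 <- simulate_reads(co, read_sim_config(mean_depth = 0))
  expect_true(all(depth_matrix(bcm0) == 0))

  # fixed depth law is exact
  bcmf <- simulate_reads(co, read_sim_config(mean_depth = 6,
                                             depth_law = "fixed"))
  expect_true(all(depth_matrix(bcmf) == 6))
})

test_that("missing genotypes are only injected on request", {
  cfg <- pop_config(n_cases = 50, n_controls = 50, n_sites = 20, seed = 9)
  expect_false(anyNA(simulate_genotypes(cfg)$genotypes))
  co <- simulate_genotypes(cfg, miss_rate = 0.2)
  expect_gt(mean(is.na(co$genotypes)), 0.1)
  # missing genotypes become depth-0 cells in the read model
  bcm <- simulate_reads(co, read_sim_config(mean_depth = 8))
  expect_true(all(depth_matrix(bcm)[is.na(co$genotypes)] == 0))
})
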