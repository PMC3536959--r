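test_that("SNP QC applies the canonical thresholds strictly", {
  # constructed SNPs around each boundary; formals carry the defaults
  expect_equal(formals(snp_qc)$maf_min, 0.005)
  expect_equal(formals(snp_qc)$call_rate_min, 0.95)
  expect_equal(formals(snp_qc)$hwe_min, 1e-7)

  n <- 1000
  g_common <- rbinom(n, 2, 0.3)
  G <- rbind(
    low_maf = c(rep(1, 8), rep(0, n - 8)),          # MAF 0.004 -> fail
    ok = g_common,                                   # pass
    mono = rep(0, n),                                # monomorphic
    bad_hwe = c(rep(2, 300), rep(0, 700))            # no hets at all
  )
  rep_qc <- snp_qc(G)
  expect_false(rep_qc$pass[1])
  expect_match(rep_qc$reason[1], "maf")
  expect_true(rep_qc$pass[2])
  expect_true(rep_qc$monomorphic[3])
  expect_false(rep_qc$pass[3])
  expect_false(rep_qc$pass[4])
  expect_match(rep_qc$reason[4], "hwe")

  # 100 individuals with 96 calls: call rate 0.96, passes that filter
  g_cr <- c(rbinom(96, 2, 0.4), rep(NA, 4))
  rep_cr <- snp_qc(matrix(g_cr, nrow = 1))
  expect_equal(rep_cr$call_rate, 0.96)
  expect_true(rep_cr$pass)
  # all-missing SNP fails on call rate
  rep_na <- snp_qc(matrix(NA_integer_, 1, 50))
  expect_false(rep_na$pass)
  expect_match(rep_na$reason, "call_rate")
})

test_that("the exact HWE test agrees with enumeration and its symmetries", {
  # forced single heterozygote
  expect_equal(hwe_exact(0, 1, 0), 1)
  # zero minor alleles
  expect_equal(hwe_exact(30, 0, 0), 1)
  # extreme het deficit matches the enumeration oracle
  expect_equal(hwe_exact(50, 0, 50), oracle_hwe(50, 0, 50), tolerance = 1e-12)
  # swapping homozygote categories leaves p unchanged
  expect_equal(hwe_exact(40, 12, 3), hwe_exact(3, 12, 40), tolerance = 1e-12)
  # random instances up to n = 100
  set.seed(8)
  for (i in 1:40) {
    n <- sample(5:100, 1)
    f <- runif(1, 0.05, 0.5)
    g <- rbinom(n, 2, f)
    cnt <- tabulate(g + 1, 3)
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("rank-inverse-normal transform matches normal quantiles", {
  # n = 3 distinct values
  expect_equal(rank_inverse_normal(c(10, -5, 2)),
               qnorm(c(5 / 6, 1 / 6, 3 / 6)))
  # monotone in, monotone out; missing propagated
  x <- c(0.1, NA, 2, 30, NA, 5)
  z <- rank_inverse_normal(x)
  expect_true(all(is.na(z) == is.na(x)))
  xn <- x[!is.na(x)]
  zn <- z[!is.na(z)]
  expect_true(all(diff(zn[order(xn)]) >= 0))
  # ties get average ranks -> equal transformed values
  zt <- rank_inverse_normal(c(1, 1, 7))
  expect_equal(zt[1], zt[2])
  # mean ~0, variance ~1 at n = 1000
  set.seed(3)
  zz <- rank_inverse_normal(rexp(1000))
  expect_lt(abs(mean(zz)), 0.01)
  expect_lt(abs(var(zz) - 1), 0.05)
  # invariance of downstream regression under monotone transform
  g <- rbinom(1000, 2, 0.3)
  y <- g * 0.2 + rnorm(1000)
  expect_equal(rank_inverse_normal(y), rank_inverse_normal(exp(y)))
  # degenerate input rejected
  expect_error(rank_inverse_normal(rep(4, 10)), "constant")
  expect_error(rank_inverse_normal(c(1, NA)), "non-missing")
})

test_that("PC1 separates population blocks and matches power iteration", {
  set.seed(12)
  n_half <- 30
  f1 <- runif(80, 0.1, 0.5)
  f2 <- pmin(f1 + 0.3, 0.9)
  G <- cbind(
    matrix(rbinom(80 * n_half, 2, f1), 80, n_half),
    matrix(rbinom(80 * n_half, 2, f2), 80, n_half)
  )
  pc <- pca_first_component(G)
  expect_gt(abs(mean(pc$pc1[1:n_half]) - mean(pc$pc1[-(1:n_half)])), 0.05)

  # leading eigenvector equals the power-iteration oracle
  M <- G - rowMeans(G)
  C <- crossprod(M) / nrow(G)
  v <- oracle_power_iteration(C)
  expect_equal(abs(pc$pc1), abs(v), tolerance = 1e-8)
  # deterministic sign convention
  pc2 <- pca_first_component(G)
  expect_identical(pc$pc1, pc2$pc1)
  expect_gt(pc$pc1[which.max(abs(pc$pc1))], 0)
})

test_that("additive regression matches closed-form OLS and flags collinearity", {
  set.seed(19)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- 0.25 * g + rnorm(n)
  G <- matrix(g, 1, dimnames = list("rs1", NULL))
  res <- assoc_additive(G, y)
  # closed-form simple-regression slope and SE
  b <- cov(g, y) / var(g)
  resid <- y - mean(y) - b * (g - mean(g))
  se <- sqrt(sum(resid^2) / (n - 2) / sum((g - mean(g))^2))
  expect_equal(res$beta, b, tolerance = 1e-10)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$direction, "+")

  # conditioning a SNP on itself is non-identifiable
  res_cond <- assoc_additive(G, y, condition_on = "rs1")
  expect_false(res_cond$converged)
  expect_true(is.na(res_cond$p))

  # binary phenotype goes through logistic regression
  p_case <- plogis(-0.5 + 0.4 * g)
  st <- rbinom(n, 1, p_case)
  res_bin <- assoc_additive(G, st)
  fit <- glm(st ~ g, family = binomial())
  expect_equal(res_bin$beta, unname(coef(fit)["g"]), tolerance = 1e-8)

  # complete-case per SNP
  y_na <- y
  y_na[1:20] <- NA
  expect_equal(assoc_additive(G, y_na)$n, n - 20)
})

test_that("regression on a null simulation is calibrated", {
  set.seed(29)
  n <- 500
  n_snps <- 400
  G <- matrix(rbinom(n * n_snps, 2, 0.3), n_snps, n)
  y <- rnorm(n)
  covs <- data.frame(sex = rbinom(n, 1, 0.5))
  res <- assoc_additive(G, y, covariates = covs)
  alpha_hat <- mean(res$p < 0.05, na.rm = TRUE)
  ci_half <- 2.576 * sqrt(0.05 * 0.95 / n_snps)
  expect_lt(abs(alpha_hat - 0.05), ci_half + 0.01)
})

test_that("enrichment estimation reproduces its arithmetic and null", {
  # saturated signal
  sat <- enrichment_pi1(rep(1e-6, 25))
  expect_equal(sat$pi1, 1)
  expect_equal(sat$expected_true, 25)
  # uniform null: pi1 within 2 SE of zero
  set.seed(44)
  p <- runif(2000)
  rep_null <- enrichment_pi1(p)
  se <- sqrt(0.5 * 0.5 / 2000) / 0.5
  expect_lt(rep_null$pi1, 2 * se)
  # the bookkeeping identity: pi1 x m rounds to the expected count
  p_mix <- c(rep(1e-4, 52), runif(1629))
  rep_mix <- enrichment_pi1(p_mix)
  expect_equal(rep_mix$expected_true, round(rep_mix$pi1 * 1681))
  expect_error(enrichment_pi1(c(0.5, 0)), "p > 0")
})
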