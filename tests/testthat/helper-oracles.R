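# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: plain loops and closed forms only.

# Brute-force genotype likelihood: product over individual reads of
# (g/2) P(b|minor) + (1 - g/2) P(b|major), never in log space.
oracle_gl <- function(counts, major, minor, err) {
  alleles <- c("A", "C", "G", "T")
  e <- unclass(err)
  reads <- rep(alleles, times = counts[alleles])
  sapply(0:2, function(g) {
    prod(vapply(reads, function(b) {
      (g / 2) * e[minor, b] + (1 - g / 2) * e[major, b]
    }, numeric(1)))
  })
}

# Grid-search maximiser of the HWE mixture likelihood over f.
oracle_grid_maf <- function(L0, L1, L2, grid = seq(0, 1, by = 1e-4)) {
  ll <- vapply(grid, function(f) {
    sum(log(L0 * (1 - f)^2 + L1 * 2 * f * (1 - f) + L2 * f^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# Exact HWE test by full enumeration of heterozygote configurations,
# computed through multinomial log-probabilities under HWE given the
# observed allele frequency, conditioned on the allele counts.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  nb <- min(nb, 2 * n - nb)
  if (nb == 0) return(1)
  hets <- seq(nb %% 2, nb, by = 2)
  logp <- vapply(hets, function(h) {
    bb <- (nb - h) / 2
    aa <- n - h - bb
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == min(n_ab, nb))
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

# Power iteration for the leading eigenvector of a symmetric matrix.
oracle_power_iteration <- function(C, iter = 2000) {
  v <- rep(1, ncol(C)) / sqrt(ncol(C))
  for (i in seq_len(iter)) {
    v <- C %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- as.vector(v)
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

# Small fixed cohort with reads, reused by several tests.
make_test_cohort <- function(n = 60, n_sites = 40, seed = 11, maf = c(0.05, 0.5),
                             depth = 8, err = uniform_error_model(0.0025)) {
  cfg <- pop_config(n_cases = n / 2, n_controls = n / 2, n_sites = n_sites,
                    maf_range = maf, seed = seed)
  cohort <- simulate_genotypes(cfg)
  bcm <- simulate_reads(cohort, read_sim_config(mean_depth = depth,
                                                error_model = err))
  list(cohort = cohort, bcm = bcm, cfg = cfg)
}
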