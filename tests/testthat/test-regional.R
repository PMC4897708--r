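# aligned-table builder for arithmetic checks (no simulation)
aligned_table <- function(b, eta = 1, n = 1000) {
  m <- length(b)
  tab <- tibble::tibble(
    snp_id = sprintf("snp%03d", seq_len(m)), chrom = "1",
    pos = 1000 * seq_len(m), b = b, se = 1 / sqrt(n),
    n_eff = n, p = NA_real_, eta = rep(eta, length.out = m), flipped = FALSE
  )
  class(tab) <- c("largv_aligned", class(tab))
  tab
}

test_that("per-SNP variance follows b^2 / eta with duplication invariance", {
  expect_equal(per_snp_variance(0.1, 1), 0.01)
  expect_equal(per_snp_variance(0.1, 2), 0.005)
  # two perfect copies jointly contribute what a single SNP would
  expect_equal(sum(per_snp_variance(c(0.1, 0.1), c(2, 2))),
               per_snp_variance(0.1, 1))
  expect_error(per_snp_variance(0.1, 0.5), "eta")
})

test_that("regional estimate is the exact noise-centred sum", {
  # all-null b, 10 independent SNPs: the noise centring pulls the estimate
  # to -C/(1-C) with C = m/(N-1) — the df-rescaled analogue of -m/N
  est0 <- estimate_region(aligned_table(rep(0, 10), eta = 1, n = 1000))
  expect_equal(est0$estimate, -(10 / 999) / (1 - 10 / 999), tolerance = 1e-12)
  expect_equal(est0$estimate, -0.01, tolerance = 0.02)  # ~ -m_eff/N
  expect_equal(est0$m_eff, 10)

  est1 <- estimate_region(aligned_table(sqrt(0.02), eta = 1, n = 1000))
  expect_equal(est1$estimate, 0.02 - 0.98 / 998, tolerance = 1e-12)
  expect_equal(est1$estimate, 0.019, tolerance = 0.002)
  expect_equal(est1$raw_sum - est1$noise_term, est1$estimate)

  # no-LD reduction: sum(b^2) minus the residual-scaled df correction,
  # approximately sum(b^2) - m/N
  b <- c(0.05, -0.02, 0.03, 0.01)
  est2 <- estimate_region(aligned_table(b, eta = 1, n = 500))
  C <- 4 / 499
  expect_equal(est2$estimate,
               sum(b^2) - (1 - sum(b^2)) / (1 - C) * C, tolerance = 1e-14)
  expect_equal(est2$estimate, sum(b^2) - 4 / 500, tolerance = 0.02)

  # genome-wide form equals the Wherry rescaling with m_eff regressors
  raw <- est2$raw_sum
  expect_equal(est2$estimate, 1 - (1 - raw) * 499 / (499 - 4), tolerance = 1e-12)
})

test_that("regions missing from the summary table are excluded with a message", {
  tab <- aligned_table(rep(0.1, 5))
  expect_message(est <- estimate_region(tab, snps = c("snp001", "absent")),
                 "excluding 1")
  expect_equal(est$m_snps, 1)
})

test_that("estimates are additive over disjoint SNP sets", {
  set.seed(5)
  tab <- aligned_table(rnorm(20, 0, 0.05), eta = runif(20, 1, 3))
  whole <- estimate_region(tab)$estimate
  parts <- estimate_region(tab, snps = 1:7)$estimate +
    estimate_region(tab, snps = 8:20)$estimate
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("variance bound: null leading term, monotonicity, CI arithmetic", {
  expect_equal(variance_bound(100, 10000, 0),
               2e-6 / (1 - 100 / 9999)^2, tolerance = 1e-12)
  expect_equal(variance_bound(100, 10000, 0), 2e-6, tolerance = 0.03)
  expect_lt(variance_bound(50, 1000, 0.1), variance_bound(80, 1000, 0.1))
  est <- estimate_region(aligned_table(rep(0, 10), n = 1e7))
  # estimate ~ 0, bound ~ 2 m/N^2: CI = +/- 1.96 sqrt(bound)
  expect_equal(est$ci_high - est$ci_low,
               2 * 1.96 * sqrt(est$variance_bound), tolerance = 1e-12)
})

test_that("the bound dominates the empirical null variance", {
  panel <- simulate_genotypes(2000, 100, ld_independent(), seed = 61)
  std <- standardize_genotypes(panel)
  eta <- ld_eta(ld_windowed_r2(std, window = 100))
  ests <- withr::with_seed(62, replicate(1200, {
    y <- simulate_trait(std, h2 = 0)$y
    estimate_region(harmonize(gwas(std, y), eta))$estimate
  }))
  bound <- estimate_region(harmonize(gwas(std, simulate_trait(std, 0, seed = 63)$y),
                                     eta))$variance_bound
  expect_lte(var(ests), bound)
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("analytic 95% CIs cover zero for at least 93% of null replicates", {
  panel <- simulate_genotypes(1000, 50, ld_independent(), seed = 77)
  std <- standardize_genotypes(panel)
  eta <- ld_eta(ld_windowed_r2(std, window = 50))
  withr::with_seed(99, {
    cover <- replicate(1000, {
      y <- simulate_trait(std, h2 = 0)$y
      est <- estimate_region(harmonize(gwas(std, y), eta))
      est$ci_low <= 0 && 0 <= est$ci_high
    })
  })
  expect_gte(mean(cover), 0.93)
})

test_that("jackknife CI width per block shrinks as 1 / sqrt(#blocks)", {
  width_for <- function(n_blocks, seed) {
    m <- 5 * n_blocks
    panel <- simulate_genotypes(800, m, ld_independent(), seed = seed)
    std <- standardize_genotypes(panel)
    ld <- ld_windowed_r2(std, window = 5)
    blocks <- partition_blocks(ld, 5, 5)
    al <- harmonize(gwas(std, simulate_trait(std, h2 = 0, seed = seed)$y),
                    ld_eta(ld))
    est <- estimate_region(al, ci = "jackknife", blocks = blocks)
    (est$ci_high - est$ci_low) / n_blocks
  }
  w40 <- width_for(40, 301)
  w160 <- width_for(160, 302)
  expect_equal(w160 / w40, sqrt(40 / 160), tolerance = 0.5)

  # too few blocks for a jackknife errors with advice
  panel <- simulate_genotypes(200, 20, ld_independent(), seed = 3)
  std <- standardize_genotypes(panel)
  ld <- ld_windowed_r2(std, 5)
  al <- harmonize(gwas(std, simulate_trait(std, 0, seed = 1)$y), ld_eta(ld))
  expect_error(estimate_region(al, ci = "jackknife",
                               blocks = partition_blocks(ld, 5, 5)),
               "analytic")
})

test_that("a planted causal block ranks first and cumulative sums telescope", {
  panel <- simulate_genotypes(5000, 200, ld_blockwise(20, 0.6), seed = 88)
  std <- standardize_genotypes(panel)
  ld <- ld_windowed_r2(std, window = 40)
  eta <- ld_eta(ld)
  blocks <- partition_blocks(ld, 18, 22)
  causal <- 81:100  # one LD block
  top_hits <- 0
  for (rep in 1:20) {
    trait <- simulate_trait(std, h2 = 0.05, causal_snps = causal,
                            seed = 500 + rep)
    al <- harmonize(gwas(std, trait), eta)
    rk <- rank_blocks(al, blocks)
    top_block <- rk$table$block_id[1]
    rng <- blocks$blocks[blocks$blocks$block_id == top_block, ]
    if (rng$start_index <= 100 && rng$end_index >= 81) top_hits <- top_hits + 1
    # additivity: cumulative estimate at 100% equals the genome-wide sum
    expect_equal(rk$table$cum_estimate[nrow(rk$table)],
                 estimate_region(al)$estimate, tolerance = 1e-10)
  }
  expect_gte(top_hits / 20, 0.95)
})

test_that("duplicating every SNP leaves the estimate nearly unchanged", {
  panel <- simulate_genotypes(5000, 150, ld_ar1(0.6), seed = 202)
  std <- standardize_genotypes(panel)
  trait <- simulate_trait(std, h2 = 0.2, seed = 203)
  eta <- ld_eta(ld_windowed_r2(std, window = 100))
  est1 <- estimate_region(harmonize(gwas(std, trait), eta))

  G2 <- panel$genotypes[, rep(1:150, each = 2)]
  dup <- make_panel(G2)
  std2 <- standardize_genotypes(dup)
  eta2 <- ld_eta(ld_windowed_r2(std2, window = 200))
  al2 <- harmonize(gwas(std2, trait$y), eta2)
  est2 <- estimate_region(al2)
  expect_lt(abs(est2$estimate - est1$estimate) / est1$estimate, 0.01)

  # without the eta adjustment the duplicated estimate roughly doubles
  naive1 <- estimate_region(harmonize(gwas(std, trait$y), eta),
                            ld_adjust = FALSE)$estimate
  naive2 <- estimate_region(al2, ld_adjust = FALSE)$estimate
  expect_gt(naive2 / naive1, 1.8)
})
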