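test_that("PLINK bed round-trips exactly, including missing calls", {
  set.seed(5)
  G <- matrix(sample(c(0:2, NA), 23 * 7, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 23, 7)
  G[, 4][is.na(G[, 4])] <- 1  # keep every SNP polymorphic-ish
  panel <- make_panel(G)
  prefix <- file.path(withr::local_tempdir(), "fix")
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_identical(back$genotypes, panel$genotypes)
  expect_equal(back$snp_meta$id, panel$snp_meta$id)
  expect_equal(back$snp_meta$pos, panel$snp_meta$pos)
  expect_equal(back$individual_ids, panel$individual_ids)
})

test_that("bed parsing validates magic bytes, length, and duplicate IIDs", {
  dir <- withr::local_tempdir()
  panel <- make_panel(matrix(sample(0:2, 12, replace = TRUE), 4, 3))
  prefix <- file.path(dir, "ok")
  write_plink(panel, prefix)

  bad <- file.path(dir, "bad")
  file.copy(paste0(prefix, c(".bim", ".fam")), paste0(bad, c(".bim", ".fam")))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xff)), paste0(bad, ".bed"))
  expect_error(read_plink(bad), "magic")

  trunc <- file.path(dir, "trunc")
  file.copy(paste0(prefix, c(".bim", ".fam")), paste0(trunc, c(".bim", ".fam")))
  raw <- readBin(paste0(prefix, ".bed"), "raw", 1e4)
  writeBin(raw[-length(raw)], paste0(trunc, ".bed"))
  expect_error(read_plink(trunc), "truncated")

  dupfam <- readLines(paste0(prefix, ".fam"))
  dupfam[2] <- dupfam[1]
  writeLines(dupfam, paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "duplicate IID")
})

test_that("a hand-written fixture reads identically from PLINK and VCF", {
  skip_if_not_installed("vcfR")
  G <- cbind(c(0, 1, 2), c(2, NA, 0))
  panel <- make_panel(G)
  dir <- withr::local_tempdir()
  write_plink(panel, file.path(dir, "x"))
  write_vcf(panel, file.path(dir, "x.vcf"))
  from_bed <- read_plink(file.path(dir, "x"))
  from_vcf <- read_vcf(file.path(dir, "x.vcf"))
  expect_identical(from_bed$genotypes, from_vcf$genotypes)
  expect_equal(from_bed$snp_meta$maf, from_vcf$snp_meta$maf)
  expect_equal(from_vcf$individual_ids, panel$individual_ids)
})

test_that("the Hardy-Weinberg exact test matches direct enumeration", {
  # independent oracle: enumerate the conditional distribution of het counts
  hwe_enum <- function(het, hom_alt, hom_ref) {
    n <- het + hom_alt + hom_ref
    nr <- 2 * min(hom_alt, hom_ref) + het
    hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
    logp <- vapply(hets, function(h) {
      ra <- (nr - h) / 2; ca <- n - h - ra
      lfactorial(n) - lfactorial(ra) - lfactorial(h) - lfactorial(ca) +
        h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n)
    }, numeric(1))
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(het, hets)] * (1 + 1e-9)])
  }
  cases <- list(c(0, 50, 50), c(10, 5, 85), c(57, 14, 50), c(1, 0, 1),
                c(12, 33, 55), c(100, 0, 0))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_enum(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  # (50, 0, 50): total heterozygote deficit is astronomically unlikely
  expect_lt(hwe_exact_test(0, 50, 50), 1e-6)
})

test_that("QC filters apply in order and report removals", {
  set.seed(9)
  n <- 200; m <- 60
  # HWE-consistent background so only the planted SNPs fail
  G <- sapply(runif(m, 0.2, 0.4), function(p) stats::rbinom(n, 2, p))
  G[1:20, 2] <- NA                       # 10% SNP missingness (1.7% per individual)
  G[, 3] <- c(rep(1, 2), rep(0, n - 2))  # maf 0.005
  G[, 4] <- c(rep(2, 100), rep(0, 100))  # total heterozygote deficit
  G[1, 5:34] <- NA                       # individual 1 half missing
  panel <- make_panel(G)
  res <- apply_qc(panel, qc_config())
  rep_ <- res$report
  expect_equal(rep_$removed[rep_$criterion == "individual_missingness"], 1)
  expect_equal(rep_$removed[rep_$criterion == "snp_missingness"], 1)
  expect_equal(rep_$removed[rep_$criterion == "maf"], 1)
  expect_equal(rep_$removed[rep_$criterion == "hwe"], 1)
  expect_equal(ncol(res$panel$genotypes), m - 3)
  expect_equal(nrow(res$panel$genotypes), n - 1)

  # clean panel passes through unchanged
  clean <- make_panel(sapply(runif(10, 0.2, 0.4),
                             function(p) stats::rbinom(50, 2, p)))
  res2 <- apply_qc(clean, qc_config())
  expect_identical(res2$panel$genotypes, clean$genotypes)
  expect_true(all(res2$report$removed == 0))
})

test_that("eta, block and estimate tables round-trip losslessly", {
  panel <- simulate_genotypes(120, 40, ld_ar1(0.7), seed = 15)
  ld <- ld_windowed_r2(panel, window = 10)
  eta <- ld_eta(ld)
  blocks <- partition_blocks(ld, 8, 12)
  dir <- withr::local_tempdir()

  write_eta(eta, file.path(dir, "eta.tsv"))
  eta2 <- read_eta(file.path(dir, "eta.tsv"))
  expect_equal(eta2$eta, eta$eta, tolerance = 1e-12)
  expect_equal(eta2$snp_id, eta$snp_id)

  write_blocks(blocks, file.path(dir, "blocks.tsv"))
  blocks2 <- read_blocks(file.path(dir, "blocks.tsv"))
  expect_equal(blocks2$blocks$start_bp, blocks$blocks$start_bp)
  expect_equal(blocks2$blocks$boundary_max_r2, blocks$blocks$boundary_max_r2,
               tolerance = 1e-12)
  expect_equal(blocks2$snp_map, blocks$snp_map, ignore_attr = TRUE)

  al <- harmonize(gwas(panel, simulate_trait(panel, 0.2, seed = 16)), eta)
  rk <- rank_blocks(al, blocks)
  write_estimates(rk, file.path(dir, "est.tsv"))
  est2 <- readr::read_tsv(file.path(dir, "est.tsv"), show_col_types = FALSE)
  expect_equal(est2$estimate, rk$table$estimate, tolerance = 1e-12)
})

test_that("summary statistics read back through the column mapping", {
  dir <- withr::local_tempdir()
  tab <- data.frame(SNP = c("a", "b"), CHR = "1", POS = c(100, 200),
                    A1 = "G", A2 = "A", BETA = c(0.1, -0.2),
                    SE = c(0.01, 0.02), N = 500, P = c(0.1, 0.9))
  readr::write_tsv(tab, file.path(dir, "ss.tsv"))
  ss <- read_sumstats(file.path(dir, "ss.tsv"))
  expect_equal(ss$snp_id, c("a", "b"))
  expect_equal(ss$b, c(0.1, -0.2))
  expect_equal(ss$n_eff, c(500, 500))
  # missing required columns error
  readr::write_tsv(tab[, c("SNP", "BETA")], file.path(dir, "bad.tsv"))
  expect_error(read_sumstats(file.path(dir, "bad.tsv")), "SE")
})
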