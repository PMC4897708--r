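#' Quality-control configuration
#'
#' Default thresholds: SNP and individual missingness at most 2%, minor
#' allele frequency at least 0.02, Hardy-Weinberg exact-test p at least
#' 1e-6.
#'
#' @param max_missing_snp,max_missing_ind maximum missingness fractions.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(max_missing_snp = 0.02, max_missing_ind = 0.02,
                      min_maf = 0.02, hwe_p_min = 1e-6) {
  vals <- c(max_missing_snp, max_missing_ind, min_maf)
  stopifnot(all(vals >= 0 & vals <= 1), hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(max_missing_snp = max_missing_snp,
                 max_missing_ind = max_missing_ind,
                 min_maf = min_maf, hwe_p_min = hwe_p_min),
            class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg equilibrium given the observed
#' genotype counts: p is the summed probability of all heterozygote counts
#' (conditional on allele counts) whose probability does not exceed the
#' observed one. Probabilities follow the standard recurrence over
#' heterozygote counts.
#'
#' @param n_het,n_hom_alt,n_hom_ref genotype counts.
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_alt, n_hom_ref) {
  stopifnot(n_het >= 0, n_hom_alt >= 0, n_hom_ref >= 0)
  n <- n_het + n_hom_alt + n_hom_ref
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom_alt, n_hom_ref) + n_het  # rare allele count
  # heterozygote counts share the parity of the rare allele count
  hets <- seq.int(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized probs by recurrence from the smallest het count
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    # P(h) / P(h-2) = 4 * (rare_hom + 1) * (common_hom + 1) / (h * (h - 1))
    lp[i] <- lp[i - 1] +
      log(4 * (rare_hom + 1) * (common_hom + 1)) - log(h) - log(h - 1)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  if (is.na(obs)) abort("inconsistent genotype counts")
  sum(pr[pr <= pr[obs] * (1 + 1e-9)])
}

#' Apply quality-control filters to a panel
#'
#' Filters in a fixed order: (1) individual missingness, (2) SNP
#' missingness, (3) minor allele frequency, (4) Hardy-Weinberg exact test.
#' MAF and HWE are computed after the missingness filters.
#'
#' @param panel a [largv_panel()].
#' @param qc a [qc_config()].
#' @return list with the filtered `panel` and a `report` tibble
#'   (`criterion`, `removed`, `unit`).
#' @export
apply_qc <- function(panel, qc = qc_config()) {
  stopifnot(inherits(panel, "largv_panel"), inherits(qc, "qc_config"))
  G <- panel$genotypes
  meta <- panel$snp_meta
  ids <- panel$individual_ids

  ind_miss <- rowMeans(is.na(G))
  drop_ind <- ind_miss > qc$max_missing_ind
  G <- G[!drop_ind, , drop = FALSE]
  ids <- ids[!drop_ind]

  snp_miss <- colMeans(is.na(G))
  drop_miss <- snp_miss > qc$max_missing_snp

  freq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  drop_maf <- !drop_miss & maf < qc$min_maf

  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[!is.na(G[, j]), j]
    hwe_exact_test(sum(g == 1), sum(g == 2), sum(g == 0))
  }, numeric(1))
  drop_hwe <- !drop_miss & !drop_maf & hwe_p < qc$hwe_p_min

  keep <- !(drop_miss | drop_maf | drop_hwe)
  if (!any(keep)) abort("all SNPs removed by QC")
  out <- largv_panel(G[, keep, drop = FALSE], meta[keep, ], ids)
  report <- tibble(
    criterion = c("individual_missingness", "snp_missingness", "maf", "hwe"),
    removed = c(sum(drop_ind), sum(drop_miss), sum(drop_maf), sum(drop_hwe)),
    unit = c("individuals", "snps", "snps", "snps")
  )
  list(panel = out, report = report)
}
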