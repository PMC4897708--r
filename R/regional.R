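#' Variance explained by a single SNP
#'
#' The LD-adjusted per-SNP contribution `b^2 / eta`, where `b` is the
#' standardized-scale univariate GWAS coefficient and `eta` the SNP's LD
#' adjustment. Under linkage equilibrium (`eta = 1`) this is the usual
#' squared standardized effect; under LD the deflation removes the
#' double-counting of shared signal, so e.g. a perfectly duplicated causal
#' SNP pair (each `eta = 2`) contributes jointly what a single copy would.
#'
#' @param b standardized univariate regression coefficient(s).
#' @param eta LD adjustment(s), `>= 1`.
#' @return `b^2 / eta`, vectorized.
#' @export
per_snp_variance <- function(b, eta) {
  if (any(eta < 1 - 1e-8)) abort("eta must be >= 1")
  b^2 / eta
}

#' Upper bound on the sampling variance of a regional estimate
#'
#' `(2 m_eff / N^2 + 4 max(estimate, 0) / N) / (1 - m_eff / (N - 1))^2`.
#' The first term bounds the null variance of the LD-adjusted sum (it is
#' near-exact for Gaussian nulls in linkage equilibrium and conservative
#' under LD); the second covers the signal-noise cross term; the final
#' factor propagates the degrees-of-freedom rescaling of the noise
#' centring. All terms are small relative to the expectation for regions
#' carrying real signal.
#'
#' @param m_eff effective marker count of the region.
#' @param n sample size (must exceed `m_eff + 1`).
#' @param estimate the regional estimate (truncated at 0 in the bound).
#' @return Scalar variance upper bound.
#' @export
variance_bound <- function(m_eff, n, estimate = 0) {
  stopifnot(n > 1, m_eff > 0, all(m_eff < n - 1))
  (2 * m_eff / n^2 + 4 * pmax(estimate, 0) / n) / (1 - m_eff / (n - 1))^2
}

#' Regional variance explained from summary statistics
#'
#' Computes the LD-adjusted regional sum `sum(b^2 / eta)` over a SNP set and
#' subtracts a per-SNP noise term `sigma2_e / (eta * (N - 1))` that centres
#' the estimate at zero under the null — the summary-statistic analogue of
#' the adjusted R-squared being null-centred. `sigma2_e` is the trait's
#' residual (non-genetic) variance, estimated once from the whole table as
#' `(1 - raw) / (1 - C)` with `C = sum(1 / (eta * (N - 1)))`; under the null
#' `E[b^2] = 1/(N - 1)` exactly, so the null expectation is exactly zero,
#' and for the genome-wide sum the estimate equals the degrees-of-freedom
#' rescaling `1 - (1 - raw) (N - 1) / (N - 1 - m_eff)` — the expected
#' adjusted R-squared with the SNP count replaced by the effective marker
#' count. Because `sigma2_e` is shared, estimates are exactly additive over
#' disjoint SNP sets of the same table.
#'
#' @param aligned a [harmonize()] table (or any tibble with `b`, `eta`,
#'   `n_eff`, `snp_id` columns). Should cover the whole genome (or all
#'   available SNPs): the residual-variance scale of the noise term is
#'   estimated from the full table, while the sum runs over `snps`.
#' @param snps SNP selection: character ids, integer indices, or logical
#'   mask; `NULL` for all SNPs. Selected SNPs absent from `aligned` are
#'   excluded with a message (only SNPs with summary statistics enter the
#'   sum).
#' @param n optional scalar sample size overriding the per-SNP `n_eff`.
#' @param region_id label for the output.
#' @param sigma2_e residual trait variance used to scale the noise term;
#'   default `NULL` estimates it from the full table as above. Supply 1 for
#'   the flat `m_eff / N`-style correction.
#' @param ld_adjust set `FALSE` to ignore eta (naive `sum(b^2)` estimator;
#'   for comparison only — it overestimates under LD).
#' @param noise_correct set `FALSE` for the uncorrected raw sum (biased
#'   upward by `m_eff / N` under the null).
#' @param ci `"analytic"` (default; `estimate +/- 1.96 sqrt(variance_bound)`),
#'   `"jackknife"` (delete-one-block; needs `blocks`), or `"none"`.
#' @param blocks a [partition_blocks()] result, required for the jackknife.
#' @return Object of class `regional_estimate` with fields `region_id`,
#'   `m_snps`, `m_eff`, `raw_sum`, `noise_term`, `estimate`,
#'   `variance_bound`, `ci_low`, `ci_high`, `n_used`, `sigma2_e`,
#'   `ci_method`.
#' @export
estimate_region <- function(aligned, snps = NULL, n = NULL,
                            region_id = "region", sigma2_e = NULL,
                            ld_adjust = TRUE, noise_correct = TRUE,
                            ci = c("analytic", "jackknife", "none"),
                            blocks = NULL) {
  ci <- match.arg(ci)
  full <- as_tibble(aligned)
  if (nrow(full) == 0) abort("empty summary-statistic table")
  n_full <- if (!is.null(n)) rep(as.numeric(n), nrow(full)) else full$n_eff
  if (any(n_full <= 1)) abort("sample size must exceed 1")
  eta_full <- if (ld_adjust) full$eta else rep(1, nrow(full))
  if (is.null(sigma2_e)) {
    sigma2_e <- residual_variance_scale(full$b, eta_full, n_full)
  }

  keep <- seq_len(nrow(full))
  if (!is.null(snps)) {
    if (is.character(snps)) {
      found <- snps %in% full$snp_id
      if (!all(found)) {
        inform(sprintf("excluding %d region SNP(s) without summary statistics",
                       sum(!found)))
      }
      keep <- match(snps[found], full$snp_id)
    } else {
      keep <- snps
    }
  }
  tab <- full[keep, ]
  if (nrow(tab) == 0) abort("no SNPs with summary statistics in the region")
  n_eff <- n_full[keep]
  eta <- eta_full[keep]

  raw_sum <- sum(per_snp_variance(tab$b, eta))
  m_eff <- sum(1 / eta)
  noise_term <- if (noise_correct) sigma2_e * sum(1 / (eta * (n_eff - 1))) else 0
  estimate <- raw_sum - noise_term
  n_used <- mean(n_eff)
  vb <- variance_bound(m_eff, n_used, estimate)

  ci_low <- ci_high <- NA_real_
  if (ci == "analytic") {
    half <- 1.96 * sqrt(vb)
    ci_low <- estimate - half
    ci_high <- estimate + half
  } else if (ci == "jackknife") {
    contrib <- per_snp_variance(tab$b, eta) -
      (if (noise_correct) sigma2_e / (eta * (n_eff - 1)) else 0)
    jk <- block_jackknife_ci(contrib, tab, blocks)
    ci_low <- jk[1]; ci_high <- jk[2]
  }

  structure(
    list(region_id = region_id, m_snps = nrow(tab), m_eff = m_eff,
         raw_sum = raw_sum, noise_term = noise_term, estimate = estimate,
         variance_bound = vb, ci_low = ci_low, ci_high = ci_high,
         n_used = n_used, sigma2_e = sigma2_e, ci_method = ci,
         ld_adjust = ld_adjust, noise_correct = noise_correct),
    class = "regional_estimate"
  )
}

# residual (non-genetic) trait variance implied by the genome-wide sum:
# solving est = raw - sigma2_e * C with sigma2_e = 1 - est gives
# sigma2_e = (1 - raw) / (1 - C), C = sum(1 / (eta * (n - 1))).
# Requires the effective marker count to be small relative to N.
residual_variance_scale <- function(b, eta, n_eff) {
  C <- sum(1 / (eta * (n_eff - 1)))
  if (C >= 1) abort("effective marker count must be smaller than the sample size")
  max(0, (1 - sum(per_snp_variance(b, eta))) / (1 - C))
}

# delete-one-block jackknife CI for a genome-wide sum of per-SNP contributions
block_jackknife_ci <- function(contrib, tab, blocks, level = 0.95) {
  if (is.null(blocks)) abort("jackknife CI needs a block partition")
  map <- blocks$snp_map
  bid <- map$block_id[match(tab$snp_id, map$snp_id)]
  if (anyNA(bid)) abort("some SNPs are not covered by the block partition")
  s <- tapply(contrib, bid, sum)
  J <- length(s)
  if (J < 30) abort("fewer than 30 blocks: use the analytic CI instead")
  total <- sum(s)
  # theta_{-j} = J/(J-1) * (total - s_j); var_jack = (J-1)/J * sum((theta_{-j} - mean)^2)
  th <- (J / (J - 1)) * (total - s)
  se <- sqrt((J - 1) / J * sum((th - mean(th))^2))
  z <- qnorm(1 - (1 - level) / 2)
  c(total - z * se, total + z * se)
}

#' @export
print.regional_estimate <- function(x, ...) {
  cat(sprintf("<regional_estimate> %s\n", x$region_id))
  cat(sprintf("  %d SNPs (m_eff %.1f), N = %.0f\n", x$m_snps, x$m_eff, x$n_used))
  cat(sprintf("  variance explained: %.4g  [%.4g, %.4g] (%s CI)\n",
              x$estimate, x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}

#' @method tidy regional_estimate
#' @export
tidy.regional_estimate <- function(x, ...) {
  tibble(region_id = x$region_id, m_snps = x$m_snps, m_eff = x$m_eff,
         raw_sum = x$raw_sum, noise_term = x$noise_term,
         estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @method glance regional_estimate
#' @export
glance.regional_estimate <- function(x, ...) {
  tibble(estimate = x$estimate, variance_bound = x$variance_bound,
         m_snps = x$m_snps, m_eff = x$m_eff, n_used = x$n_used,
         ci_method = x$ci_method)
}

#' Rank SNP blocks by regional variance explained
#'
#' One regional estimate per block of a partition, sorted by decreasing
#' estimate, with a cumulative-sum column for top-k% analyses and each
#' block's minimum univariate association p-value as a diagnostic (regions
#' can rank high through many weak associations rather than one strong
#' one).
#'
#' @inheritParams estimate_region
#' @param blocks a [partition_blocks()] result.
#' @return Object of class `block_ranking` wrapping a per-block tibble
#'   (`rank`, `block_id`, `chrom`, `start_bp`, `end_bp`, `m`, `m_eff`,
#'   `raw_sum`, `estimate`, `ci_low`, `ci_high`, `min_p`, `cum_estimate`,
#'   `prop_blocks`).
#' @export
rank_blocks <- function(aligned, blocks, n = NULL) {
  stopifnot(inherits(blocks, "block_partition"))
  tab <- as_tibble(aligned)
  map <- blocks$snp_map
  tab$block_id <- map$block_id[match(tab$snp_id, map$snp_id)]
  dropped <- sum(is.na(tab$block_id))
  if (dropped > 0) {
    inform(sprintf("%d SNP(s) outside the partition excluded", dropped))
    tab <- tab[!is.na(tab$block_id), ]
  }
  n_eff <- if (!is.null(n)) rep(as.numeric(n), nrow(tab)) else tab$n_eff
  contrib <- per_snp_variance(tab$b, tab$eta)
  sigma2_e <- residual_variance_scale(tab$b, tab$eta, n_eff)
  noise <- sigma2_e / (tab$eta * (n_eff - 1))
  per <- tibble(block_id = tab$block_id, contrib = contrib, noise = noise,
                inv_eta = 1 / tab$eta, p = tab$p) |>
    group_by(.data$block_id) |>
    summarise(m = dplyr::n(), m_eff = sum(.data$inv_eta),
              raw_sum = sum(.data$contrib),
              estimate = sum(.data$contrib) - sum(.data$noise),
              min_p = suppressWarnings(min(.data$p, na.rm = TRUE)),
              .groups = "drop")
  per$min_p[!is.finite(per$min_p)] <- NA_real_
  per <- left_join(per,
                   blocks$blocks[, c("block_id", "chrom", "start_bp", "end_bp")],
                   by = "block_id")
  nb <- if (!is.null(n)) as.numeric(n) else
    as.numeric(tapply(n_eff, tab$block_id, mean)[per$block_id])
  half <- as.numeric(1.96 * sqrt(variance_bound(per$m_eff, nb, per$estimate)))
  per$ci_low <- per$estimate - half
  per$ci_high <- per$estimate + half
  per <- arrange(per, desc(.data$estimate))
  per$rank <- seq_len(nrow(per))
  per$cum_estimate <- cumsum(per$estimate)
  per$prop_blocks <- per$rank / nrow(per)
  per <- per[, c("rank", "block_id", "chrom", "start_bp", "end_bp", "m",
                 "m_eff", "raw_sum", "estimate", "ci_low", "ci_high",
                 "min_p", "cum_estimate", "prop_blocks")]
  structure(list(table = per, n = n), class = "block_ranking")
}

#' @export
print.block_ranking <- function(x, ...) {
  cat(sprintf("<block_ranking> %d blocks, genome-wide estimate %.4g\n",
              nrow(x$table), sum(x$table$estimate)))
  print(head(x$table, 5))
  invisible(x)
}

#' @method tidy block_ranking
#' @export
tidy.block_ranking <- function(x, ...) x$table

#' @method glance block_ranking
#' @export
glance.block_ranking <- function(x, ...) {
  tab <- x$table
  k25 <- max(1L, floor(0.25 * nrow(tab)))
  total <- sum(tab$estimate)
  tibble(n_blocks = nrow(tab), total_estimate = total,
         top25_share = if (total > 0) sum(tab$estimate[seq_len(k25)]) / total
                       else NA_real_,
         min_p_genome = suppressWarnings(min(tab$min_p, na.rm = TRUE)))
}

#' @method autoplot block_ranking
#' @export
autoplot.block_ranking <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$prop_blocks,
                                    y = .data$cum_estimate)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(intercept = 0, slope = sum(tab$estimate),
                         linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "proportion of top-ranked blocks",
                  y = "cumulative variance explained",
                  title = "Concentration of regional genetic variance") +
    ggplot2::theme_minimal()
}
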