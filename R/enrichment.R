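#' Test a genomic window for excess regional variance
#'
#' Estimates the LD-adjusted variance explained by all SNPs within
#' `half_width` bp of a locus (e.g. a linkage-peak marker) and compares it
#' with the genome-wide average over randomly placed contiguous windows of
#' the *same SNP count* (the estimator's null variance scales with the
#' effective marker count, which tracks SNP count, so SNP-count matching
#' equalizes the null). The p-value is the empirical two-sided tail
#' probability with the `(r + 1) / (n_resample + 1)` correction.
#'
#' @inheritParams estimate_region
#' @param center_chrom,center_pos the window centre (peak marker position).
#' @param half_width half-width in bp (default 7.5 Mb).
#' @param n_resample number of null reference windows (>= 100 advised).
#' @param seed optional integer seed for the window resampling; stored in
#'   the result for reproducibility.
#' @param blocks optional [partition_blocks()] annotation; accepted for
#'   interface compatibility, not used by the resampling null.
#' @return Object of class `enrichment_test`: list with `excess` (window
#'   estimate minus the mean reference estimate), `ci_low`, `ci_high`
#'   (basic resampling interval), `p` (two-sided), `target`, `m_window`,
#'   `reference` (the resampled window estimates), `seed`.
#' @export
enrichment_test <- function(aligned, center_chrom, center_pos,
                            half_width = 7.5e6, n = NULL,
                            n_resample = 999, seed = NULL, blocks = NULL) {
  tab <- arrange(as_tibble(aligned), .data$chrom, .data$pos)
  if (n_resample < 100) warn("fewer than 100 resamples: p-value resolution is poor")
  local_rng(seed)

  n_eff <- if (!is.null(n)) rep(as.numeric(n), nrow(tab)) else tab$n_eff
  sigma2_e <- residual_variance_scale(tab$b, tab$eta, n_eff)
  contrib <- per_snp_variance(tab$b, tab$eta) -
    sigma2_e / (tab$eta * (n_eff - 1))

  in_win <- tab$chrom == center_chrom &
    abs(tab$pos - center_pos) <= half_width
  k <- sum(in_win)
  if (k == 0) abort("no SNPs with summary statistics in the window")
  target <- sum(contrib[in_win])

  # valid start indices for contiguous k-SNP windows within one chromosome
  chrom_rle <- rle(tab$chrom)
  ends <- cumsum(chrom_rle$lengths)
  starts_chrom <- ends - chrom_rle$lengths + 1L
  valid <- unlist(lapply(seq_along(ends), function(i) {
    if (chrom_rle$lengths[i] >= k) seq.int(starts_chrom[i], ends[i] - k + 1L)
    else integer(0)
  }))
  if (length(valid) == 0) abort("no chromosome long enough for a matched window")

  cs <- cumsum(contrib)
  win_sum <- function(s) cs[s + k - 1L] - c(0, cs)[s]
  draw <- sample(valid, n_resample, replace = TRUE)
  reference <- win_sum(draw)

  refc <- reference - mean(reference)
  excess <- target - mean(reference)
  p <- (sum(abs(refc) >= abs(excess)) + 1) / (n_resample + 1)
  q <- quantile(refc, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(excess = excess, ci_low = excess - q[2], ci_high = excess - q[1],
         p = p, target = target, m_window = k,
         reference = reference, n_resample = n_resample, seed = seed,
         center_chrom = center_chrom, center_pos = center_pos,
         half_width = half_width),
    class = "enrichment_test"
  )
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("<enrichment_test> %s:%d +/- %.3g Mb (%d SNPs)\n",
              x$center_chrom, x$center_pos, x$half_width / 1e6, x$m_window))
  cat(sprintf("  excess regional variance %.4g [%.4g, %.4g], two-sided p = %.3g\n",
              x$excess, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' @method tidy enrichment_test
#' @export
tidy.enrichment_test <- function(x, ...) {
  tibble(region = sprintf("%s:%d+/-%g", x$center_chrom, x$center_pos,
                          x$half_width),
         excess = x$excess, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p)
}

#' @method glance enrichment_test
#' @export
glance.enrichment_test <- function(x, ...) {
  tibble(excess = x$excess, p = x$p, m_window = x$m_window,
         n_resample = x$n_resample,
         reference_mean = mean(x$reference),
         reference_sd = sd(x$reference))
}

#' @method autoplot enrichment_test
#' @export
autoplot.enrichment_test <- function(object, ...) {
  df <- tibble(reference = object$reference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$target, colour = "red") +
    ggplot2::labs(x = "regional estimate of matched null windows",
                  y = "count",
                  title = sprintf("Window estimate vs. genome-wide reference (p = %.3g)",
                                  object$p)) +
    ggplot2::theme_minimal()
}
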