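#' Align GWAS summary statistics with an LD reference
#'
#' Intersects a summary-statistics table with a per-SNP eta table (and,
#' optionally, the LD panel's allele metadata), resolving allele coding and
#' effect-size scale so that downstream sums operate on standardized-scale
#' effects aligned to the LD reference.
#'
#' Allele handling (only when `panel_meta` is supplied): effects reported for
#' the panel's alternate allele are kept; effects reported for the reference
#' allele are sign-flipped; SNPs whose alleles match neither are dropped.
#' Strand-ambiguous SNPs (A/T, C/G) can be dropped with `drop_ambiguous`.
#'
#' @param stats data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `b`, `se`, `n_eff` (and optionally `p`), e.g. from
#'   [gwas()] or [read_sumstats()].
#' @param eta a [ld_eta()] table.
#' @param panel_meta optional per-SNP allele table (`id`, `allele_ref`,
#'   `allele_alt`, and `maf` when `scale = "raw"`), typically
#'   `panel$snp_meta`.
#' @param scale `"beta"` if `b` is already on the standardized
#'   genotype/trait scale; `"z"` to reconstruct `b = z / sqrt(n_eff)` from
#'   `z = b/se` (recommended for meta-analysis input with unknown trait
#'   units); `"raw"` if `b` is per allele, rescaled by
#'   `sqrt(2 maf (1-maf)) / sd_y`.
#' @param sd_y trait standard deviation for `scale = "raw"`.
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) SNPs.
#' @return tibble of class `largv_aligned` with columns `snp_id`, `chrom`,
#'   `pos`, `b`, `se`, `n_eff`, `p` (NA if absent), `eta`, `flipped`; the
#'   harmonization report (counts of matched / flipped / dropped SNPs) is in
#'   `attr(, "report")`.
#' @export
harmonize <- function(stats, eta, panel_meta = NULL,
                      scale = c("beta", "z", "raw"), sd_y = 1,
                      drop_ambiguous = FALSE) {
  scale <- match.arg(scale)
  stats <- as_tibble(stats)
  need <- c("snp_id", "b", "se", "n_eff")
  miss <- setdiff(need, names(stats))
  if (length(miss)) abort(paste0("stats lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(stats$snp_id)) abort("duplicate snp_id in summary statistics")
  if (!"p" %in% names(stats)) stats$p <- NA_real_

  report <- list(n_stats = nrow(stats), n_panel = nrow(eta),
                 dropped_ambiguous = 0L, dropped_mismatch = 0L,
                 flipped = 0L, rescaled = 0L)

  if (drop_ambiguous &&
      all(c("effect_allele", "other_allele") %in% names(stats))) {
    pair <- paste0(toupper(stats$effect_allele), toupper(stats$other_allele))
    amb <- pair %in% c("AT", "TA", "CG", "GC")
    report$dropped_ambiguous <- sum(amb)
    stats <- stats[!amb, ]
  }

  aligned <- inner_join(
    stats[, setdiff(names(stats), c("chrom", "pos"))],  # coordinates come from the LD reference
    tibble(snp_id = eta$snp_id, chrom = eta$chrom, pos = eta$pos, eta = eta$eta),
    by = "snp_id"
  )
  if (nrow(aligned) < 0.5 * min(report$n_stats, report$n_panel)) {
    warn(sprintf("only %d of %d summary-statistic SNPs matched the LD reference",
                 nrow(aligned), report$n_stats))
  }

  aligned$flipped <- FALSE
  if (!is.null(panel_meta)) {
    pm <- as_tibble(panel_meta)
    aligned <- inner_join(
      aligned,
      tibble(snp_id = pm$id, .ref = toupper(pm$allele_ref),
             .alt = toupper(pm$allele_alt),
             .maf = if ("maf" %in% names(pm)) pm$maf else NA_real_),
      by = "snp_id"
    )
    ea <- toupper(aligned$effect_allele)
    oa <- toupper(aligned$other_allele)
    keep_same <- ea == aligned$.alt & oa == aligned$.ref
    keep_flip <- ea == aligned$.ref & oa == aligned$.alt
    report$dropped_mismatch <- sum(!(keep_same | keep_flip))
    aligned <- aligned[keep_same | keep_flip, ]
    flip <- (toupper(aligned$effect_allele) == aligned$.ref)
    aligned$b[flip] <- -aligned$b[flip]
    aligned$flipped <- flip
    report$flipped <- sum(flip)
  }

  if (scale == "z") {
    aligned$b <- (aligned$b / aligned$se) / sqrt(aligned$n_eff)
    aligned$se <- 1 / sqrt(aligned$n_eff)
    report$rescaled <- nrow(aligned)
  } else if (scale == "raw") {
    maf <- if (".maf" %in% names(aligned)) aligned$.maf else NULL
    if (is.null(maf) || anyNA(maf)) {
      abort("scale = \"raw\" needs panel_meta with a maf column")
    }
    fac <- sqrt(2 * maf * (1 - maf)) / sd_y
    aligned$b <- aligned$b * fac
    aligned$se <- aligned$se * fac
    report$rescaled <- nrow(aligned)
  }

  out <- aligned[, c("snp_id", "chrom", "pos", "b", "se", "n_eff", "p",
                     "eta", "flipped")]
  out <- arrange(out, .data$chrom, .data$pos)
  report$n_aligned <- nrow(out)
  attr(out, "report") <- report
  class(out) <- c("largv_aligned", class(out))
  out
}

#' @export
#' @rdname harmonize
harmonize_report <- function(x) attr(x, "report")
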