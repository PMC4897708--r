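#' Windowed pairwise LD (r-squared)
#'
#' Computes squared Pearson correlations between every pair of SNPs at most
#' `window` positions apart on the same chromosome arm (composite LD from
#' unphased dosages). Pairs spanning an arm boundary are not stored and are
#' treated as r-squared = 0 downstream, i.e. assumed in linkage equilibrium.
#'
#' The result is a banded store: `band[d, j]` holds the r-squared between SNP
#' `d` and SNP `d + j` for lags `j = 1..window` (`NA` where the pair crosses
#' an arm boundary or runs off the end). The diagonal (`j = 0`) is 1 by
#' definition and not stored.
#'
#' @param x a [largv_panel()] or [standardize_genotypes()] result.
#' @param window integer window half-width in SNP count; the default 100
#'   assumes loci more than 100 SNPs apart are in linkage equilibrium
#'   (other values may be used).
#' @param arms optional data frame `chrom`, `centromere_bp` splitting each
#'   listed chromosome into p/q arms at the given coordinate; chromosomes not
#'   listed (or `arms = NULL`) are treated as a single arm.
#' @return An object of class `largv_ld`: list with `band` (m x window
#'   matrix), `window`, `snp_meta` (with an `arm` column), `n_individuals`.
#' @export
ld_windowed_r2 <- function(x, window = 100L, arms = NULL) {
  std <- as_largv_std(x)
  window <- as.integer(window)
  if (window < 1L) abort("window must be >= 1")
  X <- std$matrix
  n <- nrow(X)
  m <- ncol(X)
  meta <- std$snp_meta
  if (nrow(meta) != m) abort("snp_meta misaligned with genotype columns")
  arm <- arm_labels(meta, arms)

  band <- matrix(NA_real_, m, max(window, 1L))
  w_eff <- min(window, m - 1L)
  if (m >= 2L && w_eff >= 1L) {
    if (m <= 4000L) {
      # dense route: one crossprod, then extract the band
      R <- crossprod(X) / n
      for (j in seq_len(w_eff)) {
        band[seq_len(m - j), j] <- R[cbind(seq_len(m - j), seq_len(m - j) + j)]^2
      }
    } else {
      for (j in seq_len(w_eff)) {
        d <- seq_len(m - j)
        band[d, j] <- (colSums(X[, d, drop = FALSE] * X[, d + j, drop = FALSE]) / n)^2
      }
    }
    # blank pairs that span an arm boundary
    for (j in seq_len(w_eff)) {
      d <- seq_len(m - j)
      band[d[arm[d] != arm[d + j]], j] <- NA_real_
    }
    band[band > 1] <- 1  # guard FP overshoot
  }
  meta$arm <- arm
  structure(
    list(band = band, window = window, snp_meta = meta, n_individuals = n),
    class = "largv_ld"
  )
}

arm_labels <- function(meta, arms = NULL) {
  arm <- as.character(meta$chrom)
  if (!is.null(arms)) {
    arms <- as_tibble(arms)
    stopifnot(all(c("chrom", "centromere_bp") %in% names(arms)))
    for (i in seq_len(nrow(arms))) {
      on <- arm == as.character(arms$chrom[i])
      arm[on] <- paste0(arms$chrom[i],
                        ifelse(meta$pos[on] <= arms$centromere_bp[i], "p", "q"))
    }
  }
  arm
}

#' @export
print.largv_ld <- function(x, ...) {
  cat(sprintf("<largv_ld> %d SNPs, window %d (%d individuals)\n",
              nrow(x$band), x$window, x$n_individuals))
  invisible(x)
}

#' Retrieve a stored pairwise r-squared
#'
#' @param ld a [ld_windowed_r2()] result.
#' @param d,k SNP indices. Returns 1 when `d == k`, the stored value when
#'   `|d - k| <= window` on the same arm, and 0 otherwise.
#' @export
ld_r2_at <- function(ld, d, k) {
  stopifnot(inherits(ld, "largv_ld"))
  lo <- pmin(d, k); lag <- abs(d - k)
  out <- numeric(length(lo))
  out[lag == 0] <- 1
  sel <- lag >= 1 & lag <= ld$window
  v <- ld$band[cbind(lo[sel], lag[sel])]
  v[is.na(v)] <- 0
  out[sel] <- v
  out
}

#' Per-SNP LD adjustment (eta)
#'
#' For each SNP `d`, eta is the sum of r-squared between `d` and every SNP
#' within `window` positions up- and downstream on the same arm, including
#' the self term r-squared = 1. Under linkage equilibrium eta = 1, so the
#' per-SNP variance `b^2 / eta` reduces to `b^2` and the effective marker
#' count equals the SNP count; the window truncates naturally at arm ends.
#'
#' By default each off-diagonal term is the sampling-debiased
#' `max(0, r2 - (1 - r2) / (n - 2))`: the sample r-squared of two truly
#' uncorrelated SNPs has expectation about `1/n`, and summing hundreds of
#' such terms would inflate eta by `2 * window / n`. The floor at zero keeps
#' eta >= 1 and leaves exact-LD values (0 and 1) untouched;
#' `debias = FALSE` gives the plain sum of sample r-squared.
#'
#' @param ld a [ld_windowed_r2()] result.
#' @param debias subtract the null sampling bias of each pairwise r-squared
#'   (default `TRUE`).
#' @return A tibble of class `largv_eta` with columns `snp_id`, `chrom`,
#'   `pos`, `eta`, `window`.
#' @export
ld_eta <- function(ld, debias = TRUE) {
  stopifnot(inherits(ld, "largv_ld"))
  m <- nrow(ld$band)
  eta <- rep(1, m)
  w <- min(ld$window, max(m - 1L, 0L))
  b <- ld$band
  if (debias && ld$n_individuals > 2) {
    b <- b - (1 - b) / (ld$n_individuals - 2)
    b[b < 0] <- 0
  }
  b[is.na(b)] <- 0
  for (j in seq_len(w)) {
    d <- seq_len(m - j)
    eta[d] <- eta[d] + b[d, j]        # downstream partner
    eta[d + j] <- eta[d + j] + b[d, j] # upstream partner
  }
  out <- tibble(
    snp_id = ld$snp_meta$id,
    chrom = ld$snp_meta$chrom,
    pos = ld$snp_meta$pos,
    eta = eta,
    window = ld$window
  )
  class(out) <- c("largv_eta", class(out))
  out
}

#' Effective number of markers
#'
#' `m_eff = sum(1 / eta)` over a SNP subset: the number of markers
#' discounted for LD. It equals the subset size when every SNP is in
#' linkage equilibrium (all eta = 1) and is strictly smaller under any LD.
#'
#' @param eta a [ld_eta()] tibble, or a bare numeric vector of eta values.
#' @param subset optional SNP selection: integer indices, logical mask, or
#'   character SNP ids. Default: all SNPs.
#' @return Scalar `m_eff`.
#' @export
effective_markers <- function(eta, subset = NULL) {
  e <- if (is.data.frame(eta)) eta$eta else as.numeric(eta)
  ids <- if (is.data.frame(eta)) eta$snp_id else NULL
  if (!is.null(subset)) {
    if (is.character(subset)) {
      if (is.null(ids)) abort("character subset needs an eta table with snp_id")
      e <- e[match(subset, ids)]
      if (anyNA(e)) abort("subset contains unknown SNP ids")
    } else {
      e <- e[subset]
    }
  }
  if (length(e) == 0) abort("empty SNP subset")
  if (any(e < 1 - 1e-8)) abort("eta values must be >= 1")
  sum(1 / e)
}

#' @method autoplot largv_eta
#' @export
autoplot.largv_eta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos / 1e6, y = .data$eta)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(eta[d]),
                  title = "Per-SNP LD adjustment") +
    ggplot2::theme_minimal()
}
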