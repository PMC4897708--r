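#' LD model specifications for the genotype simulator
#'
#' Three latent-correlation structures: `ld_independent()` (linkage
#' equilibrium), `ld_ar1(rho)` (correlation decaying geometrically with SNP
#' distance), and `ld_blockwise(block_len, rho_in)` (equicorrelated blocks of
#' `block_len` SNPs with independence across blocks — known true LD-block
#' breakpoints every `block_len` SNPs).
#'
#' @param rho latent adjacent-SNP correlation, in `[0, 1)`.
#' @param block_len SNPs per LD block.
#' @param rho_in latent within-block correlation, in `[0, 1)`.
#' @name ld_models
NULL

#' @rdname ld_models
#' @export
ld_independent <- function() structure(list(model = "independent"), class = "largv_ld_model")

#' @rdname ld_models
#' @export
ld_ar1 <- function(rho = 0.8) {
  stopifnot(rho >= 0, rho < 1)
  structure(list(model = "ar1", rho = rho), class = "largv_ld_model")
}

#' @rdname ld_models
#' @export
ld_blockwise <- function(block_len = 20L, rho_in = 0.8) {
  stopifnot(block_len >= 1, rho_in >= 0, rho_in < 1)
  structure(list(model = "blockwise", block_len = as.integer(block_len),
                 rho_in = rho_in), class = "largv_ld_model")
}

#' Simulate a genotype panel with controllable LD
#'
#' Haplotype alleles are generated by thresholding a latent Gaussian with
#' the configured correlation structure at each SNP's frequency quantile, so
#' each allele is marginally Bernoulli(maf) and the realized dosage LD decays
#' with the latent correlation. A genotype is the sum of two independent
#' haplotypes. Deterministic given `seed`. Columns that come out monomorphic
#' (possible at small `n` and low maf) are redrawn as independent
#' Bernoulli(maf) columns so every SNP is polymorphic.
#'
#' @param n_individuals,n_snps panel dimensions.
#' @param ld_model an [ld_independent()], [ld_ar1()] or [ld_blockwise()]
#'   specification.
#' @param maf_range per-SNP minor allele frequencies are drawn uniformly
#'   from this range.
#' @param chrom chromosome label; `spacing_bp` the (even) inter-SNP spacing.
#' @param seed integer seed; the RNG state is restored on exit.
#' @return a [largv_panel()].
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               ld_model = ld_independent(),
                               maf_range = c(0.05, 0.5),
                               chrom = "1", spacing_bp = 5000L,
                               seed = NULL) {
  stopifnot(inherits(ld_model, "largv_ld_model"),
            maf_range[1] > 0, maf_range[1] <= maf_range[2], maf_range[2] <= 0.5)
  local_rng(seed)
  n <- as.integer(n_individuals); m <- as.integer(n_snps)
  maf <- runif(m, maf_range[1], maf_range[2])
  thr <- qnorm(maf)

  draw_haplotype <- function() {
    Z <- switch(ld_model$model,
      independent = matrix(rnorm(n * m), n, m),
      ar1 = {
        Z <- matrix(rnorm(n * m), n, m)
        r <- ld_model$rho; s <- sqrt(1 - r^2)
        for (j in seq_len(m)[-1]) Z[, j] <- r * Z[, j - 1] + s * Z[, j]
        Z
      },
      blockwise = {
        E <- matrix(rnorm(n * m), n, m)
        blk <- rep(seq_len(ceiling(m / ld_model$block_len)),
                   each = ld_model$block_len)[seq_len(m)]
        U <- matrix(rnorm(n * max(blk)), n, max(blk))
        sqrt(ld_model$rho_in) * U[, blk, drop = FALSE] +
          sqrt(1 - ld_model$rho_in) * E
      })
    (Z < rep(thr, each = n)) * 1
  }
  G <- draw_haplotype() + draw_haplotype()

  mono <- which(apply(G, 2, function(g) min(g) == max(g)))
  tries <- 0
  while (length(mono) > 0 && tries < 100) {
    for (j in mono) {
      G[, j] <- stats::rbinom(n, 1, maf[j]) + stats::rbinom(n, 1, maf[j])
    }
    mono <- which(apply(G, 2, function(g) min(g) == max(g)))
    tries <- tries + 1
  }
  if (length(mono) > 0) abort("could not produce polymorphic SNPs; increase n or maf")

  meta <- tibble(id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
                 pos = as.integer(spacing_bp) * seq_len(m),
                 allele_ref = "A", allele_alt = "G")
  largv_panel(G, meta)
}

#' Simulate an additive polygenic trait
#'
#' Draws causal effects `beta ~ N(0, sigma^2)` on the standardized-genotype
#' scale for the chosen causal SNPs, rescales them so the realized genetic
#' variance `Var(X beta)` equals `h2` exactly, and adds an environmental
#' residual orthogonalized and scaled so the realized trait variance is
#' exactly 1. No interaction or haplotype effects. The "true" regional
#' variance reported by [realized_regional_variance()] is the realized
#' `Var(X_region beta_region) / Var(y)` in the simulated sample, which frees
#' recovery tests from beta-sampling noise.
#'
#' @param x a [largv_panel()] or [standardize_genotypes()] result.
#' @param h2 trait variance explained jointly by the causal SNPs, in `[0, 1)`.
#' @param prop_causal fraction of SNPs that are causal (default 1: the
#'   infinitesimal model in which every SNP carries a random effect).
#' @param causal_snps optional explicit causal SNP indices, overriding
#'   `prop_causal`.
#' @param seed integer seed; RNG state restored on exit.
#' @return Object of class `largv_trait`: list with `y` (length n, mean 0,
#'   variance 1), `beta` (length m, zero for non-causal SNPs), `g` (genetic
#'   values), `causal` (indices), `h2`.
#' @export
simulate_trait <- function(x, h2, prop_causal = 1, causal_snps = NULL,
                           seed = NULL) {
  stopifnot(h2 >= 0, h2 < 1)
  std <- as_largv_std(x)
  local_rng(seed)
  n <- nrow(std$matrix); m <- ncol(std$matrix)
  pvar <- function(v) sum((v - mean(v))^2) / length(v)

  if (is.null(causal_snps)) {
    n_causal <- max(1L, round(prop_causal * m))
    causal_snps <- if (n_causal == m) seq_len(m) else sort(sample.int(m, n_causal))
  }
  beta <- numeric(m)
  g <- numeric(n)
  if (h2 > 0) {
    b0 <- rnorm(length(causal_snps))
    g0 <- as.numeric(std$matrix[, causal_snps, drop = FALSE] %*% b0)
    sc <- sqrt(h2 / pvar(g0))
    beta[causal_snps] <- b0 * sc
    g <- g0 * sc
  }
  e0 <- rnorm(n); e0 <- e0 - mean(e0)
  if (h2 > 0) e0 <- e0 - g * (sum(e0 * g) / sum(g^2))  # orthogonalize to g
  e <- e0 * sqrt((1 - h2) / pvar(e0))
  y <- g + e
  structure(list(y = y, beta = beta, g = g, causal = causal_snps, h2 = h2),
            class = "largv_trait")
}

#' Realized variance explained by a SNP region in a simulated sample
#'
#' @param x the panel or standardized genotypes the trait was simulated on.
#' @param trait a [simulate_trait()] result.
#' @param snps SNP indices of the region (default: all).
#' @return Scalar realized `Var(X_region beta_region) / Var(y)`.
#' @export
realized_regional_variance <- function(x, trait, snps = NULL) {
  std <- as_largv_std(x)
  if (is.null(snps)) snps <- seq_len(ncol(std$matrix))
  gr <- as.numeric(std$matrix[, snps, drop = FALSE] %*% trait$beta[snps])
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  pv(gr) / pv(trait$y)
}

#' Univariate GWAS on a simulated or real panel
#'
#' Per-SNP ordinary least squares of the trait on each standardized SNP with
#' intercept. With population-SD standardized genotypes the slope is
#' `sum(x * (y - mean(y))) / n`, its standard error
#' `sqrt(RSS / ((n - 2) n))`, and the p-value two-sided from the t(n-2)
#' distribution — identical to `lm()` per SNP.
#'
#' @param x a [largv_panel()] or [standardize_genotypes()] result.
#' @param y numeric trait vector (length n) or a [simulate_trait()] result.
#' @return tibble (SummaryStats): `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `b`, `se`, `p`, `n_eff`.
#' @export
gwas <- function(x, y) {
  std <- as_largv_std(x)
  if (inherits(y, "largv_trait")) y <- y$y
  X <- std$matrix
  n <- nrow(X)
  if (length(y) != n) abort("trait length must match individuals")
  yc <- y - mean(y)
  b <- as.numeric(crossprod(X, yc)) / n
  syy <- sum(yc^2)
  rss <- pmax(syy - n * b^2, 0)
  se <- sqrt(rss / ((n - 2) * n))
  tstat <- ifelse(se > 0, b / se, sign(b) * Inf)
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble(
    snp_id = std$snp_meta$id, chrom = std$snp_meta$chrom,
    pos = std$snp_meta$pos,
    effect_allele = std$snp_meta$allele_alt,
    other_allele = std$snp_meta$allele_ref,
    b = b, se = se, p = p, n_eff = n
  )
}

# seed the RNG for the calling function's scope, restoring the caller's
# stream on exit (no-op when seed is NULL)
local_rng <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  withr::local_preserve_seed(.local_envir = env)
  set.seed(seed)
  invisible(NULL)
}
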