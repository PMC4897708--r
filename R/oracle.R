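#' Residualize and standardize a phenotype
#'
#' Trims trait values outside the given percentile range (outlier control),
#' regresses the remainder on the named covariates (e.g. age, sex, genetic
#' principal components), and standardizes the residuals to mean 0, SD 1.
#' Covariate adjustment is done once, up front, rather than inside every
#' per-block model.
#'
#' @param pheno data frame with columns `individual_id`, the trait, and any
#'   covariates.
#' @param trait name of the trait column (default `"y"`).
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param trim percentile bounds `c(low, high)` in `[0, 100]`; values
#'   outside are dropped. `c(0, 100)` disables trimming.
#' @return tibble `individual_id`, `y_resid` (one row per retained
#'   individual).
#' @export
preprocess_phenotype <- function(pheno, trait = "y", covariates = character(),
                                 trim = c(1, 99)) {
  pheno <- as_tibble(pheno)
  stopifnot(all(c("individual_id", trait, covariates) %in% names(pheno)),
            length(trim) == 2, trim[1] >= 0, trim[2] <= 100, trim[1] < trim[2])
  y <- pheno[[trait]]
  keep <- !is.na(y)
  if (trim[1] > 0 || trim[2] < 100) {
    q <- quantile(y[keep], trim / 100, names = FALSE)
    keep <- keep & y >= q[1] & y <= q[2]
  }
  if (sum(keep, na.rm = TRUE) < 3) abort("too few trait values remain after trimming")
  dat <- pheno[which(keep), c(trait, covariates)]
  if (length(covariates) > 0) {
    fm <- stats::as.formula(paste0("`", trait, "` ~ ",
                                   paste0("`", covariates, "`", collapse = " + ")))
    fit <- lm(fm, data = dat)
    if (anyNA(stats::coef(fit))) abort("collinear covariates")
    r <- residuals(fit)
  } else {
    r <- dat[[trait]] - mean(dat[[trait]])
  }
  s <- sd(r)
  if (!is.finite(s) || s <= .Machine$double.eps^0.5) {
    abort("residual trait variance is zero after covariate adjustment")
  }
  tibble(individual_id = pheno$individual_id[which(keep)],
         y_resid = as.numeric(scale(r)))
}

#' Genetic principal components
#'
#' Top-`k` eigenvectors of the genetic relationship matrix `X X' / m`
#' computed from standardized genotypes, for use as stratification
#' covariates. Columns are unit-norm with a deterministic sign convention
#' (the largest-magnitude loading is positive).
#'
#' @param x a [largv_panel()] or [standardize_genotypes()] result.
#' @param k number of components, `k < min(n, m)`; `k = 0` returns an
#'   `n x 0` matrix.
#' @return `n x k` matrix with columns `PC1..PCk`.
#' @export
genetic_pcs <- function(x, k = 20L) {
  std <- as_largv_std(x)
  n <- nrow(std$matrix); m <- ncol(std$matrix)
  if (k >= min(n, m)) abort("k must be smaller than min(n_individuals, n_snps)")
  if (k == 0) return(matrix(numeric(0), n, 0))
  G <- tcrossprod(std$matrix) / m
  ev <- eigen(G, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(k))
  V
}

#' Adjusted R-squared of one SNP block
#'
#' Ordinary least squares of the (residualized) trait on all SNPs of a block
#' jointly, with intercept. Rank-deficient blocks (perfect within-block LD)
#' are handled by dropping redundant columns, with the regressor count `m`
#' set to the retained columns so the adjustment stays null-centred. The
#' adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - m - 1)` has expectation 0
#' under the null, unlike the raw R-squared whose null mean is about `m/n`.
#'
#' @param x a [largv_panel()] or [standardize_genotypes()] result.
#' @param snps SNP column selection (integer indices, logical mask, or
#'   character ids).
#' @param y_resid numeric residualized trait, one value per individual.
#' @return One-row tibble `m`, `n`, `r2`, `adj_r2`.
#' @export
block_adjusted_r2 <- function(x, snps, y_resid) {
  std <- as_largv_std(x)
  if (is.character(snps)) snps <- match(snps, std$snp_meta$id)
  X <- std$matrix[, snps, drop = FALSE]
  n <- nrow(X)
  if (length(y_resid) != n) abort("y_resid length must match individuals")
  yc <- y_resid - mean(y_resid)
  tss <- sum(yc^2)
  # columns of a largv_std matrix are centred, so the intercept reduces to
  # centring y; normal equations via Cholesky, QR fallback on rank deficiency
  S <- crossprod(X)
  cxy <- crossprod(X, yc)
  m <- ncol(X)  # chol succeeding implies full column rank
  ess <- tryCatch({
    R <- chol(S)
    v <- backsolve(R, cxy, transpose = TRUE)
    sum(v^2)
  }, error = function(e) NULL)
  if (is.null(ess)) {
    qrx <- qr(X)
    m <- qrx$rank
    ess <- sum(qr.fitted(qrx, yc)^2)
  }
  if (m < 1) abort("no informative regressors in block")
  if (n <= m + 1L) {
    abort("n <= m + 1: use a larger sample or smaller blocks")
  }
  r2 <- ess / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  tibble(m = m, n = n, r2 = r2, adj_r2 = adj)
}

#' Sum of per-block adjusted R-squared (individual-level estimator)
#'
#' Fits every block of a partition with [block_adjusted_r2()] and sums the
#' adjusted R-squared values: the individual-level regional-variance
#' estimator that the summary-statistic estimator is asymptotically
#' equivalent to under a strictly additive model. Its genome-wide null
#' expectation is zero.
#'
#' @inheritParams block_adjusted_r2
#' @param blocks a [partition_blocks()] result.
#' @return Object of class `oracle_fit`: list with `per_block` tibble
#'   (`block_id`, `m`, `n`, `r2`, `adj_r2`) and `total`.
#' @export
sum_adjusted_r2 <- function(x, blocks, y_resid) {
  stopifnot(inherits(blocks, "block_partition"))
  std <- as_largv_std(x)
  bt <- blocks$blocks
  per <- purrr::map_dfr(seq_len(nrow(bt)), function(i) {
    res <- block_adjusted_r2(std, seq.int(bt$start_index[i], bt$end_index[i]),
                             y_resid)
    res$block_id <- bt$block_id[i]
    res
  })
  per <- per[, c("block_id", "m", "n", "r2", "adj_r2")]
  structure(list(per_block = per, total = sum(per$adj_r2)),
            class = "oracle_fit")
}

#' @export
print.oracle_fit <- function(x, ...) {
  cat(sprintf("<oracle_fit> %d blocks, total adjusted R-squared %.4g\n",
              nrow(x$per_block), x$total))
  invisible(x)
}

#' @method tidy oracle_fit
#' @export
tidy.oracle_fit <- function(x, ...) x$per_block

#' @method glance oracle_fit
#' @export
glance.oracle_fit <- function(x, ...) {
  tibble(total = x$total, n_blocks = nrow(x$per_block),
         n = x$per_block$n[1], m_total = sum(x$per_block$m))
}
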