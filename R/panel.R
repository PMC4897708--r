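#' Genotype panel
#'
#' A genotype panel couples an `n` individuals by `m` SNPs dosage matrix
#' (alternate-allele counts in `{0, 1, 2}`, `NA` for missing hard calls) with
#' per-SNP metadata. SNPs must be ordered by chromosome and strictly
#' increasing position within chromosome; this ordering is what "windowed"
#' LD and block partitioning operate on.
#'
#' @param genotypes numeric matrix, individuals in rows, SNPs in columns.
#' @param snp_meta data frame with one row per SNP and columns `id`, `chrom`,
#'   `pos` (1-based bp), `allele_ref`, `allele_alt`. Minor-allele frequency
#'   and missingness are (re)computed from the dosages.
#' @param individual_ids character vector of unique individual identifiers;
#'   defaults to the matrix rownames or `ind_1..ind_n`.
#'
#' @return An object of class `largv_panel`: a list with elements
#'   `genotypes`, `snp_meta` (tibble with added `maf` and `missingness`
#'   columns) and `individual_ids`.
#' @export
largv_panel <- function(genotypes, snp_meta, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  snp_meta <- as_tibble(snp_meta)
  required <- c("id", "chrom", "pos", "allele_ref", "allele_alt")
  missing_cols <- setdiff(required, names(snp_meta))
  if (length(missing_cols) > 0) {
    abort(paste0("snp_meta lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(snp_meta) != ncol(genotypes)) {
    abort("snp_meta rows must match genotype columns")
  }
  if (anyDuplicated(snp_meta$id)) abort("duplicate SNP ids")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) > 0 && (min(bad) < 0 || max(bad) > 2)) {
    abort("dosages must lie in [0, 2]")
  }
  # enforce (chrom, pos) sort with strictly increasing pos within chromosome
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(paste0("positions not strictly increasing on chromosome ", ch))
    }
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(genotypes)
    if (is.null(individual_ids)) {
      individual_ids <- paste0("ind_", seq_len(nrow(genotypes)))
    }
  }
  if (anyDuplicated(individual_ids)) abort("duplicate individual ids")
  if (length(individual_ids) != nrow(genotypes)) {
    abort("individual_ids must match genotype rows")
  }
  dimnames(genotypes) <- list(NULL, NULL)
  freq <- colMeans(genotypes, na.rm = TRUE) / 2
  snp_meta$maf <- pmin(freq, 1 - freq)
  snp_meta$missingness <- colMeans(is.na(genotypes))
  structure(
    list(genotypes = genotypes, snp_meta = snp_meta,
         individual_ids = as.character(individual_ids)),
    class = "largv_panel"
  )
}

#' @export
print.largv_panel <- function(x, ...) {
  cat(sprintf("<largv_panel> %d individuals x %d SNPs on chromosome(s) %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(unique(x$snp_meta$chrom), collapse = ", ")))
  cat(sprintf("  MAF range %.3f-%.3f, max missingness %.3f\n",
              min(x$snp_meta$maf), max(x$snp_meta$maf),
              max(x$snp_meta$missingness)))
  invisible(x)
}

#' @export
dim.largv_panel <- function(x) dim(x$genotypes)

#' Standardize genotype dosages
#'
#' Mean-imputes missing dosages, then centres and scales every SNP column to
#' mean 0 and standard deviation 1. The population-SD convention (denominator
#' `n`) is used throughout the package so that for standardized columns
#' `crossprod(x) = n`, which keeps the summary-statistic algebra (`X'X/N`
#' correlations, `E[b^2] = 1/N` under the null) exact rather than `O(1/n)`
#' off.
#'
#' @param panel a [largv_panel()].
#' @return An object of class `largv_std`: list with `matrix` (n x m, each
#'   column mean 0, population SD 1), `means`, `sds`, `snp_meta`,
#'   `individual_ids`.
#' @export
standardize_genotypes <- function(panel) {
  stopifnot(inherits(panel, "largv_panel"))
  X <- panel$genotypes
  if (nrow(X) == 0 || ncol(X) == 0) abort("empty genotype panel")
  means <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- means[idx[, 2]]
  }
  X <- sweep(X, 2, means, "-")
  n <- nrow(X)
  sds <- sqrt(colSums(X^2) / n)
  zero <- which(sds <= .Machine$double.eps^0.5)
  if (length(zero) > 0) {
    abort(paste0("monomorphic SNP(s): ",
                 paste(head(panel$snp_meta$id[zero], 5), collapse = ", ")))
  }
  X <- sweep(X, 2, sds, "/")
  structure(
    list(matrix = X, means = means, sds = sds,
         snp_meta = panel$snp_meta, individual_ids = panel$individual_ids),
    class = "largv_std"
  )
}

#' @export
print.largv_std <- function(x, ...) {
  cat(sprintf("<largv_std> %d x %d standardized genotype matrix\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# resolve a panel-or-std argument to largv_std
as_largv_std <- function(x) {
  if (inherits(x, "largv_std")) return(x)
  if (inherits(x, "largv_panel")) return(standardize_genotypes(x))
  abort("expected a largv_panel or largv_std object")
}
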