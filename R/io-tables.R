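#' Read and write tabular artifacts
#'
#' TSV readers/writers for the per-SNP eta table, block definitions
#' (BED-like, 0-based half-open bp intervals plus a SNP-to-block map), GWAS
#' summary statistics (configurable column mapping, gz accepted), and
#' per-block estimate tables. Numeric columns round-trip losslessly.
#'
#' @param eta a [ld_eta()] tibble; `path` a file path.
#' @name io_tables
NULL

#' @rdname io_tables
#' @export
write_eta <- function(eta, path) {
  readr::write_tsv(as_tibble(eta), path)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_eta <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           snp_id = "c", chrom = "c", pos = "i",
                           eta = "d", window = "i"))
  class(out) <- c("largv_eta", class(out))
  out
}

#' @rdname io_tables
#' @param blocks a [partition_blocks()] result.
#' @export
write_blocks <- function(blocks, path) {
  stopifnot(inherits(blocks, "block_partition"))
  bed <- mutate(blocks$blocks, start_bp = .data$start_bp - 1L)  # 0-based half-open
  readr::write_tsv(bed, path)
  readr::write_tsv(blocks$snp_map, paste0(path, ".snp_map"))
  invisible(path)
}

#' @rdname io_tables
#' @export
read_blocks <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  bed$start_bp <- bed$start_bp + 1L
  snp_map <- readr::read_tsv(paste0(path, ".snp_map"), show_col_types = FALSE,
                             col_types = "cc")
  structure(list(blocks = bed, snp_map = snp_map,
                 min_size = min(bed$n_snps), max_size = max(bed$n_snps)),
            class = "block_partition")
}

#' Read GWAS summary statistics
#'
#' Whitespace- or tab-delimited with header; gz-compressed accepted. Column
#' names are remapped to the package convention via `col_map`.
#'
#' @param path summary-statistics file.
#' @param col_map named character vector mapping package names (`snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `b`, `se`, `n_eff`,
#'   `p`) to the file's column names.
#' @return tibble in [gwas()] layout.
#' @export
read_sumstats <- function(path,
                          col_map = c(snp_id = "SNP", chrom = "CHR",
                                      pos = "POS", effect_allele = "A1",
                                      other_allele = "A2", b = "BETA",
                                      se = "SE", n_eff = "N", p = "P")) {
  tab <- readr::read_table(path, show_col_types = FALSE)
  if (ncol(tab) == 1) {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
  }
  present <- col_map[col_map %in% names(tab)]
  # columns already in package convention pass through unmapped
  canonical <- setdiff(intersect(names(col_map), names(tab)), names(present))
  present <- c(present, stats::setNames(canonical, canonical))
  need <- c("snp_id", "b", "se")
  miss <- setdiff(need, names(present))
  if (length(miss)) {
    abort(paste0("summary statistics lack required column(s): ",
                 paste(col_map[miss], collapse = ", ")))
  }
  out <- tab[, unname(present)]
  names(out) <- names(present)
  as_tibble(out)
}

#' @rdname io_tables
#' @param ranking a [rank_blocks()] result (or its tidy tibble).
#' @export
write_estimates <- function(ranking, path) {
  tab <- if (inherits(ranking, "block_ranking")) ranking$table else as_tibble(ranking)
  readr::write_tsv(tab, path)
  invisible(path)
}
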