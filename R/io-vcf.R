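#' Read genotypes from a VCF
#'
#' Converts GT fields to alternate-allele dosages via vcfR. Multi-allelic
#' records are skipped with a message; half calls (e.g. `./0`) are treated
#' as missing by default or as the observed allele's dosage with
#' `half_calls = "as_called"`.
#'
#' @param path VCF file (optionally bgzipped).
#' @param half_calls `"missing"` (default) or `"as_called"`.
#' @return a [largv_panel()].
#' @export
read_vcf <- function(path, half_calls = c("missing", "as_called")) {
  half_calls <- match.arg(half_calls)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    inform(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dose_one <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) {
      if (half_calls == "missing") return(NA_real_)
      al <- al[al != "."]
    }
    sum(al != "0")
  }
  G <- matrix(vapply(as.vector(gt), dose_one, numeric(1)),
              nrow = nrow(gt), ncol = ncol(gt))
  meta <- tibble(id = fix[keep, "ID"], chrom = fix[keep, "CHROM"],
                 pos = as.integer(fix[keep, "POS"]),
                 allele_ref = fix[keep, "REF"], allele_alt = fix[keep, "ALT"])
  blank <- is.na(meta$id) | meta$id == "."
  meta$id[blank] <- paste0(meta$chrom[blank], ":", meta$pos[blank])
  largv_panel(t(G), meta, individual_ids = colnames(gt))
}

#' Write a panel as a minimal VCF
#'
#' Plain-text VCFv4.2 with GT-only genotype fields (unphased); missing
#' dosages become `./.`.
#'
#' @param panel a [largv_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "largv_panel"))
  meta <- panel$snp_meta
  gt_of <- function(d) {
    ifelse(is.na(d), "./.", ifelse(d == 0, "0/0", ifelse(d == 1, "0/1", "1/1")))
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individual_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(meta)), function(j) {
    paste(c(meta$chrom[j], meta$pos[j], meta$id[j], meta$allele_ref[j],
            meta$allele_alt[j], ".", "PASS", ".", "GT",
            gt_of(panel$genotypes[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
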