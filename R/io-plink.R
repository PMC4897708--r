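#' Read PLINK bed/bim/fam genotypes
#'
#' Bit-exact parser for the PLINK 1 binary format (SNP-major). Dosages count
#' the bim A1 allele (stored as `allele_alt`); the 2-bit codes map to
#' dosage 2 (hom A1), missing, 1 (het), 0 (hom A2).
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @return a [largv_panel()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok)) abort(paste0("missing file(s): ", paste(paths[!ok], collapse = ", ")))
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam) < 2) abort("malformed fam file")
  iid <- as.character(fam[[2]])
  if (anyDuplicated(iid)) abort("duplicate IID in fam file")
  n <- length(iid); m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK bed file (bad magic number)")
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major bed files are supported")
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3 != bps * m) {
    abort("bed file length inconsistent with bim/fam (truncated?)")
  }
  # 2-bit code -> A1 dosage: 00 -> 2, 01 -> NA, 10 -> 1, 11 -> 0
  code_map <- c(2, NA_real_, 1, 0)
  lut <- matrix(0, 256, 4)
  for (v in 0:255) {
    lut[v + 1, ] <- code_map[1 + c(bitwAnd(v, 3L), bitwAnd(bitwShiftR(v, 2L), 3L),
                                   bitwAnd(bitwShiftR(v, 4L), 3L),
                                   bitwAnd(bitwShiftR(v, 6L), 3L))]
  }
  bytes <- as.integer(raw[-(1:3)])
  G <- matrix(NA_real_, 4 * bps, m)
  for (p in 1:4) {
    G[seq.int(p, by = 4, length.out = bps), ] <- matrix(lut[bytes + 1, p], bps, m)
  }
  G <- G[seq_len(n), , drop = FALSE]
  meta <- tibble(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                 allele_ref = bim$a2, allele_alt = bim$a1)
  largv_panel(G, meta, individual_ids = iid)
}

#' Write a panel as PLINK bed/bim/fam
#'
#' @param panel a [largv_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "largv_panel"))
  meta <- panel$snp_meta
  utils::write.table(
    data.frame(meta$chrom, meta$id, 0, meta$pos, meta$allele_alt, meta$allele_ref),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$individual_ids, panel$individual_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  G <- panel$genotypes
  n <- nrow(G); m <- ncol(G); bps <- ceiling(n / 4)
  # dosage -> 2-bit code (A1 counts): 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(1L, 4 * bps, m)  # pad with "missing"
  d <- G
  cmap <- function(x) ifelse(is.na(x), 1L, ifelse(x == 2, 0L, ifelse(x == 1, 2L, 3L)))
  codes[seq_len(n), ] <- cmap(d)
  i1 <- seq.int(1, 4 * bps, by = 4)
  byte_vals <- codes[i1, , drop = FALSE] +
    codes[i1 + 1, , drop = FALSE] * 4L +
    codes[i1 + 2, , drop = FALSE] * 16L +
    codes[i1 + 3, , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(byte_vals)), con)
  invisible(prefix)
}
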