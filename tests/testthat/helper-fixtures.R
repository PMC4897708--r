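# small deterministic fixtures built in code

# wrap a dosage matrix in a panel with evenly spaced SNPs
make_panel <- function(G, chrom = "1", spacing = 1000L) {
  m <- ncol(G)
  meta <- tibble::tibble(
    id = sprintf("snp%03d", seq_len(m)), chrom = chrom,
    pos = spacing * seq_len(m), allele_ref = "A", allele_alt = "G"
  )
  largv_panel(G, meta)
}

# panel whose dosage columns are exactly pairwise uncorrelated:
# columns are {0,2} dosages built from orthogonal +/-1 contrasts of a
# full factorial design (n = 2^k rows, up to 2^k - 1 columns)
orthogonal_panel <- function(m, k = ceiling(log2(m + 1))) {
  n <- 2^k
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  cols <- list()
  for (size in seq_len(k)) {
    for (set in utils::combn(k, size, simplify = FALSE)) {
      cols[[length(cols) + 1]] <- apply(base[, set, drop = FALSE], 1, prod)
    }
  }
  H <- do.call(cbind, cols)
  stopifnot(ncol(H) >= m)
  make_panel(H[, seq_len(m), drop = FALSE] + 1)
}

# dense pairwise r^2 by an independent route (stats::cor on raw dosages)
dense_r2 <- function(panel) {
  suppressWarnings(stats::cor(panel$genotypes, use = "pairwise.complete.obs"))^2
}

# brute-force first cut: enumerate every admissible cut and every crossing
# pair within the window, first-wins tie break
brute_force_cut <- function(ld, start, min_size, max_size, end) {
  cands <- seq.int(start + min_size - 1L, min(start + max_size - 1L, end - 1L))
  mx <- vapply(cands, function(c_) {
    worst <- 0
    for (i in seq.int(start, c_)) {
      hi <- min(i + ld$window, end)
      if (hi > c_) {
        for (j in seq.int(c_ + 1L, hi)) {
          worst <- max(worst, ld_r2_at(ld, i, j))
        }
      }
    }
    worst
  }, numeric(1))
  list(cut = cands[which.min(mx)], boundary_max_r2 = min(mx))
}
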