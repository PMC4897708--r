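#' Choose a single block cut-point
#'
#' Evaluates every admissible cut `c` (block sizes between `min_size` and
#' `max_size` SNPs starting at `start`) and, for each, the maximal r-squared
#' over stored SNP pairs that straddle the boundary (pair `(i, j)` with
#' `start <= i <= c < j`, within the LD window; pairs beyond the window
#' contribute 0). Returns the cut minimizing that maximum; ties break to the
#' smallest cut index so partitions are deterministic.
#'
#' @param ld a [ld_windowed_r2()] result.
#' @param start first SNP index of the block being formed.
#' @param min_size,max_size admissible block size range in SNP count.
#' @param end last SNP index of the arm (defaults to the last SNP sharing
#'   `start`'s arm).
#' @return list with `cut` (index of the last SNP in the block) and
#'   `boundary_max_r2`.
#' @export
choose_cut_point <- function(ld, start, min_size, max_size, end = NULL) {
  stopifnot(inherits(ld, "largv_ld"))
  m <- nrow(ld$band)
  arm <- ld$snp_meta$arm %||% arm_labels(ld$snp_meta)
  if (is.null(end)) end <- max(which(arm == arm[start]))
  n_left <- end - start + 1L
  if (n_left < min_size) {
    abort("terminal block: fewer than min_size SNPs remain",
          class = "largv_terminal_block")
  }
  cands <- seq.int(start + min_size - 1L, min(start + max_size - 1L, end))
  cands <- cands[cands < end]  # a cut at the arm end is no cut
  if (length(cands) == 0) {
    return(list(cut = end, boundary_max_r2 = 0))
  }
  w <- ld$window
  # rev-cummax along each needed band row: rcm[i, j] = max_{j' >= j} band[i, j']
  rows <- seq.int(max(start, min(cands) - w + 1L), max(cands))
  b <- ld$band[rows, , drop = FALSE]
  b[is.na(b)] <- 0
  rcm <- b
  if (ncol(rcm) > 1) {
    for (j in rev(seq_len(ncol(rcm) - 1L))) {
      rcm[, j] <- pmax(rcm[, j], rcm[, j + 1L])
    }
  }
  best_cut <- NA_integer_
  best_max <- Inf
  for (c_ in cands) {
    i <- seq.int(max(start, c_ - w + 1L), c_)
    lag <- c_ + 1L - i
    v <- rcm[cbind(i - rows[1] + 1L, lag)]
    mx <- if (length(v)) max(v) else 0
    if (mx < best_max - 1e-15) {
      best_max <- mx
      best_cut <- c_
    }
  }
  list(cut = best_cut, boundary_max_r2 = if (is.finite(best_max)) best_max else 0)
}

#' Partition one chromosome arm into SNP blocks
#'
#' Applies [choose_cut_point()] greedily from the low-coordinate end of the
#' arm until every SNP is assigned. A leftover tail shorter than `min_size`
#' is merged into the final block, so the terminal block may exceed
#' `max_size` by fewer than `min_size` SNPs.
#'
#' @inheritParams choose_cut_point
#' @param arm_range integer vector `c(first, last)` SNP index of the arm.
#' @return tibble of blocks (`start_index`, `end_index`, `n_snps`,
#'   `boundary_max_r2`; the boundary value belongs to the boundary *after*
#'   the block, `NA` for the terminal block).
#' @export
partition_arm <- function(ld, arm_range, min_size, max_size) {
  stopifnot(inherits(ld, "largv_ld"), min_size >= 1, max_size >= min_size)
  first <- arm_range[1]; last <- arm_range[2]
  starts <- integer(0); ends <- integer(0); bmax <- numeric(0)
  s <- first
  repeat {
    remaining <- last - s + 1L
    if (remaining <= max_size) {
      if (remaining >= min_size || length(ends) == 0L) {
        starts <- c(starts, s); ends <- c(ends, last); bmax <- c(bmax, NA_real_)
      } else {
        # tail shorter than min_size: merge into the previous block
        ends[length(ends)] <- last
        bmax[length(bmax)] <- NA_real_
      }
      break
    }
    cp <- choose_cut_point(ld, s, min_size, max_size, end = last)
    starts <- c(starts, s); ends <- c(ends, cp$cut); bmax <- c(bmax, cp$boundary_max_r2)
    s <- cp$cut + 1L
  }
  tibble(start_index = starts, end_index = ends,
         n_snps = ends - starts + 1L, boundary_max_r2 = bmax)
}

#' Partition the genome into SNP blocks
#'
#' Runs the greedy minimal-cross-boundary-LD partitioner on every chromosome
#' arm of an LD object. Blocks are contiguous, non-overlapping, and jointly
#' exhaustive over the arm's SNPs.
#'
#' @inheritParams choose_cut_point
#' @param min_size,max_size admissible block sizes in SNPs (e.g. 85-95 for a
#'   median block of 90 SNPs, or 195-205 for larger blocks).
#' @return An object of class `block_partition`: list with `blocks` (tibble:
#'   `block_id`, `chrom`, `arm`, `start_index`, `end_index`, `start_bp`,
#'   `end_bp`, `n_snps`, `boundary_max_r2`), `snp_map` (tibble `snp_id`,
#'   `block_id`), and the size bounds.
#' @export
partition_blocks <- function(ld, min_size, max_size) {
  stopifnot(inherits(ld, "largv_ld"))
  meta <- ld$snp_meta
  arm <- meta$arm %||% arm_labels(meta)
  pieces <- list()
  for (a in unique(arm)) {
    idx <- which(arm == a)
    blk <- partition_arm(ld, c(min(idx), max(idx)), min_size, max_size)
    blk$chrom <- meta$chrom[idx[1]]
    blk$arm <- a
    pieces[[a]] <- blk
  }
  blocks <- bind_rows(pieces)
  blocks$block_id <- sprintf("block_%04d", seq_len(nrow(blocks)))
  blocks$start_bp <- meta$pos[blocks$start_index]
  blocks$end_bp <- meta$pos[blocks$end_index]
  blocks <- blocks[, c("block_id", "chrom", "arm", "start_index", "end_index",
                       "start_bp", "end_bp", "n_snps", "boundary_max_r2")]
  snp_map <- tibble(
    snp_id = meta$id,
    block_id = rep(blocks$block_id, blocks$n_snps)
  )
  structure(
    list(blocks = blocks, snp_map = snp_map,
         min_size = min_size, max_size = max_size),
    class = "block_partition"
  )
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d blocks over %d SNPs (sizes %d-%d%s)\n",
              nrow(x$blocks), nrow(x$snp_map), min(x$blocks$n_snps),
              max(x$blocks$n_snps),
              if (max(x$blocks$n_snps) > x$max_size) ", terminal merge" else ""))
  bmx <- x$blocks$boundary_max_r2
  if (any(!is.na(bmx))) {
    cat(sprintf("  boundary max r2: median %.3f, max %.3f\n",
                stats::median(bmx, na.rm = TRUE), max(bmx, na.rm = TRUE)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
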