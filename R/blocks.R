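# Cohort-wide genome segmentation at merged crossover breakpoints and the
# recombination-block genotype matrix with Mendelian segregation
# diagnostics.
#
# Crossover positions are snapped to a segmentation grid (default 10 kb,
# the mapping resolution) with half-up rounding before merging. A sample's
# snapped genotype path equals its original path evaluated at grid-cell
# midpoints with the strict-inequality convention (#{breakpoints < mid}),
# which is how blocks are filled; this makes the block matrix exactly
# consistent with the snapped breakpoints that delimit it.

#' Segment the genome at merged cohort breakpoints
#'
#' Block boundaries are `{0, chromosome length}` union all cohort
#' crossover positions snapped to the nearest grid multiple; duplicates
#' collapse. Blocks shorter than the grid (possible only at chromosome
#' ends when the length is not a grid multiple) are merged into their left
#' neighbor.
#'
#' @param crossovers Data frame with columns `sample`, `chrom`, `pos0`
#'   (from [call_crossovers()] or [true_crossovers()]).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param grid Segmentation grid in bp (default 10000).
#' @return A `block_set`: data frame `chrom`, `start`, `end`, `block_id`
#'   (0-based half-open intervals exactly tiling each chromosome), with
#'   `grid` and `chrom_lengths` attributes.
#' @export
segment_genome <- function(crossovers, chrom_lengths, grid = 10000) {
  check_scalar_number(grid, "grid", lower = 0, strict_lower = TRUE)
  if (nrow(crossovers)) {
    if (any(!crossovers$chrom %in% names(chrom_lengths))) {
      stopf("invalid-argument: crossovers on unknown chromosomes")
    }
    if (any(crossovers$pos0 < 0) ||
        any(crossovers$pos0 > chrom_lengths[crossovers$chrom])) {
      stopf("invalid-argument: breakpoints outside chromosome bounds")
    }
  }
  res <- list()
  for (cn in names(chrom_lengths)) {
    len <- chrom_lengths[[cn]]
    bp <- crossovers$pos0[crossovers$chrom == cn]
    snapped <- snap_to_grid(bp, grid)
    snapped <- snapped[snapped > 0 & snapped < len]
    bounds <- sort(unique(c(0, snapped, len)))
    repeat {
      lens_b <- diff(bounds)
      small <- which(lens_b < grid)
      if (!length(small) || length(bounds) <= 2L) break
      i <- small[1L]
      bounds <- bounds[-(if (i == 1L) 2L else i)]
    }
    start <- bounds[-length(bounds)]
    end <- bounds[-1L]
    res[[cn]] <- data.frame(chrom = cn, start = start, end = end,
                            block_id = sprintf("%s:%d-%d", cn, as.integer(start),
                                               as.integer(end)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  structure(out, grid = grid, chrom_lengths = chrom_lengths,
            class = c("block_set", "data.frame"))
}

# State of each grid cell for one decoded (or true) path, defined as the
# path state at the cell midpoint with breakpoints counted strictly before
# the midpoint. `bp` are state-change positions, `states` the run states
# (length(bp) + 1).
cell_states <- function(bp, states, len, grid) {
  ncell <- ceiling(len / grid)
  j <- seq_len(ncell) - 1
  mid <- pmin((j + 0.5) * grid, (j * grid + len) / 2)
  states[findInterval(mid, bp, left.open = TRUE) + 1L]
}

#' Fill the recombination-block genotype matrix
#'
#' Assigns each (individual, block) cell the individual's snapped-path
#' state over the block. If a block straddles a state change of some
#' individual (impossible when blocks were segmented from the same
#' crossover calls on grid-multiple chromosomes) an internal-consistency
#' error is raised.
#'
#' @param blocks A `block_set` from [segment_genome()].
#' @param paths A `genotype_paths` object covering the same cohort.
#' @return A `genotype_matrix`: the block table plus a
#'   blocks-by-individuals integer state matrix (1/2/3 = AA/AB/BB). Use
#'   [geno_dosage()] for the additive 2/1/0 dosage view.
#' @export
fill_genotype_matrix <- function(blocks, paths) {
  if (!inherits(blocks, "block_set")) stopf("invalid-argument: not a block_set")
  if (!inherits(paths, "genotype_paths")) stopf("invalid-argument: not a genotype_paths object")
  grid <- attr(blocks, "grid")
  lens <- attr(blocks, "chrom_lengths")
  states <- matrix(NA_integer_, nrow(blocks), length(paths$samples),
                   dimnames = list(blocks$block_id, paths$samples))
  for (cn in names(lens)) {
    brows <- which(blocks$chrom == cn)
    wrows <- which(paths$windows$chrom == cn)
    if (!length(brows) || !length(wrows)) next
    len <- lens[[cn]]
    starts <- paths$windows$start[wrows]
    bstart <- blocks$start[brows]
    first_cell <- bstart %/% grid + 1L
    boundary_set <- c(bstart, len)
    for (j in seq_along(paths$samples)) {
      st <- paths$states[wrows, j]
      chg <- which(diff(st) != 0L)
      bp <- starts[chg + 1L]
      runs <- st[c(1L, chg + 1L)]
      cs <- cell_states(bp, runs, len, grid)
      chgcell <- which(diff(cs) != 0L)
      if (length(chgcell) && !all((chgcell * grid) %in% boundary_set)) {
        stopf("internal-consistency error: block straddles a state change (sample %s, %s)",
              paths$samples[j], cn)
      }
      states[brows, j] <- cs[first_cell]
    }
  }
  structure(list(blocks = as.data.frame(blocks), states = states,
                 samples = paths$samples, grid = grid, chrom_lengths = lens),
            class = "genotype_matrix")
}

#' Block genotype matrix directly from simulation truth
#'
#' Segments the genome at the cohort's true genotype-visible crossovers and
#' fills the matrix from the true gamete mosaics, bypassing sequencing and
#' HMM decoding. Useful for studying the association stage in isolation.
#'
#' @param truth An `f2_truth`.
#' @param grid Segmentation grid in bp.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix_from_truth <- function(truth, grid = 10000) {
  xo <- true_crossovers(truth)
  blocks <- segment_genome(xo, truth$chrom_lengths, grid)
  states <- matrix(NA_integer_, nrow(blocks), length(truth$samples),
                   dimnames = list(blocks$block_id, truth$samples))
  for (cn in names(truth$chrom_lengths)) {
    brows <- which(blocks$chrom == cn)
    if (!length(brows)) next
    mid <- pmin(blocks$start[brows] + grid / 2,
                (blocks$start[brows] + blocks$end[brows]) / 2)
    states[brows, ] <- 3L - true_genotype_at(truth, cn, mid)
  }
  structure(list(blocks = as.data.frame(blocks), states = states,
                 samples = truth$samples, grid = grid,
                 chrom_lengths = truth$chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$blocks), "blocks x", length(x$samples),
      "individuals (grid", x$grid, "bp)\n")
  invisible(x)
}

#' Additive dosage view of a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @return Integer matrix of A-allele counts (AA = 2, AB = 1, BB = 0).
#' @export
geno_dosage <- function(gm) {
  d <- 3L - gm$states
  dimnames(d) <- dimnames(gm$states)
  d
}

#' Re-expand a block matrix onto a window tiling
#'
#' Inverse of the segmentation: every window takes the state of the block
#' containing its start. When all crossovers lie on the segmentation grid
#' and the grid equals the window size, this reproduces the decoded window
#' paths exactly.
#'
#' @param gm A `genotype_matrix`.
#' @param window_size Window size in bp.
#' @return List with `windows` data frame and `states` matrix.
#' @export
expand_blocks_to_windows <- function(gm, window_size) {
  lens <- gm$chrom_lengths
  win_list <- list(); st_list <- list()
  for (cn in names(lens)) {
    len <- lens[[cn]]
    nwin <- ceiling(len / window_size)
    start <- (seq_len(nwin) - 1) * window_size
    brows <- which(gm$blocks$chrom == cn)
    idx <- findInterval(start, gm$blocks$start[brows])
    win_list[[cn]] <- data.frame(chrom = cn, win = seq_len(nwin) - 1L,
                                 start = start,
                                 end = pmin(start + window_size, len),
                                 stringsAsFactors = FALSE)
    st_list[[cn]] <- gm$states[brows[idx], , drop = FALSE]
  }
  list(windows = do.call(rbind, c(win_list, list(make.row.names = FALSE))),
       states = do.call(rbind, st_list))
}

#' Mendelian segregation diagnostics per block
#'
#' Per block, tests the AA:AB:BB counts against the Mendelian 1:2:1
#' expectation with a 2-df chi-square and reports genotype fractions; the
#' cohort-wide AA excess (mean over blocks of the AA fraction minus 0.25)
#' summarizes reference bias.
#'
#' @param gm A `genotype_matrix` with at least one individual.
#' @return A `segregation_report` data frame (`block_id`, `chrom`, `start`,
#'   `end`, `n_AA`, `n_AB`, `n_BB`, `frac_AA`, `frac_AB`, `frac_BB`,
#'   `chisq`, `p`) with an `aa_excess` attribute.
#' @export
segregation_diagnostics <- function(gm) {
  n <- length(gm$samples)
  if (n < 1L) stopf("invalid-argument: need at least one individual")
  cnt <- t(apply(gm$states, 1L, tabulate, nbins = 3L))
  expected <- n * c(0.25, 0.5, 0.25)
  chisq <- rowSums(sweep(cnt, 2L, expected)^2 / rep(expected, each = nrow(cnt)))
  frac <- cnt / n
  out <- data.frame(block_id = gm$blocks$block_id, chrom = gm$blocks$chrom,
                    start = gm$blocks$start, end = gm$blocks$end,
                    n_AA = cnt[, 1L], n_AB = cnt[, 2L], n_BB = cnt[, 3L],
                    frac_AA = frac[, 1L], frac_AB = frac[, 2L],
                    frac_BB = frac[, 3L],
                    chisq = chisq,
                    p = pchisq(chisq, df = 2L, lower.tail = FALSE),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, aa_excess = mean(frac[, 1L]) - 0.25, n = n,
            class = c("segregation_report", "data.frame"))
}
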