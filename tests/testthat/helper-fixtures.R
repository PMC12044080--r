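# Shared fixtures and independent oracles, built in code at test time.

# Small one- or two-chromosome genome specs used across tests.
tiny_spec <- function(...) {
  genome_spec(chromosomes = c(chr1 = 1e6), marker_density = 1 / 1000,
              coverage = 0.78, read_error = 0.01, ref_bias = 0,
              crossover_rate = 1.5, ...)
}

# Hand-built allele_counts object (markers x samples count matrices).
make_counts <- function(chrom, pos0, nA, nB, chrom_lengths,
                        samples = paste0("S", seq_len(ncol(nA)))) {
  markers <- structure(
    data.frame(chrom = chrom, pos0 = pos0,
               allele_A = rep("A", length(pos0)),
               allele_B = rep("G", length(pos0)), stringsAsFactors = FALSE),
    chrom_lengths = chrom_lengths, class = c("marker_set", "data.frame"))
  dimnames(nA) <- dimnames(nB) <- list(NULL, samples)
  structure(list(markers = markers, samples = samples,
                 nA = nA, nB = nB, chrom_lengths = chrom_lengths),
            class = "allele_counts")
}

# Hand-built genotype_paths object from a windows-by-samples state matrix.
make_paths <- function(states, chrom_lengths, window_size = 5000,
                       samples = paste0("S", seq_len(ncol(states)))) {
  win_list <- lapply(names(chrom_lengths), function(cn) {
    nwin <- ceiling(chrom_lengths[[cn]] / window_size)
    start <- (seq_len(nwin) - 1) * window_size
    data.frame(chrom = cn, win = seq_len(nwin) - 1L, start = start,
               end = pmin(start + window_size, chrom_lengths[[cn]]),
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, c(win_list, list(make.row.names = FALSE)))
  stopifnot(nrow(windows) == nrow(states))
  dimnames(states) <- list(NULL, samples)
  logp <- expand.grid(sample = samples, chrom = names(chrom_lengths),
                      stringsAsFactors = FALSE)
  logp$logp <- 0
  structure(list(windows = windows, states = states, samples = samples,
                 logp = logp, window_size = window_size,
                 chrom_lengths = chrom_lengths),
            class = "genotype_paths")
}

# Hand-built genotype_matrix from a blocks-by-samples dosage matrix.
make_gm <- function(blocks_df, dosage, chrom_lengths, grid = 10000,
                    samples = paste0("S", seq_len(ncol(dosage)))) {
  states <- 3L - dosage
  dimnames(states) <- list(blocks_df$block_id, samples)
  structure(list(blocks = blocks_df, states = states, samples = samples,
                 grid = grid, chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

make_blocks_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             block_id = sprintf("%s:%d-%d", chrom, as.integer(start),
                                as.integer(end)),
             stringsAsFactors = FALSE)
}

# Hand-built fdr_thresholds fixture.
make_thresholds <- function(p05, p01 = p05 / 10, phenotype = "trait") {
  structure(data.frame(level = c(0.01, 0.05), p_threshold = c(p01, p05),
                       neg_log10_p = -log10(c(p01, p05))),
            n_perm = 1L, seed = 1L, phenotype = phenotype,
            class = c("fdr_thresholds", "data.frame"))
}

# Independent exhaustive Viterbi oracle: scores every one of the 3^T state
# paths directly from the model definition (binomial emissions, two-gamete
# F2 transitions) and returns the maximum joint log-likelihood.
brute_force_viterbi <- function(nA, nB, e, r, init = c(0.25, 0.5, 0.25)) {
  T <- length(nA)
  pA <- c(1 - e, 0.5, e)
  trans <- matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
                    r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
                    r^2, 2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE)
  emis <- function(t, s) {
    tot <- nA[t] + nB[t]
    if (tot == 0) 0 else dbinom(nA[t], tot, pA[s], log = TRUE)
  }
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  scores <- apply(paths, 1L, function(p) {
    sc <- log(init[p[1L]]) + emis(1L, p[1L])
    for (t in seq_len(T - 1L)) {
      sc <- sc + log(trans[p[t], p[t + 1L]]) + emis(t + 1L, p[t + 1L])
    }
    sc
  })
  list(logp = max(scores), path = paths[which.max(scores), ])
}
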