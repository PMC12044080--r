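# Windowed observation building and three-state HMM genotype decoding.
#
# Observations are per-window allele-count sums over the marker set; the
# hidden chain is the diploid genotype (AA, AB, BB) with transitions given
# by the two-gamete F2 model at per-window recombination fraction r.

#' HMM parameters for F2 genotype decoding
#'
#' @param window_size Window size in bp (default 5000, the standard
#'   aggregation scale for ultra-low-coverage intercross genotyping).
#' @param error Emission error `e` in `[0, 0.5)`: the probability that a
#'   read drawn from a homozygous window supports the other founder allele,
#'   so `pA` is `1 - e`, `0.5`, `e` for AA, AB, BB.
#' @param init Initial state distribution over (AA, AB, BB); the Mendelian
#'   prior `(1/4, 1/2, 1/4)` by default.
#' @param recomb Per-window recombination fraction `r` per gamete. If
#'   `NULL`, derived per chromosome as
#'   `crossover_rate * window_size / chromosome_length`. Clamped to
#'   `[1e-9, 0.5 - 1e-9]`.
#' @param crossover_rate Expected crossovers per gamete per chromosome,
#'   used only when `recomb` is `NULL`.
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(window_size = 5000,
                       error = 0.02,
                       init = c(0.25, 0.5, 0.25),
                       recomb = NULL,
                       crossover_rate = NULL) {
  check_scalar_number(window_size, "window_size", lower = 0, strict_lower = TRUE)
  check_scalar_number(error, "error", lower = 0, upper = 0.5, strict_upper = TRUE)
  if (length(init) != 3L || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stopf("invalid-spec: 'init' must be three non-negative probabilities summing to 1")
  }
  if (!is.null(recomb)) {
    check_scalar_number(recomb, "recomb", lower = 0, upper = 0.5, strict_upper = TRUE)
  }
  if (is.null(recomb) && is.null(crossover_rate)) {
    stopf("invalid-spec: give either 'recomb' or 'crossover_rate'")
  }
  structure(list(window_size = window_size, error = error, init = init,
                 recomb = recomb, crossover_rate = crossover_rate),
            class = "hmm_params")
}

clamp_recomb <- function(r) pmin(pmax(r, 1e-9), 0.5 - 1e-9)

# F2 two-gamete transition matrix between adjacent windows at per-gamete
# recombination fraction r (rows = from AA/AB/BB, columns = to).
f2_transition_matrix <- function(r) {
  r <- clamp_recomb(r)
  matrix(c((1 - r)^2,      2 * r * (1 - r), r^2,
           r * (1 - r),    (1 - r)^2 + r^2, r * (1 - r),
           r^2,            2 * r * (1 - r), (1 - r)^2),
         nrow = 3L, byrow = TRUE, dimnames = list(GENO_STATES, GENO_STATES))
}

#' Aggregate per-marker allele counts into fixed windows
#'
#' Windows tile each chromosome as 0-based half-open intervals
#' `[k*w, (k+1)*w)` (the terminal window is truncated at the chromosome
#' end); marker counts are assigned by position and summed, conserving
#' totals exactly.
#'
#' @param counts An `allele_counts` object.
#' @param window_size Window size in bp.
#' @return A `window_obs` object: window table (`chrom`, `win`, `start`,
#'   `end`) plus windows-by-individuals `nA`/`nB` matrices. The A-read
#'   proportion of a window is `nA/(nA+nB)`, undefined for empty windows.
#' @export
aggregate_windows <- function(counts, window_size = 5000) {
  if (!inherits(counts, "allele_counts")) stopf("invalid-argument: not an allele_counts object")
  check_scalar_number(window_size, "window_size", lower = 0, strict_lower = TRUE)
  lens <- counts$chrom_lengths
  markers <- counts$markers
  if (any(!markers$chrom %in% names(lens))) {
    stopf("consistency error: counts reference markers on unknown chromosomes")
  }
  if (any(markers$pos0 < 0) ||
      any(markers$pos0 >= lens[markers$chrom])) {
    stopf("consistency error: marker positions outside chromosome bounds")
  }
  win_list <- list(); nA_list <- list(); nB_list <- list()
  for (cn in names(lens)) {
    len <- lens[[cn]]
    nwin <- as.integer(ceiling(len / window_size))
    start <- (seq_len(nwin) - 1) * window_size
    rows <- which(markers$chrom == cn)
    widx <- factor(markers$pos0[rows] %/% window_size, levels = 0:(nwin - 1L))
    sum_by_window <- function(m) {
      out <- rowsum(m[rows, , drop = FALSE], group = widx)
      full <- matrix(0L, nwin, length(counts$samples),
                     dimnames = list(NULL, counts$samples))
      full[as.integer(rownames(out)) + 1L, ] <- as.integer(out)
      full
    }
    win_list[[cn]] <- data.frame(chrom = cn, win = seq_len(nwin) - 1L,
                                 start = start, end = pmin(start + window_size, len),
                                 stringsAsFactors = FALSE)
    nA_list[[cn]] <- sum_by_window(counts$nA)
    nB_list[[cn]] <- sum_by_window(counts$nB)
  }
  structure(list(windows = do.call(rbind, c(win_list, list(make.row.names = FALSE))),
                 nA = do.call(rbind, nA_list),
                 nB = do.call(rbind, nB_list),
                 samples = counts$samples,
                 chrom_lengths = lens,
                 window_size = window_size),
            class = "window_obs")
}

#' @export
print.window_obs <- function(x, ...) {
  cat("window_obs:", nrow(x$windows), "windows of", x$window_size, "bp x",
      length(x$samples), "individuals\n")
  invisible(x)
}

#' Decode genotype paths with the three-state Viterbi algorithm
#'
#' Computes, per individual and chromosome, the maximum-probability
#' AA/AB/BB state path under binomial emissions on the raw window counts
#' (`pA` = `1-e`, `0.5`, `e`) and the two-gamete F2 transition model;
#' empty windows emit likelihood one for all states and are decoded rather
#' than dropped, so paths remain coordinate-addressable. Computation is in
#' log space; exact score ties prefer the same-state predecessor so no
#' spurious crossover is introduced.
#'
#' @param obs A `window_obs` from [aggregate_windows()].
#' @param params An [hmm_params()].
#' @return A `genotype_paths` object: the window table, a
#'   windows-by-individuals integer state matrix (1/2/3 = AA/AB/BB) and a
#'   per-(sample, chromosome) table of decoded joint log-probabilities.
#' @export
viterbi_decode <- function(obs, params) {
  if (!inherits(obs, "window_obs")) stopf("invalid-argument: not a window_obs object")
  if (!inherits(params, "hmm_params")) stopf("invalid-argument: not an hmm_params object")
  if (nrow(obs$windows) == 0L) stopf("invalid-argument: empty observation sequence")
  e <- params$error
  pA <- c(1 - e, 0.5, e)
  log_init <- log(params$init)
  lens <- obs$chrom_lengths
  states <- matrix(NA_integer_, nrow(obs$windows), length(obs$samples),
                   dimnames = list(NULL, obs$samples))
  logp <- list()
  for (cn in names(lens)) {
    rows <- which(obs$windows$chrom == cn)
    if (!length(rows)) next
    r <- if (!is.null(params$recomb)) params$recomb else
      params$crossover_rate * obs$window_size / lens[[cn]]
    lt <- log(f2_transition_matrix(r))
    lp <- numeric(length(obs$samples))
    for (j in seq_along(obs$samples)) {
      dec <- .viterbi_core(obs$nA[rows, j], obs$nB[rows, j], pA, log_init, lt)
      states[rows, j] <- dec$path
      lp[j] <- dec$logp
    }
    logp[[cn]] <- data.frame(sample = obs$samples, chrom = cn, logp = lp,
                             stringsAsFactors = FALSE)
  }
  structure(list(windows = obs$windows, states = states,
                 samples = obs$samples,
                 logp = do.call(rbind, c(logp, list(make.row.names = FALSE))),
                 window_size = obs$window_size,
                 chrom_lengths = lens),
            class = "genotype_paths")
}

#' @export
print.genotype_paths <- function(x, ...) {
  cat("genotype_paths:", nrow(x$windows), "windows x", length(x$samples),
      "individuals (window", x$window_size, "bp)\n")
  invisible(x)
}

#' Call crossovers from decoded genotype paths
#'
#' Emits one call per adjacent state change of each individual's path; the
#' breakpoint is the shared boundary of the two windows. Direct AA-BB
#' changes carry step distance 2 (a double crossover within one window
#' span) and are flagged.
#'
#' @param paths A `genotype_paths` object.
#' @return Data frame `sample`, `chrom`, `pos0` (window boundary),
#'   `from`, `to`, `distance`, `double_crossover`.
#' @export
call_crossovers <- function(paths) {
  if (!inherits(paths, "genotype_paths")) stopf("invalid-argument: not a genotype_paths object")
  res <- list()
  for (cn in unique(paths$windows$chrom)) {
    rows <- which(paths$windows$chrom == cn)
    starts <- paths$windows$start[rows]
    for (j in seq_along(paths$samples)) {
      st <- paths$states[rows, j]
      chg <- which(diff(st) != 0L)
      if (!length(chg)) next
      res[[length(res) + 1L]] <- data.frame(
        sample = paths$samples[j], chrom = cn,
        pos0 = starts[chg + 1L],
        from = GENO_STATES[st[chg]], to = GENO_STATES[st[chg + 1L]],
        distance = abs(st[chg + 1L] - st[chg]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(sample = character(), chrom = character(), pos0 = numeric(),
               from = character(), to = character(), distance = integer(),
               stringsAsFactors = FALSE)
  out$double_crossover <- out$distance == 2L
  rownames(out) <- NULL
  out
}
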