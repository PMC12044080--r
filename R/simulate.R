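# Forward simulation of an F2 intercross of two inbred founders:
# marker maps, gametes with Poisson crossovers, low-coverage allele counts
# with optional reference bias, and multi-temperature phenotypes with
# planted QTLs. Everything is truth-labelled for downstream validation.

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate a homozygous-divergent marker map
#'
#' Draws a Poisson number of markers per chromosome (mean
#' `length * marker_density`), placed uniformly without replacement at
#' integer 0-based positions. Each marker is biallelic with distinct
#' founder alleles: allele B is the reference-strain base, allele A the
#' alternate founder base, so every F2 genotype is unambiguous given reads.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; identical seeds give identical maps.
#' @return A `marker_set`: data frame with columns `chrom`, `pos0`
#'   (0-based), `allele_A`, `allele_B`, carrying a `chrom_lengths`
#'   attribute.
#' @export
simulate_marker_map <- function(spec, seed = NULL) {
  if (!inherits(spec, "genome_spec")) stopf("invalid-spec: not a genome_spec")
  with_seed(seed, {
    per_chrom <- lapply(names(spec$chromosomes), function(cn) {
      len <- spec$chromosomes[[cn]]
      m <- rpois(1L, len * spec$marker_density)
      m <- min(m, len)
      pos <- sort(sample.int(len, m)) - 1L
      ref <- sample(DNA_BASES, m, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      data.frame(chrom = rep(cn, m), pos0 = pos,
                 allele_A = unname(alt), allele_B = ref,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    markers <- do.call(rbind, per_chrom)
    rownames(markers) <- NULL
    structure(markers,
              chrom_lengths = spec$chromosomes,
              class = c("marker_set", "data.frame"))
  })
}

new_gamete <- function(len, crossover_rate) {
  k <- rpois(1L, crossover_rate)
  bp <- sort(runif(k, 0, len))
  first <- sample.int(2L, 1L) - 1L  # 1 = founder A haplotype, 0 = founder B
  list(bp = bp, first = first)
}

gamete_allele <- function(gamete, pos) {
  (gamete$first + findInterval(pos, gamete$bp)) %% 2L
}

#' Simulate an F2 cohort with recorded crossovers
#'
#' Each F2 individual is the union of two independent gametes; each gamete
#' is a mosaic of the two founder haplotypes with a Poisson number of
#' crossovers (mean `spec$crossover_rate`) placed uniformly along each
#' chromosome, i.e. one cycle of meiotic recombination without
#' interference (Haldane-consistent).
#'
#' @param markers A `marker_set` from [simulate_marker_map()].
#' @param n Number of F2 individuals (>= 1).
#' @param spec The [genome_spec()] used for the cross.
#' @param seed Integer seed.
#' @return An `f2_truth` object: sample names, the marker set, a
#'   markers-by-individuals integer dosage matrix (count of A alleles,
#'   2/1/0 for AA/AB/BB), and the two gamete mosaics (breakpoint lists)
#'   per individual.
#' @export
simulate_f2_cohort <- function(markers, n, spec, seed = NULL) {
  if (!inherits(markers, "marker_set")) stopf("invalid-argument: 'markers' is not a marker_set")
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stopf("invalid-argument: 'n' must be >= 1")
  }
  n <- as.integer(n)
  lens <- chrom_lengths_of(markers)
  with_seed(seed, {
    samples <- sprintf("F2_%04d", seq_len(n))
    geno <- matrix(0L, nrow = nrow(markers), ncol = n,
                   dimnames = list(NULL, samples))
    gametes <- vector("list", n)
    names(gametes) <- samples
    chrom_rows <- split(seq_len(nrow(markers)), factor(markers$chrom, levels = names(lens)))
    for (i in seq_len(n)) {
      per_chrom <- vector("list", length(lens))
      names(per_chrom) <- names(lens)
      for (cn in names(lens)) {
        g1 <- new_gamete(lens[[cn]], spec$crossover_rate)
        g2 <- new_gamete(lens[[cn]], spec$crossover_rate)
        rows <- chrom_rows[[cn]]
        if (length(rows)) {
          pos <- markers$pos0[rows]
          geno[rows, i] <- gamete_allele(g1, pos) + gamete_allele(g2, pos)
        }
        per_chrom[[cn]] <- list(g1 = g1, g2 = g2)
      }
      gametes[[i]] <- per_chrom
    }
    structure(
      list(samples = samples, markers = markers, geno = geno,
           gametes = gametes, chrom_lengths = lens),
      class = "f2_truth"
    )
  })
}

#' @export
print.f2_truth <- function(x, ...) {
  cat("f2_truth:", length(x$samples), "individuals,",
      nrow(x$markers), "markers,",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' True genotype dosages at arbitrary positions
#'
#' Evaluates each individual's genotype (A-allele dosage 0/1/2) at the given
#' genomic positions directly from the stored gamete mosaics, independently
#' of the marker set.
#'
#' @param truth An `f2_truth`.
#' @param chrom Chromosome name (scalar).
#' @param pos0 Numeric vector of 0-based positions.
#' @return Integer matrix, `length(pos0)` rows by individuals.
#' @export
true_genotype_at <- function(truth, chrom, pos0) {
  if (!chrom %in% names(truth$chrom_lengths)) stopf("unknown chromosome '%s'", chrom)
  out <- vapply(truth$gametes, function(g) {
    gamete_allele(g[[chrom]]$g1, pos0) + gamete_allele(g[[chrom]]$g2, pos0)
  }, integer(length(pos0)))
  matrix(as.integer(out), nrow = length(pos0),
         dimnames = list(NULL, truth$samples))
}

#' True crossover breakpoints as genotype-state transitions
#'
#' Merges each individual's two gamete breakpoint lists and reports every
#' position where the diploid genotype state changes (breakpoints where the
#' two gametes exchange complementary alleles leave the diploid state
#' unchanged and are not genotype-visible).
#'
#' @param truth An `f2_truth`.
#' @return Data frame `sample`, `chrom`, `pos0`, `from`, `to` (state
#'   labels), sorted by sample then position.
#' @export
true_crossovers <- function(truth) {
  res <- list()
  for (s in truth$samples) {
    for (cn in names(truth$chrom_lengths)) {
      g <- truth$gametes[[s]][[cn]]
      bp <- sort(unique(c(g$g1$bp, g$g2$bp)))
      if (!length(bp)) next
      # evaluate dosage on each side of every breakpoint
      probe <- c(0, bp + 1e-9)
      dos <- gamete_allele(g$g1, probe) + gamete_allele(g$g2, probe)
      chg <- which(diff(dos) != 0L)
      if (!length(chg)) next
      res[[length(res) + 1L]] <- data.frame(
        sample = s, chrom = cn, pos0 = bp[chg],
        from = GENO_STATES[3L - dos[chg]],
        to = GENO_STATES[3L - dos[chg + 1L]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(sample = character(), chrom = character(),
                      pos0 = numeric(), from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' True genotype states on a window tiling
#'
#' Evaluates the cohort's true genotype state at every window midpoint and
#' flags windows whose interval contains a genotype-visible breakpoint
#' (their single-state label is ambiguous). Used to score decoded paths
#' against the simulation truth.
#'
#' @param truth An `f2_truth`.
#' @param window_size Window size in bp.
#' @return List with `windows` (data frame `chrom`, `win`, `start`, `end`),
#'   `states` (windows-by-individuals integer matrix, 1/2/3 = AA/AB/BB) and
#'   `has_breakpoint` (logical matrix of the same shape).
#' @export
true_window_states <- function(truth, window_size = 5000) {
  lens <- truth$chrom_lengths
  xo <- true_crossovers(truth)
  win_list <- list(); st_list <- list(); bp_list <- list()
  for (cn in names(lens)) {
    len <- lens[[cn]]
    nwin <- ceiling(len / window_size)
    start <- (seq_len(nwin) - 1L) * window_size
    end <- pmin(start + window_size, len)
    mid <- (start + end) / 2
    dos <- true_genotype_at(truth, cn, mid)
    st <- matrix(3L - dos, nrow = nwin, dimnames = dimnames(dos))
    hb <- matrix(FALSE, nrow = nwin, ncol = length(truth$samples),
                 dimnames = list(NULL, truth$samples))
    xoc <- xo[xo$chrom == cn, , drop = FALSE]
    if (nrow(xoc)) {
      widx <- pmin(floor(xoc$pos0 / window_size) + 1L, nwin)
      hb[cbind(widx, match(xoc$sample, truth$samples))] <- TRUE
    }
    win_list[[cn]] <- data.frame(chrom = cn, win = seq_len(nwin) - 1L,
                                 start = start, end = end,
                                 stringsAsFactors = FALSE)
    st_list[[cn]] <- st
    bp_list[[cn]] <- hb
  }
  list(windows = do.call(rbind, c(win_list, list(make.row.names = FALSE))),
       states = do.call(rbind, st_list),
       has_breakpoint = do.call(rbind, bp_list))
}

#' Simulate low-coverage allele counts
#'
#' Per marker and individual, sequencing depth is Poisson with mean
#' `spec$coverage`; each read independently supports allele A with
#' probability `clamp(base + delta, 0, 1)` where `base` is `1 - read_error`
#' for AA, `0.5` for AB and `read_error` for BB genotypes, and `delta` is
#' the reference-bias shift `spec$ref_bias`. A positive `delta` produces the
#' over-representation of AA calls typical of reference bias.
#'
#' @param truth An `f2_truth` covering all markers.
#' @param markers The `marker_set` (defaults to the truth's own markers).
#' @param spec The [genome_spec()].
#' @param seed Integer seed.
#' @return An `allele_counts` object: marker table, sample names, and two
#'   markers-by-individuals integer matrices `nA`, `nB`.
#' @export
simulate_allele_counts <- function(truth, markers = truth$markers, spec,
                                   seed = NULL) {
  if (!inherits(truth, "f2_truth")) stopf("invalid-argument: 'truth' is not an f2_truth")
  if (!identical(dim(truth$geno)[1], nrow(markers))) {
    stopf("invalid-argument: truth does not cover the marker set")
  }
  with_seed(seed, {
    m <- nrow(markers); n <- length(truth$samples)
    depth <- matrix(rpois(m * n, spec$coverage), nrow = m)
    base <- c(spec$read_error, 0.5, 1 - spec$read_error)  # dosage 0,1,2
    pA <- pmin(pmax(base[truth$geno + 1L] + spec$ref_bias, 0), 1)
    nA <- matrix(rbinom(m * n, depth, pA), nrow = m,
                 dimnames = list(NULL, truth$samples))
    nB <- depth - nA
    dimnames(nB) <- dimnames(nA)
    structure(list(markers = markers, samples = truth$samples,
                   nA = nA, nB = nB,
                   chrom_lengths = chrom_lengths_of(markers)),
              class = "allele_counts")
  })
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", nrow(x$markers), "markers x",
      length(x$samples), "individuals; mean depth",
      fmt_num(mean(x$nA + x$nB)), "\n")
  invisible(x)
}

#' Specify planted QTLs
#'
#' @param chrom Chromosome name per QTL.
#' @param pos0 0-based position per QTL.
#' @param additive Additive effect in bpm per A allele: a vector of length 3
#'   (one per assay temperature 21/28/35 C) per QTL, or a scalar recycled
#'   across temperatures. For several QTLs pass a matrix with 3 columns.
#' @param dominance Dominance deviation in bpm for heterozygotes; same
#'   recycling rules.
#' @return A `qtl_spec` data frame with columns `chrom`, `pos0`,
#'   `a_21`, `a_28`, `a_35`, `d_21`, `d_28`, `d_35`.
#' @export
qtl_spec <- function(chrom, pos0, additive, dominance = 0) {
  k <- length(chrom)
  expand <- function(x) {
    if (is.matrix(x)) {
      if (nrow(x) != k || ncol(x) != 3L) stopf("invalid-spec: effect matrix must be k x 3")
      return(x)
    }
    if (length(x) == 1L) return(matrix(x, k, 3L))
    if (length(x) == 3L && k == 1L) return(matrix(x, 1L, 3L, byrow = TRUE))
    if (length(x) == k) return(matrix(x, k, 3L))
    stopf("invalid-spec: cannot recycle effects of length %d to %d QTLs", length(x), k)
  }
  a <- expand(additive); d <- expand(dominance)
  if (any(!is.finite(a)) || any(!is.finite(d))) stopf("invalid-spec: QTL effects must be finite")
  structure(data.frame(chrom = chrom, pos0 = pos0,
                       a_21 = a[, 1], a_28 = a[, 2], a_35 = a[, 3],
                       d_21 = d[, 1], d_28 = d[, 2], d_35 = d[, 3],
                       stringsAsFactors = FALSE),
            class = c("qtl_spec", "data.frame"))
}

#' QTL genotype dosages for a cohort
#'
#' @param truth An `f2_truth`.
#' @param qtls A [qtl_spec()].
#' @return Integer matrix, QTLs by individuals, of A-allele dosages.
#' @export
qtl_genotypes <- function(truth, qtls) {
  if (is.null(qtls) || nrow(qtls) == 0L) {
    return(matrix(integer(0), 0L, length(truth$samples),
                  dimnames = list(NULL, truth$samples)))
  }
  out <- matrix(0L, nrow(qtls), length(truth$samples),
                dimnames = list(NULL, truth$samples))
  for (q in seq_len(nrow(qtls))) {
    if (qtls$pos0[q] < 0 || qtls$pos0[q] >= truth$chrom_lengths[[qtls$chrom[q]]]) {
      stopf("invalid-spec: QTL %d lies outside chromosome '%s'", q, qtls$chrom[q])
    }
    out[q, ] <- true_genotype_at(truth, qtls$chrom[q], qtls$pos0[q])[1L, ]
  }
  out
}

#' Simulate multi-temperature heart-rate phenotypes
#'
#' The latent heart rate of individual i at temperature t is
#' `baseline(t) + sum_q a_q(t) * dosage_i(q) + d_q(t) * het_i(q) + N(0, noise_sd)`.
#' With probability `arrhythmia_rate` an individual shows 2:1
#' atrioventricular conduction: its recorded rate at every temperature is
#' the latent rate times `arrhythmia_ratio` (default one half) and the
#' arrhythmia flag is set.
#'
#' @param truth An `f2_truth`.
#' @param qtls Optional [qtl_spec()] of planted QTLs.
#' @param baselines Positive baseline rates in bpm at 21/28/35 C.
#' @param noise_sd Residual (polygenic + measurement) SD in bpm; >= 0.
#' @param arrhythmia_rate Probability of the arrhythmia outlier state.
#' @param arrhythmia_ratio Recorded/latent ratio for arrhythmic individuals.
#' @param seed Integer seed.
#' @return A `phenotype_table` data frame: `sample`, `hr21`, `hr28`,
#'   `hr35`, `arrhythmia` (logical), with the latent rates as a `latent`
#'   attribute (individuals by temperatures matrix).
#' @export
simulate_phenotypes <- function(truth, qtls = NULL,
                                baselines = c(hr21 = 90, hr28 = 130, hr35 = 170),
                                noise_sd = 10,
                                arrhythmia_rate = 0.01,
                                arrhythmia_ratio = 0.5,
                                seed = NULL) {
  if (any(baselines <= 0) || length(baselines) != 3L) {
    stopf("invalid-argument: 'baselines' must be three positive rates")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(arrhythmia_rate, "arrhythmia_rate", lower = 0, upper = 1)
  with_seed(seed, {
    n <- length(truth$samples)
    latent <- matrix(rep(baselines, each = n), n, 3L,
                     dimnames = list(truth$samples, c("hr21", "hr28", "hr35")))
    if (!is.null(qtls) && nrow(qtls)) {
      dos <- qtl_genotypes(truth, qtls)
      a <- as.matrix(qtls[, c("a_21", "a_28", "a_35")])
      d <- as.matrix(qtls[, c("d_21", "d_28", "d_35")])
      latent <- latent + t(dos) %*% a + t(dos == 1L) %*% d
    }
    latent <- latent + matrix(rnorm(n * 3L, 0, noise_sd), n, 3L)
    arr <- runif(n) < arrhythmia_rate
    recorded <- latent * ifelse(arr, arrhythmia_ratio, 1)
    out <- data.frame(sample = truth$samples,
                      hr21 = recorded[, 1L], hr28 = recorded[, 2L],
                      hr35 = recorded[, 3L], arrhythmia = arr,
                      stringsAsFactors = FALSE, row.names = NULL)
    structure(out, latent = latent,
              class = c("phenotype_table", "data.frame"))
  })
}

#' Simulate a gene annotation for a simulated genome
#'
#' Places a Poisson number of non-overlapping genes per chromosome with
#' uniform starts and log-normal lengths; used to exercise region
#' annotation and candidate ranking on synthetic crosses.
#'
#' @param spec A [genome_spec()].
#' @param gene_density Expected genes per bp.
#' @param mean_length Mean gene length in bp.
#' @param seed Integer seed.
#' @return A `gene_table` data frame: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `name`.
#' @export
simulate_gene_annotation <- function(spec, gene_density = 1 / 50000,
                                     mean_length = 15000, seed = NULL) {
  with_seed(seed, {
    res <- list()
    gid <- 0L
    for (cn in names(spec$chromosomes)) {
      len <- spec$chromosomes[[cn]]
      k <- rpois(1L, len * gene_density)
      if (!k) next
      start <- sort(sample.int(len, k)) - 1L
      glen <- pmax(200, round(stats::rlnorm(k, log(mean_length), 0.6)))
      end <- pmin(start + glen, len)
      # enforce non-overlap by truncating at the next start
      if (k > 1L) end[-k] <- pmin(end[-k], start[-1L])
      keep <- end > start
      ids <- sprintf("GENE%05d", gid + seq_len(sum(keep)))
      gid <- gid + sum(keep)
      res[[cn]] <- data.frame(gene_id = ids, chrom = cn,
                              start = start[keep], end = end[keep],
                              strand = sample(c("+", "-"), sum(keep), TRUE),
                              name = tolower(ids), stringsAsFactors = FALSE)
    }
    out <- if (length(res)) do.call(rbind, res) else
      data.frame(gene_id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), name = character())
    rownames(out) <- NULL
    structure(out, class = c("gene_table", "data.frame"))
  })
}

#' Simulate differential-expression and loss-of-function evidence tables
#'
#' Marks a fraction of genes as differentially expressed (adjusted p below
#' the usual 0.01 cut-off with |log2 fold change| >= 1) and gives genes a
#' rare loss-of-function variant count (most genes 0, maximum small), the
#' regime typical of inbred-strain comparisons.
#'
#' @param genes A `gene_table`.
#' @param de_fraction Fraction of genes differentially expressed.
#' @param lof_rate Poisson mean of per-gene LoF counts (rare).
#' @param seed Integer seed.
#' @return List with elements `de` (`gene_id`, `log2fc`, `padj`) and `lof`
#'   (`gene_id`, `lof_count`).
#' @export
simulate_evidence <- function(genes, de_fraction = 0.1, lof_rate = 0.05,
                              seed = NULL) {
  with_seed(seed, {
    n <- nrow(genes)
    is_de <- runif(n) < de_fraction
    log2fc <- ifelse(is_de, sample(c(-1, 1), n, TRUE) * runif(n, 1, 4),
                     rnorm(n, 0, 0.3))
    padj <- ifelse(is_de, runif(n, 0, 0.009), runif(n, 0.02, 1))
    lof <- pmin(rpois(n, lof_rate), 3L)
    list(de = data.frame(gene_id = genes$gene_id, log2fc = log2fc,
                         padj = padj, stringsAsFactors = FALSE),
         lof = data.frame(gene_id = genes$gene_id, lof_count = lof,
                          stringsAsFactors = FALSE))
  })
}
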