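# Round-trip-safe readers and writers for every on-disk artifact. All
# formats are plain text (TSV / BED / GFF3 / VCF / JSON); floating-point
# fields are serialized with 10 significant digits so reruns with
# identical inputs are byte-identical.

write_tsv_file <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("##", comments), con)
  is_dbl <- vapply(df, is.double, TRUE)
  df[is_dbl] <- lapply(df[is_dbl], fmt_num)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_file <- function(path, required = NULL) {
  lines <- readLines(path)
  meta <- sub("^##", "", grep("^##", lines, value = TRUE))
  body <- lines[!grepl("^##", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stopf("parse error in %s: expected columns %s", path,
          paste(required, collapse = ", "))
  }
  list(df = df, meta = meta)
}

meta_value <- function(meta, key) {
  hit <- grep(paste0("^", key, "="), meta, value = TRUE)
  sub(paste0("^", key, "="), "", hit)
}

chrom_length_comments <- function(lens) {
  sprintf("chrom_length=%s:%s", names(lens), fmt_num(lens))
}

parse_chrom_lengths <- function(meta) {
  vals <- meta_value(meta, "chrom_length")
  if (!length(vals)) stopf("parse error: missing chrom_length header lines")
  parts <- strsplit(vals, ":", fixed = TRUE)
  setNames(as.numeric(vapply(parts, `[`, "", 2L)),
           vapply(parts, `[`, "", 1L))
}

#' Write / read a marker map as TSV
#'
#' Columns `chrom`, `pos0` (0-based), `allele_A`, `allele_B`; chromosome
#' lengths are carried in `##chrom_length=` header lines.
#'
#' @param markers A `marker_set`.
#' @param path File path.
#' @return `read_marker_map()` returns the `marker_set`.
#' @export
write_marker_map <- function(markers, path) {
  write_tsv_file(as.data.frame(markers), path,
                 chrom_length_comments(chrom_lengths_of(markers)))
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  r <- read_tsv_file(path, c("chrom", "pos0", "allele_A", "allele_B"))
  structure(r$df, chrom_lengths = parse_chrom_lengths(r$meta),
            class = c("marker_set", "data.frame"))
}

#' Write / read allele counts as long TSV
#'
#' One row per (sample, marker) with nonzero depth: `sample`, `chrom`,
#' `pos0`, `nA`, `nB`. The sample roster is carried in a `##samples=`
#' header line so all-zero individuals survive the round trip; reading
#' requires the marker set to rebuild the count matrices.
#'
#' @param counts An `allele_counts` object.
#' @param path File path.
#' @param markers The `marker_set` the counts refer to.
#' @return `read_allele_counts()` returns the `allele_counts`.
#' @export
write_allele_counts <- function(counts, path) {
  depth <- counts$nA + counts$nB
  idx <- which(depth > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  df <- data.frame(sample = counts$samples[idx[, 2L]],
                   chrom = counts$markers$chrom[idx[, 1L]],
                   pos0 = counts$markers$pos0[idx[, 1L]],
                   nA = counts$nA[idx], nB = counts$nB[idx],
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path,
                 c(paste0("samples=", paste(counts$samples, collapse = ",")),
                   chrom_length_comments(counts$chrom_lengths)))
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path, markers) {
  r <- read_tsv_file(path, c("sample", "chrom", "pos0", "nA", "nB"))
  samples <- strsplit(meta_value(r$meta, "samples"), ",", fixed = TRUE)[[1L]]
  key <- paste(markers$chrom, markers$pos0)
  mi <- match(paste(r$df$chrom, r$df$pos0), key)
  if (anyNA(mi)) stopf("consistency error: counts reference unknown markers in %s", path)
  si <- match(r$df$sample, samples)
  if (anyNA(si)) stopf("parse error: sample outside the roster in %s", path)
  nA <- matrix(0L, nrow(markers), length(samples),
               dimnames = list(NULL, samples))
  nB <- nA
  nA[cbind(mi, si)] <- as.integer(r$df$nA)
  nB[cbind(mi, si)] <- as.integer(r$df$nB)
  structure(list(markers = markers, samples = samples, nA = nA, nB = nB,
                 chrom_lengths = parse_chrom_lengths(r$meta)),
            class = "allele_counts")
}

#' Write / read allele counts as a VCF with AD fields
#'
#' Sites-only VCF body (one record per marker, REF = allele B of the
#' reference founder, ALT = allele A) with one sample column per
#' individual carrying the allelic-depth `AD` field as `nB,nA`
#' (reference-first, as emitted by standard callers).
#'
#' @param counts An `allele_counts` object.
#' @param path File path.
#' @return `read_allele_counts_vcf()` returns the `allele_counts`.
#' @export
write_allele_counts_vcf <- function(counts, path) {
  lens <- counts$chrom_lengths
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", counts$samples), collapse = "\t"))
  ad <- matrix(paste0(counts$nB, ",", counts$nA), nrow = nrow(counts$markers))
  body <- paste(counts$markers$chrom, counts$markers$pos0 + 1L, ".",
                counts$markers$allele_B, counts$markers$allele_A,
                ".", "PASS", ".", "AD",
                apply(ad, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_allele_counts_vcf
#' @export
read_allele_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  contig <- regmatches(v@meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)", v@meta))
  contig <- contig[lengths(contig) == 3L]
  if (!length(contig)) stopf("parse error: VCF %s lacks contig length headers", path)
  lens <- setNames(as.numeric(vapply(contig, `[`, "", 3L)),
                   vapply(contig, `[`, "", 2L))
  markers <- structure(
    data.frame(chrom = fix[, "CHROM"], pos0 = as.integer(fix[, "POS"]) - 1L,
               allele_A = fix[, "ALT"], allele_B = fix[, "REF"],
               stringsAsFactors = FALSE, row.names = NULL),
    chrom_lengths = lens, class = c("marker_set", "data.frame"))
  ad <- vcfR::extract.gt(v, element = "AD")
  split_ad <- function(k) {
    m <- matrix(as.integer(unlist(strsplit(ad, ",", fixed = TRUE))), nrow = 2L)
    matrix(m[k, ], nrow = nrow(ad), dimnames = dimnames(ad))
  }
  nB <- split_ad(1L); nA <- split_ad(2L)
  rownames(nA) <- rownames(nB) <- NULL
  structure(list(markers = markers, samples = colnames(ad), nA = nA, nB = nB,
                 chrom_lengths = lens),
            class = "allele_counts")
}

#' Write / read phenotypes as TSV
#'
#' Columns `sample`, `hr21`, `hr28`, `hr35`, `arrhythmia`.
#'
#' @param phenotypes A `phenotype_table`.
#' @param path File path.
#' @return `read_phenotypes()` returns the table (latent rates, a
#'   simulation-only attribute, are not serialized).
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv_file(as.data.frame(phenotypes), path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  r <- read_tsv_file(path, c("sample", "hr21", "hr28", "hr35"))
  structure(r$df, class = c("phenotype_table", "data.frame"))
}

#' Write / read decoded genotype paths as run-length TSV
#'
#' One row per constant-state run: `sample`, `chrom`, `start`, `end`,
#' `state`; window size, chromosome lengths, the sample roster and the
#' per-(sample, chromosome) path log-probabilities are carried in header
#' lines.
#'
#' @param paths A `genotype_paths` object.
#' @param path File path.
#' @return `read_genotype_paths()` returns the `genotype_paths`.
#' @export
write_genotype_paths <- function(paths, path) {
  rows <- list()
  for (cn in unique(paths$windows$chrom)) {
    wrows <- which(paths$windows$chrom == cn)
    starts <- paths$windows$start[wrows]
    ends <- paths$windows$end[wrows]
    for (j in seq_along(paths$samples)) {
      r <- rle(paths$states[wrows, j])
      stop_i <- cumsum(r$lengths)
      start_i <- c(1L, head(stop_i, -1L) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paths$samples[j], chrom = cn,
        start = starts[start_i], end = ends[stop_i],
        state = GENO_STATES[r$values], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  lp <- sprintf("logp=%s:%s:%s", paths$logp$sample, paths$logp$chrom,
                fmt_num(paths$logp$logp))
  write_tsv_file(df, path,
                 c(paste0("window_size=", fmt_num(paths$window_size)),
                   paste0("samples=", paste(paths$samples, collapse = ",")),
                   chrom_length_comments(paths$chrom_lengths), lp))
  invisible(path)
}

#' @rdname write_genotype_paths
#' @export
read_genotype_paths <- function(path) {
  r <- read_tsv_file(path, c("sample", "chrom", "start", "end", "state"))
  w <- as.numeric(meta_value(r$meta, "window_size"))
  lens <- parse_chrom_lengths(r$meta)
  samples <- strsplit(meta_value(r$meta, "samples"), ",", fixed = TRUE)[[1L]]
  win_list <- list()
  for (cn in names(lens)) {
    nwin <- ceiling(lens[[cn]] / w)
    start <- (seq_len(nwin) - 1) * w
    win_list[[cn]] <- data.frame(chrom = cn, win = seq_len(nwin) - 1L,
                                 start = start,
                                 end = pmin(start + w, lens[[cn]]),
                                 stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, c(win_list, list(make.row.names = FALSE)))
  states <- matrix(NA_integer_, nrow(windows), length(samples),
                   dimnames = list(NULL, samples))
  offset <- c(0, cumsum(vapply(win_list, nrow, 0L)))
  names(offset) <- c(names(lens), "_end")
  for (i in seq_len(nrow(r$df))) {
    row <- r$df[i, ]
    first <- offset[[row$chrom]] + row$start %/% w + 1L
    last <- offset[[row$chrom]] + (row$end - 1) %/% w + 1L
    states[first:last, row$sample] <- state_codes(row$state)
  }
  lp <- strsplit(meta_value(r$meta, "logp"), ":", fixed = TRUE)
  logp <- data.frame(sample = vapply(lp, `[`, "", 1L),
                     chrom = vapply(lp, `[`, "", 2L),
                     logp = as.numeric(vapply(lp, `[`, "", 3L)),
                     stringsAsFactors = FALSE)
  structure(list(windows = windows, states = states, samples = samples,
                 logp = logp, window_size = w, chrom_lengths = lens),
            class = "genotype_paths")
}

#' Write / read crossover calls as BED-like TSV
#'
#' Columns `chrom`, `pos0`, `pos0 + 1`, `sample`, `from`, `to`,
#' `distance`.
#'
#' @param crossovers Data frame from [call_crossovers()].
#' @param path File path.
#' @return `read_crossovers()` returns the data frame.
#' @export
write_crossovers <- function(crossovers, path) {
  df <- data.frame(chrom = crossovers$chrom, start = crossovers$pos0,
                   end = crossovers$pos0 + 1, sample = crossovers$sample,
                   from = crossovers$from, to = crossovers$to,
                   distance = crossovers$distance, stringsAsFactors = FALSE)
  write_tsv_file(df[order(df$chrom, df$start, df$sample), ], path)
  invisible(path)
}

#' @rdname write_crossovers
#' @export
read_crossovers <- function(path) {
  r <- read_tsv_file(path, c("chrom", "start", "end", "sample", "from", "to",
                             "distance"))
  out <- data.frame(sample = r$df$sample, chrom = r$df$chrom,
                    pos0 = r$df$start, from = r$df$from, to = r$df$to,
                    distance = r$df$distance,
                    double_crossover = r$df$distance == 2L,
                    stringsAsFactors = FALSE)
  out
}

#' Write / read the block set as BED
#'
#' Standard 0-based half-open BED (`chrom`, `start`, `end`, `block_id`)
#' with `##grid=` and `##chrom_length=` header lines.
#'
#' @param blocks A `block_set`.
#' @param path File path.
#' @return `read_blocks_bed()` returns the `block_set`.
#' @export
write_blocks_bed <- function(blocks, path) {
  write_tsv_file(as.data.frame(blocks), path,
                 c(paste0("grid=", fmt_num(attr(blocks, "grid"))),
                   chrom_length_comments(attr(blocks, "chrom_lengths"))))
  invisible(path)
}

#' @rdname write_blocks_bed
#' @export
read_blocks_bed <- function(path) {
  r <- read_tsv_file(path, c("chrom", "start", "end", "block_id"))
  if (is.unsorted(order(r$df$chrom, r$df$start))) {
    stopf("parse error: unsorted BED intervals in %s", path)
  }
  structure(r$df, grid = as.numeric(meta_value(r$meta, "grid")),
            chrom_lengths = parse_chrom_lengths(r$meta),
            class = c("block_set", "data.frame"))
}

#' Write / read the block genotype matrix as wide TSV
#'
#' One row per block (`block_id`, `chrom`, `start`, `end`) followed by one
#' state column (AA/AB/BB) per individual. [write_dosage_matrix()] writes
#' the additive 2/1/0 view (write-only convenience).
#'
#' @param gm A `genotype_matrix`.
#' @param path File path.
#' @return `read_genotype_matrix()` returns the `genotype_matrix`.
#' @export
write_genotype_matrix <- function(gm, path) {
  lab <- matrix(GENO_STATES[gm$states], nrow = nrow(gm$states),
                dimnames = dimnames(gm$states))
  df <- cbind(gm$blocks[, c("block_id", "chrom", "start", "end")],
              as.data.frame(lab, stringsAsFactors = FALSE))
  write_tsv_file(df, path,
                 c(paste0("grid=", fmt_num(gm$grid)),
                   chrom_length_comments(gm$chrom_lengths)))
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  r <- read_tsv_file(path, c("block_id", "chrom", "start", "end"))
  samples <- setdiff(names(r$df), c("block_id", "chrom", "start", "end"))
  states <- vapply(r$df[samples], state_codes, integer(nrow(r$df)))
  states <- matrix(states, nrow = nrow(r$df),
                   dimnames = list(r$df$block_id, samples))
  structure(list(blocks = r$df[, c("chrom", "start", "end", "block_id")],
                 states = states, samples = samples,
                 grid = as.numeric(meta_value(r$meta, "grid")),
                 chrom_lengths = parse_chrom_lengths(r$meta)),
            class = "genotype_matrix")
}

#' @rdname write_genotype_matrix
#' @export
write_dosage_matrix <- function(gm, path) {
  df <- cbind(gm$blocks[, c("block_id", "chrom", "start", "end")],
              as.data.frame(geno_dosage(gm)))
  write_tsv_file(df, path,
                 c(paste0("grid=", fmt_num(gm$grid)),
                   chrom_length_comments(gm$chrom_lengths)))
  invisible(path)
}

#' Write / read association scans as TSV
#'
#' Columns `block_id`, `chrom`, `start`, `end`, `phenotype`, `beta`, `se`,
#' `p`, `neg_log10_p`; per-phenotype heritability estimates and the cohort
#' size are carried in header lines.
#'
#' @param scan An `association_scan` or a row-bound combination of scans.
#' @param path File path.
#' @return `read_scan()` returns the scan data frame (with `h2` and `n`
#'   attributes when present in the header).
#' @export
write_scan <- function(scan, path) {
  meta <- character()
  h2 <- attr(scan, "h2")
  if (!is.null(h2)) {
    meta <- c(meta, sprintf("h2=%s:%s",
                            if (is.null(names(h2))) unique(scan$phenotype) else names(h2),
                            fmt_num(h2)))
  }
  if (!is.null(attr(scan, "n"))) meta <- c(meta, paste0("n=", attr(scan, "n")))
  write_tsv_file(as.data.frame(scan), path, meta)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  r <- read_tsv_file(path, c("block_id", "chrom", "start", "end", "phenotype",
                             "beta", "se", "p", "neg_log10_p"))
  h2v <- meta_value(r$meta, "h2")
  h2 <- NULL
  if (length(h2v)) {
    parts <- strsplit(h2v, ":", fixed = TRUE)
    h2 <- setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                   vapply(parts, `[`, "", 1L))
  }
  nv <- meta_value(r$meta, "n")
  structure(r$df, h2 = h2, n = if (length(nv)) as.integer(nv) else NULL,
            class = c("association_scan", "data.frame"))
}

#' Write / read permutation-FDR thresholds as JSON
#'
#' @param thresholds An `fdr_thresholds` or a named list of them (one per
#'   phenotype).
#' @param path File path.
#' @return `read_thresholds_json()` returns a named list of
#'   `fdr_thresholds`.
#' @export
write_thresholds_json <- function(thresholds, path) {
  if (inherits(thresholds, "fdr_thresholds")) {
    thresholds <- setNames(list(thresholds),
                           attr(thresholds, "phenotype") %||% "trait")
  }
  obj <- lapply(thresholds, function(th) {
    list(phenotype = attr(th, "phenotype"),
         n_perm = attr(th, "n_perm"),
         seed = attr(th, "seed"),
         thresholds = as.data.frame(th))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(o) {
    structure(as.data.frame(o$thresholds),
              n_perm = o$n_perm, seed = o$seed, phenotype = o$phenotype,
              class = c("fdr_thresholds", "data.frame"))
  })
}

#' Write / read fine-mapped regions (JSON + BED)
#'
#' The JSON form round-trips members, phenotypes and gene assignments; the
#' BED form (`chrom`, `start`, `end`, `region_id`, `lead_neg_log10_p`) is
#' a browser-ready summary.
#'
#' @param regions A `fine_mapped_regions` data frame.
#' @param path File path.
#' @return `read_regions_json()` returns the `fine_mapped_regions`.
#' @export
write_regions_json <- function(regions, path) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    row <- list(region_id = r$region_id, chrom = r$chrom,
                start = r$start, end = r$end,
                lead_block_id = r$lead_block_id,
                lead_neg_log10_p = r$lead_neg_log10_p,
                n_blocks = r$n_blocks,
                members = strsplit(r$members, ";")[[1L]],
                phenotypes = strsplit(r$phenotypes, ";")[[1L]])
    if (!is.null(r$n_genes)) {
      row$n_genes <- r$n_genes
      row$genes <- if (nzchar(r$genes)) strsplit(r$genes, ";")[[1L]] else character()
    }
    row
  })
  gene_map <- attr(regions, "gene_map")
  obj <- list(regions = rows,
              gene_map = if (!is.null(gene_map)) gene_map else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_regions_json
#' @export
read_regions_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$regions, function(r) {
    data.frame(region_id = r$region_id, chrom = r$chrom, start = r$start,
               end = r$end, lead_block_id = r$lead_block_id,
               lead_neg_log10_p = r$lead_neg_log10_p, n_blocks = r$n_blocks,
               members = paste(unlist(r$members), collapse = ";"),
               phenotypes = paste(unlist(r$phenotypes), collapse = ";"),
               n_genes = if (length(r$n_genes)) as.integer(r$n_genes) else NA_integer_,
               genes = paste(unlist(r$genes), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$n_genes))) out$n_genes <- NULL
  if (!is.null(out$n_genes)) out$genes[is.na(out$genes)] <- "" else out$genes <- NULL
  gm <- obj$gene_map
  gm <- if (!is.null(gm) && length(gm)) {
    do.call(rbind, lapply(gm, function(g) as.data.frame(g, stringsAsFactors = FALSE)))
  } else NULL
  structure(out, gene_map = gm,
            class = c("fine_mapped_regions", "data.frame"))
}

#' @rdname write_regions_json
#' @export
write_regions_bed <- function(regions, path) {
  df <- regions[order(regions$chrom, regions$start),
                c("chrom", "start", "end", "region_id", "lead_neg_log10_p")]
  write_tsv_file(df, path)
  invisible(path)
}

#' Write / read the candidate-gene ranking as TSV
#'
#' @param candidates A `candidate_table`.
#' @param path File path.
#' @return `read_candidates()` returns the table.
#' @export
write_candidates <- function(candidates, path) {
  write_tsv_file(as.data.frame(candidates), path)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  r <- read_tsv_file(path, c("gene_id", "region_id", "lead_neg_log10_p",
                             "de_flag", "lof_count", "score", "rank"))
  structure(r$df, class = c("candidate_table", "data.frame"))
}

#' Write a gene table as GFF3
#'
#' Emits `gene` features (1-based inclusive coordinates per the GFF3
#' standard) with `ID` and `Name` attributes and `##sequence-region`
#' pragmas.
#'
#' @param genes A `gene_table` (0-based half-open coordinates).
#' @param path File path.
#' @param chrom_lengths Optional named lengths for the sequence-region
#'   pragmas.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(genes, path, chrom_lengths = NULL) {
  hdr <- "##gff-version 3"
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##sequence-region %s 1 %d",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  body <- sprintf("%s\tblockqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                  genes$chrom, as.integer(genes$start) + 1L,
                  as.integer(genes$end), genes$strand,
                  genes$gene_id, genes$name)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read the segregation report as TSV
#'
#' @param report A `segregation_report`.
#' @param path File path.
#' @return `read_segregation()` returns the report.
#' @export
write_segregation <- function(report, path) {
  write_tsv_file(as.data.frame(report), path,
                 c(paste0("aa_excess=", fmt_num(attr(report, "aa_excess"))),
                   paste0("n=", attr(report, "n"))))
  invisible(path)
}

#' @rdname write_segregation
#' @export
read_segregation <- function(path) {
  r <- read_tsv_file(path, c("block_id", "chisq", "p"))
  structure(r$df, aa_excess = as.numeric(meta_value(r$meta, "aa_excess")),
            n = as.integer(meta_value(r$meta, "n")),
            class = c("segregation_report", "data.frame"))
}
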