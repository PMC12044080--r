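# LD-based collapsing of significant blocks into distinct fine-mapped
# regions (greedy best-p-first clumping, PLINK-clump style), gene
# annotation by interval overlap, and evidence-weighted candidate ranking.

#' Collapse significant blocks into fine-mapped regions
#'
#' Blocks significant in any phenotype (p at or below the chosen
#' permutation-FDR threshold) are sorted by ascending p; greedily, the best
#' remaining block seeds a region and absorbs every remaining significant
#' block on the same chromosome whose dosage correlation with the seed
#' satisfies `r^2 >= r2_threshold` or whose interval lies within
#' `merge_distance` bp of the seed block. The region interval is the
#' min/max span of its members; regions whose intervals still overlap are
#' merged. The procedure is deterministic and idempotent.
#'
#' @param scan An `association_scan` (rows for one or several phenotypes).
#' @param gm The `genotype_matrix` the scan was computed on.
#' @param thresholds An `fdr_thresholds`, or a named list of them keyed by
#'   phenotype for multi-phenotype scans.
#' @param level FDR level selecting the threshold (default 0.05).
#' @param r2_threshold Squared dosage correlation for absorption
#'   (default 0.5).
#' @param merge_distance Distance in bp for proximity absorption
#'   (default 500 kb).
#' @return A `fine_mapped_regions` data frame: `region_id`, `chrom`,
#'   `start`, `end`, `lead_block_id`, `lead_neg_log10_p`, `n_blocks`,
#'   `members` (semicolon-joined block ids), `phenotypes`
#'   (semicolon-joined). Empty (zero-row) when nothing is significant.
#' @export
collapse_loci <- function(scan, gm, thresholds, level = 0.05,
                          r2_threshold = 0.5, merge_distance = 5e5) {
  if (!all(scan$block_id %in% gm$blocks$block_id)) {
    stopf("invalid-argument: scan and genotype matrix do not share block ids")
  }
  thr_for <- function(ph) {
    if (inherits(thresholds, "fdr_thresholds")) return(threshold_at(thresholds, level))
    if (is.list(thresholds) && !is.null(thresholds[[ph]])) {
      return(threshold_at(thresholds[[ph]], level))
    }
    stopf("invalid-argument: no thresholds for phenotype '%s'", ph)
  }
  thr <- vapply(scan$phenotype, thr_for, 0)
  sig <- scan[scan$p <= thr, , drop = FALSE]
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      lead_block_id = character(), lead_neg_log10_p = numeric(),
                      n_blocks = integer(), members = character(),
                      phenotypes = character(), stringsAsFactors = FALSE)
  if (!nrow(sig)) {
    return(structure(empty, class = c("fine_mapped_regions", "data.frame")))
  }
  # one row per significant block: best p and the phenotypes it is
  # significant in
  ord <- order(sig$p, sig$block_id)
  sig <- sig[ord, , drop = FALSE]
  first <- !duplicated(sig$block_id)
  phenos <- vapply(split(sig$phenotype, sig$block_id), function(x)
    paste(sort(unique(x)), collapse = ";"), "")
  blocks <- sig[first, , drop = FALSE]
  blocks$phenotypes <- phenos[blocks$block_id]
  blocks <- blocks[order(blocks$p, blocks$block_id), , drop = FALSE]

  dose <- geno_dosage(gm)
  rownames(dose) <- gm$blocks$block_id
  remaining <- blocks
  regions <- list()
  while (nrow(remaining)) {
    seed <- remaining[1L, ]
    same_chrom <- remaining$chrom == seed$chrom
    g_seed <- dose[seed$block_id, ]
    r2 <- rep(0, nrow(remaining))
    if (sd(g_seed) > 0) {
      cand <- which(same_chrom)
      cc <- suppressWarnings(
        cor(g_seed, t(dose[remaining$block_id[cand], , drop = FALSE])))
      r2[cand] <- ifelse(is.na(cc), 0, cc^2)
    }
    near <- same_chrom &
      (pmax(remaining$start, seed$start) - pmin(remaining$end, seed$end)) <= merge_distance
    take <- which((same_chrom & r2 >= r2_threshold) | near)
    take <- union(1L, take)
    members <- remaining[take, , drop = FALSE]
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = seed$chrom,
      start = min(members$start), end = max(members$end),
      lead_block_id = seed$block_id,
      lead_neg_log10_p = seed$neg_log10_p,
      n_blocks = nrow(members),
      members = paste(sort(members$block_id), collapse = ";"),
      phenotypes = paste(sort(unique(unlist(strsplit(members$phenotypes, ";")))),
                         collapse = ";"),
      lead_p = seed$p,
      stringsAsFactors = FALSE)
    remaining <- remaining[-take, , drop = FALSE]
  }
  out <- do.call(rbind, regions)
  # merge regions whose intervals overlap on the same chromosome
  repeat {
    out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
    ov <- which(out$chrom[-1L] == out$chrom[-nrow(out)] &
                  out$start[-1L] < out$end[-nrow(out)])
    if (!length(ov)) break
    i <- ov[1L]
    a <- out[i, ]; b <- out[i + 1L, ]
    keep <- if (a$lead_p <= b$lead_p) a else b
    merged <- data.frame(
      chrom = a$chrom, start = min(a$start, b$start), end = max(a$end, b$end),
      lead_block_id = keep$lead_block_id,
      lead_neg_log10_p = keep$lead_neg_log10_p,
      n_blocks = a$n_blocks + b$n_blocks,
      members = paste(sort(unique(c(strsplit(a$members, ";")[[1L]],
                                    strsplit(b$members, ";")[[1L]]))),
                      collapse = ";"),
      phenotypes = paste(sort(unique(c(strsplit(a$phenotypes, ";")[[1L]],
                                       strsplit(b$phenotypes, ";")[[1L]]))),
                         collapse = ";"),
      lead_p = keep$lead_p, stringsAsFactors = FALSE)
    out <- rbind(out[seq_len(i - 1L), ], merged,
                 out[setdiff(seq_len(nrow(out)), seq_len(i + 1L)), ])
  }
  out$lead_p <- NULL
  out <- cbind(region_id = sprintf("R%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, level = level, r2_threshold = r2_threshold,
            merge_distance = merge_distance,
            class = c("fine_mapped_regions", "data.frame"))
}

#' Read gene records from a GFF3 annotation
#'
#' Imports features of type `gene` and returns them with 0-based half-open
#' coordinates (GFF3 is 1-based inclusive).
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_table` data frame: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `name`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$gene_id)
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    name = nm, stringsAsFactors = FALSE)
  if (anyNA(out$gene_id) || any(out$end <= out$start)) {
    stopf("parse error: malformed gene feature(s) in %s", path)
  }
  rownames(out) <- NULL
  structure(out, class = c("gene_table", "data.frame"))
}

#' Annotate fine-mapped regions with overlapping genes
#'
#' A gene belongs to a region iff their intervals overlap by at least 1 bp
#' (any-overlap rule). Each gene is assigned to exactly one region -- the
#' one with the largest overlap, ties to the earlier region -- so per-region
#' gene counts sum to the number of distinct overlapping genes.
#'
#' @param regions A `fine_mapped_regions` data frame.
#' @param genes A `gene_table` (same 0-based half-open coordinates).
#' @return The regions with added `n_genes` and `genes` (semicolon-joined
#'   gene ids) columns and a `gene_map` attribute (data frame `gene_id`,
#'   `region_id`, `overlap_bp`, gene coordinates).
#' @export
annotate_regions <- function(regions, genes) {
  regions$n_genes <- 0L
  regions$genes <- ""
  gene_map <- data.frame(gene_id = character(), region_id = character(),
                         g_start = numeric(), g_end = numeric(),
                         overlap_bp = numeric(), stringsAsFactors = FALSE)
  if (nrow(regions) && nrow(genes)) {
    rg <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1, regions$end))
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
    hits <- GenomicRanges::findOverlaps(gg, rg)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(IRanges::pintersect(gg[qh], rg[sh]))
      df <- data.frame(g = qh, r = sh, ov = ov)
      df <- df[order(df$g, -df$ov, df$r), , drop = FALSE]
      df <- df[!duplicated(df$g), , drop = FALSE]   # one region per gene
      gene_map <- data.frame(gene_id = genes$gene_id[df$g],
                             region_id = regions$region_id[df$r],
                             g_start = genes$start[df$g],
                             g_end = genes$end[df$g],
                             overlap_bp = df$ov, stringsAsFactors = FALSE)
      agg <- split(gene_map$gene_id, gene_map$region_id)
      idx <- match(names(agg), regions$region_id)
      regions$n_genes[idx] <- lengths(agg)
      regions$genes[idx] <- vapply(agg, function(x) paste(sort(x), collapse = ";"), "")
    }
  }
  structure(regions, gene_map = gene_map,
            class = c("fine_mapped_regions", "data.frame"))
}

#' Rank candidate genes by association and functional evidence
#'
#' Genes of regions whose lead `-log10 p` strictly exceeds `min_log10p`
#' are scored as
#' `w_lp * min(lead -log10 p, lp_cap) + w_de * 1[DE] + w_lof * 1[LoF > 0]`
#' where the DE gate is adjusted p below `de_fdr` with fold change at least
#' `de_fc`, and ranked by descending score (ties by descending lead
#' `-log10 p`, then gene id). Genes absent from both evidence tables score
#' zero on the evidence terms.
#'
#' @param regions Annotated `fine_mapped_regions` (see
#'   [annotate_regions()]).
#' @param de Optional data frame `gene_id`, `log2fc`, `padj`.
#' @param lof Optional data frame `gene_id`, `lof_count`.
#' @param weights Non-negative weights `c(lp, de, lof)`, not all zero.
#' @param de_fdr Adjusted-p cut-off for the DE gate (default 0.01).
#' @param de_fc Minimum fold change for the DE gate (default 2).
#' @param min_log10p Region filter on lead `-log10 p` (strict, default 3).
#' @param lp_cap Ceiling applied to the association term (default 10).
#' @return A `candidate_table` data frame: `gene_id`, `region_id`,
#'   `lead_neg_log10_p`, `de_flag`, `lof_count`, `score`, `rank`.
#' @export
rank_candidates <- function(regions, de = NULL, lof = NULL,
                            weights = c(lp = 1, de = 1, lof = 1),
                            de_fdr = 0.01, de_fc = 2,
                            min_log10p = 3, lp_cap = 10) {
  if (any(weights < 0) || all(weights == 0) || length(weights) != 3L) {
    stopf("invalid-argument: weights must be three non-negative values, not all zero")
  }
  gm <- attr(regions, "gene_map")
  if (is.null(gm)) stopf("invalid-argument: regions must be annotated first (annotate_regions)")
  keep <- regions$region_id[regions$lead_neg_log10_p > min_log10p]
  gm <- gm[gm$region_id %in% keep, , drop = FALSE]
  empty <- data.frame(gene_id = character(), region_id = character(),
                      lead_neg_log10_p = numeric(), de_flag = logical(),
                      lof_count = integer(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (!nrow(gm)) return(structure(empty, class = c("candidate_table", "data.frame")))
  lp <- regions$lead_neg_log10_p[match(gm$region_id, regions$region_id)]
  de_flag <- rep(FALSE, nrow(gm))
  if (!is.null(de) && nrow(de)) {
    i <- match(gm$gene_id, de$gene_id)
    de_flag <- !is.na(i) & de$padj[i] < de_fdr & abs(de$log2fc[i]) >= log2(de_fc)
  }
  lof_count <- rep(0L, nrow(gm))
  if (!is.null(lof) && nrow(lof)) {
    i <- match(gm$gene_id, lof$gene_id)
    lof_count <- ifelse(is.na(i), 0L, as.integer(lof$lof_count[i]))
  }
  score <- weights[1L] * pmin(lp, lp_cap) + weights[2L] * de_flag +
    weights[3L] * (lof_count > 0L)
  out <- data.frame(gene_id = gm$gene_id, region_id = gm$region_id,
                    lead_neg_log10_p = lp, de_flag = de_flag,
                    lof_count = lof_count, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$lead_neg_log10_p, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("candidate_table", "data.frame"))
}
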