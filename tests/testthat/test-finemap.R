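# LD-based collapsing, gene annotation, candidate ranking.

# Construct a scan + genotype matrix with chosen dosage columns and p-values.
make_scan <- function(blocks_df, p, phenotype = "hr28") {
  structure(data.frame(block_id = blocks_df$block_id, chrom = blocks_df$chrom,
                       start = blocks_df$start, end = blocks_df$end,
                       phenotype = phenotype, beta = 1, se = 1, p = p,
                       neg_log10_p = -log10(p), stringsAsFactors = FALSE),
            h2 = 0.1, n = 20L, class = c("association_scan", "data.frame"))
}

rand_dosage <- function(n) sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4)

test_that("collapse handles single blocks, perfect LD and separate chromosomes", {
  set.seed(201)
  n <- 40L
  bl <- rbind(make_blocks_df("chr1", c(0, 1e4, 5e6), c(1e4, 2e4, 5.01e6)),
              make_blocks_df("chr2", 0, 1e4))
  g1 <- rand_dosage(n); g3 <- rand_dosage(n); g4 <- rand_dosage(n)
  gm <- make_gm(bl, rbind(g1, g1, g3, g4), c(chr1 = 6e6, chr2 = 1e6))
  th <- make_thresholds(p05 = 1e-3, phenotype = "hr28")

  # one significant block
  r1 <- collapse_loci(make_scan(bl, c(1e-6, 0.5, 0.5, 0.5)), gm, th,
                      merge_distance = 0)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$lead_block_id, bl$block_id[1L])
  expect_equal(c(r1$start, r1$end), c(0, 1e4))

  # two adjacent blocks in perfect LD: one region, lead = smaller p
  r2 <- collapse_loci(make_scan(bl, c(1e-5, 1e-6, 0.5, 0.5)), gm, th,
                      merge_distance = 0)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$lead_block_id, bl$block_id[2L])
  expect_equal(r2$n_blocks, 2L)
  expect_equal(c(r2$start, r2$end), c(0, 2e4))

  # different chromosomes never merge
  r3 <- collapse_loci(make_scan(bl, c(1e-6, 0.5, 0.5, 1e-6)), gm, th,
                      merge_distance = 0)
  expect_equal(nrow(r3), 2L)
  expect_setequal(r3$chrom, c("chr1", "chr2"))

  # nothing significant: empty result, not an error
  r4 <- collapse_loci(make_scan(bl, rep(0.5, 4L)), gm, th)
  expect_equal(nrow(r4), 0L)
})

test_that("two planted loci with satellites collapse to exactly two regions", {
  set.seed(211)
  n <- 60L
  starts <- c(0, 1e4, 2e4, 4e6, 4.01e6, 4.02e6)
  bl <- make_blocks_df("chr1", starts, starts + 1e4)
  gA <- rand_dosage(n); gB <- rand_dosage(n)
  gm <- make_gm(bl, rbind(gA, gA, gA, gB, gB, gB), c(chr1 = 5e6))
  p <- c(1e-8, 1e-7, 1e-6, 1e-9, 1e-6, 1e-5)
  th <- make_thresholds(p05 = 1e-4, phenotype = "hr28")
  rg <- collapse_loci(make_scan(bl, p), gm, th, r2_threshold = 0.5,
                      merge_distance = 5e5)
  expect_equal(nrow(rg), 2L)
  expect_setequal(rg$lead_block_id, bl$block_id[c(1L, 4L)])
  expect_equal(sum(rg$n_blocks), 6L)

  # idempotence: collapsing the leads returns the same two leads
  lead_rows <- match(rg$lead_block_id, bl$block_id)
  rg2 <- collapse_loci(make_scan(bl[lead_rows, ], p[lead_rows]),
                       make_gm(bl[lead_rows, ], rbind(gA, gB), c(chr1 = 5e6)),
                       th, r2_threshold = 0.5, merge_distance = 5e5)
  expect_equal(nrow(rg2), 2L)
  expect_setequal(rg2$lead_block_id, rg$lead_block_id)
})

test_that("annotation assigns genes by overlap and conserves totals", {
  rg <- structure(
    data.frame(region_id = c("R001", "R002"), chrom = "chr1",
               start = c(0, 5e5), end = c(1000, 5.02e5),
               lead_block_id = c("b1", "b2"), lead_neg_log10_p = c(8, 5),
               n_blocks = 1L, members = c("b1", "b2"), phenotypes = "hr28",
               stringsAsFactors = FALSE),
    class = c("fine_mapped_regions", "data.frame"))
  genes <- structure(
    data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
               start = c(100, 900, 2e6), end = c(200, 1100, 2.001e6),
               strand = "+", name = c("g1", "g2", "g3"),
               stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame"))
  ann <- annotate_regions(rg, genes)
  # fully inside and boundary-overlap genes included; distant gene not
  expect_equal(ann$n_genes, c(2L, 0L))
  expect_equal(ann$genes[1L], "G1;G2")
  gene_map <- attr(ann, "gene_map")
  expect_equal(sum(ann$n_genes), nrow(gene_map))
  expect_equal(sum(ann$n_genes), length(unique(gene_map$gene_id)))
})

test_that("GFF3 gene records round-trip through the standard parser", {
  genes <- simulate_gene_annotation(tiny_spec(), gene_density = 1 / 1e5,
                                    seed = 221)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(genes, gff, chrom_lengths = c(chr1 = 1e6))
  back <- read_gff_genes(gff)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
})

test_that("candidate ranking is gated at -log10 p > 3 and monotone in evidence", {
  rg <- structure(
    data.frame(region_id = c("R001", "R002", "R003"), chrom = "chr1",
               start = c(0, 1e6, 2e6), end = c(1e4, 1.01e6, 2.01e6),
               lead_block_id = c("b1", "b2", "b3"),
               lead_neg_log10_p = c(6, 6, 3), n_blocks = 1L,
               members = c("b1", "b2", "b3"), phenotypes = "hr28",
               stringsAsFactors = FALSE),
    class = c("fine_mapped_regions", "data.frame"))
  genes <- structure(
    data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
               start = c(100, 1.001e6, 2.001e6), end = c(400, 1.002e6, 2.002e6),
               strand = "+", name = c("g1", "g2", "g3"),
               stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame"))
  ann <- annotate_regions(rg, genes)
  de <- data.frame(gene_id = "G1", log2fc = 2.5, padj = 0.001)
  lof <- data.frame(gene_id = "G1", lof_count = 1L)
  cand <- rank_candidates(ann, de, lof)
  # region at exactly -log10 p = 3 is excluded (strict inequality)
  expect_false("G3" %in% cand$gene_id)
  # equal association, but DE + LoF evidence ranks G1 strictly above G2
  expect_lt(cand$rank[cand$gene_id == "G1"], cand$rank[cand$gene_id == "G2"])
  expect_gt(cand$score[cand$gene_id == "G1"], cand$score[cand$gene_id == "G2"])
  # empty evidence: ordering reduces to lead -log10 p
  cand0 <- rank_candidates(ann, NULL, NULL)
  expect_equal(cand0$rank, seq_len(nrow(cand0)))
  expect_equal(cand0$lead_neg_log10_p, sort(cand0$lead_neg_log10_p, decreasing = TRUE))
  # monotonicity: adding a LoF variant to G2 never lowers its rank
  lof2 <- rbind(lof, data.frame(gene_id = "G2", lof_count = 2L))
  cand2 <- rank_candidates(ann, de, lof2)
  expect_lte(cand2$rank[cand2$gene_id == "G2"],
             cand$rank[cand$gene_id == "G2"])
  # DE gate respects both the FDR and the fold-change cut-offs
  de_weak <- data.frame(gene_id = "G2", log2fc = 0.5, padj = 0.001)
  cand3 <- rank_candidates(ann, de_weak, NULL)
  expect_false(any(cand3$de_flag))
  expect_error(rank_candidates(ann, de, lof, weights = c(0, 0, 0)), "weights")
})
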