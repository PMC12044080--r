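# Genome segmentation at cohort breakpoints and the block genotype matrix.

xo_df <- function(sample, chrom, pos0) {
  k <- length(pos0)
  data.frame(sample = sample, chrom = chrom, pos0 = pos0,
             from = rep("AA", k), to = rep("AB", k),
             distance = rep(1L, k), stringsAsFactors = FALSE)
}

test_that("segmentation merges breakpoints into an exact tiling", {
  lens <- c(chr1 = 50000)
  b0 <- segment_genome(xo_df(character(), character(), numeric()), lens, 10000)
  expect_equal(nrow(b0), 1L)
  expect_equal(c(b0$start, b0$end), c(0, 50000))
  b1 <- segment_genome(xo_df("S1", "chr1", 20000), lens, 10000)
  expect_equal(b1$start, c(0, 20000))
  expect_equal(b1$end, c(20000, 50000))
  b2 <- segment_genome(xo_df(c("S1", "S2"), "chr1", c(20000, 30000)), lens, 10000)
  expect_equal(b2$start, c(0, 20000, 30000))
  expect_error(segment_genome(b1[0, 1:3], lens, 0), "grid")
  expect_error(segment_genome(xo_df("S1", "chr1", 60000), lens, 10000),
               "bounds")
  # partition property on a simulated cohort
  spec <- genome_spec(c(chr1 = 2e6, chr2 = 1.5e6), marker_density = 1 / 1000,
                      crossover_rate = 2)
  mk <- simulate_marker_map(spec, seed = 61)
  tr <- simulate_f2_cohort(mk, 80, spec, seed = 62)
  bl <- segment_genome(true_crossovers(tr), spec$chromosomes, 10000)
  for (cn in names(spec$chromosomes)) {
    b <- bl[bl$chrom == cn, ]
    expect_equal(sum(b$end - b$start), unname(spec$chromosomes[[cn]]))
    expect_equal(b$start[-1L], b$end[-nrow(b)])
    expect_true(all(b$end - b$start >= 10000))
  }
})

test_that("the genotype matrix is the snapped path state over each block", {
  lens <- c(chr1 = 40000)
  # sample 1 constant AA; sample 2 changes AB -> BB at 20000 (on grid)
  st <- cbind(rep(1L, 8L), rep(c(2L, 3L), each = 4L))
  pt <- make_paths(st, lens, window_size = 5000)
  bl <- segment_genome(xo_df("S2", "chr1", 20000), lens, 10000)
  gm <- fill_genotype_matrix(bl, pt)
  expect_equal(unname(gm$states[, 1L]), c(1L, 1L))
  expect_equal(unname(gm$states[, 2L]), c(2L, 3L))
  # dosage coding and completeness
  expect_equal(unname(geno_dosage(gm)[, 2L]), c(1L, 0L))
  expect_equal(length(gm$states), nrow(bl) * 2L)
  expect_false(anyNA(gm$states))
  # a block straddling a state change is an internal-consistency error
  bl_wrong <- segment_genome(xo_df(character(), character(), numeric()),
                             lens, 10000)
  expect_error(fill_genotype_matrix(bl_wrong, pt), "straddles")
})

test_that("block matrices round-trip to window paths when breakpoints are on-grid", {
  spec <- genome_spec(c(chr1 = 2e6, chr2 = 1e6), marker_density = 1 / 1000,
                      coverage = 3, read_error = 0.005, crossover_rate = 2)
  mk <- simulate_marker_map(spec, seed = 71)
  tr <- simulate_f2_cohort(mk, 40, spec, seed = 72)
  ct <- simulate_allele_counts(tr, mk, spec, seed = 73)
  pt <- viterbi_decode(aggregate_windows(ct, 5000),
                       hmm_params(error = 0.01, crossover_rate = 2))
  xo <- call_crossovers(pt)
  bl <- segment_genome(xo, spec$chromosomes, grid = 5000)
  gm <- fill_genotype_matrix(bl, pt)
  back <- expand_blocks_to_windows(gm, 5000)
  expect_identical(unname(back$states), unname(pt$states))
  expect_equal(back$windows$start, pt$windows$start)
})

test_that("segregation diagnostics match the closed-form chi-square", {
  bl <- make_blocks_df("chr1", c(0, 20000), c(20000, 50000))
  dos <- rbind(rep(c(2L, 1L, 0L), c(25L, 50L, 25L)),
               rep(2L, 100L))
  gm <- make_gm(bl, dos, c(chr1 = 50000))
  seg <- segregation_diagnostics(gm)
  expect_equal(seg$chisq[1L], 0)
  expect_equal(seg$p[1L], 1)
  expect_equal(seg$chisq[2L], 300)  # (100-25)^2/25 + 50 + 25
  expect_equal(seg$frac_AA + seg$frac_AB + seg$frac_BB, c(1, 1))
  expect_equal(attr(seg, "aa_excess"), mean(c(0.25, 1)) - 0.25)
})

test_that("chi-square p-values are near-uniform without bias and AA grows with bias", {
  spec <- genome_spec(c(chr1 = 25e6, chr2 = 25e6), marker_density = 1 / 5000,
                      crossover_rate = 1.5)
  mk <- simulate_marker_map(spec, seed = 81)
  tr <- simulate_f2_cohort(mk, 300, spec, seed = 82)
  gm <- genotype_matrix_from_truth(tr, grid = 10000)
  expect_gt(nrow(gm$blocks), 1000)
  seg <- segregation_diagnostics(gm)
  # thin to approximately independent blocks (one per 2 Mb) for the KS test
  keep <- !duplicated(paste(seg$chrom, seg$start %/% 2e6))
  ks <- suppressWarnings(ks.test(seg$p[keep], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(attr(seg, "aa_excess")), 3 * sqrt(0.25 * 0.75 / 300))
})

test_that("median block size shrinks as the cohort grows", {
  spec <- genome_spec(c(chr1 = 10e6), marker_density = 1 / 5000,
                      crossover_rate = 2)
  mk <- simulate_marker_map(spec, seed = 91)
  med_size <- vapply(c(20L, 80L, 320L), function(n) {
    tr <- simulate_f2_cohort(mk, n, spec, seed = 92)
    bl <- segment_genome(true_crossovers(tr), spec$chromosomes, 10000)
    median(bl$end - bl$start)
  }, 0)
  expect_true(all(diff(med_size) < 0))
})
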