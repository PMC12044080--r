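# Forward simulator: marker maps, F2 cohorts, sequencing reads, phenotypes.

test_that("marker maps are Poisson-dense, sorted, unique and deterministic", {
  spec <- tiny_spec()
  mk <- simulate_marker_map(spec, seed = 7)
  # Poisson(1000) count: 4 sigma band
  expect_gt(nrow(mk), 1000 - 4 * sqrt(1000))
  expect_lt(nrow(mk), 1000 + 4 * sqrt(1000))
  expect_false(is.unsorted(mk$pos0, strictly = TRUE))
  expect_true(all(mk$pos0 >= 0 & mk$pos0 < 1e6))
  expect_true(all(mk$allele_A != mk$allele_B))
  expect_identical(mk, simulate_marker_map(spec, seed = 7))
  expect_error(genome_spec(c(chr1 = 1e6), marker_density = 0), "invalid-spec")
  expect_error(genome_spec(c(chr1 = -5), marker_density = 1e-3), "invalid-spec")
})

test_that("F2 genotypes segregate 1:2:1 and agree with the gamete mosaics", {
  spec <- genome_spec(c(chr1 = 1e6), marker_density = 20 / 1e6,
                      crossover_rate = 1.5)
  mk <- simulate_marker_map(spec, seed = 3)
  n <- 5000
  tr <- simulate_f2_cohort(mk, n, spec, seed = 4)
  # per-marker genotype fractions within 3 binomial SE of 1/4, 1/2, 1/4
  frac_AA <- rowMeans(tr$geno == 2L)
  frac_AB <- rowMeans(tr$geno == 1L)
  expect_true(all(abs(frac_AA - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))
  expect_true(all(abs(frac_AB - 0.50) < 3 * sqrt(0.50 * 0.50 / n)))
  # truth consistency: genotypes re-derived from the stored gametes
  rebuilt <- true_genotype_at(tr, "chr1", mk$pos0)
  expect_identical(rebuilt, tr$geno)
  # breakpoints sorted and inside chromosome bounds
  for (s in sample(tr$samples, 50)) {
    for (g in tr$gametes[[s]]$chr1[c("g1", "g2")]) {
      expect_false(is.unsorted(g$bp))
      expect_true(all(g$bp >= 0 & g$bp <= 1e6))
    }
  }
  expect_error(simulate_f2_cohort(mk, 0, spec), "invalid-argument")
})

test_that("zero crossover rate yields whole-chromosome F2 segregation", {
  spec <- genome_spec(c(chr1 = 1e6), marker_density = 30 / 1e6,
                      crossover_rate = 0)
  mk <- simulate_marker_map(spec, seed = 5)
  tr <- simulate_f2_cohort(mk, 400, spec, seed = 6)
  # every individual constant along the chromosome
  expect_true(all(apply(tr$geno, 2L, function(g) length(unique(g))) == 1L))
  first <- tr$geno[1L, ]
  frac <- tabulate(first + 1L, 3L) / length(first)  # BB, AB, AA
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < 3 * sqrt(0.375 / 400)))
})

test_that("allele counts follow the Poisson-depth binomial-read model", {
  spec <- genome_spec(c(chr1 = 1e7), marker_density = 1 / 1000,
                      coverage = 0.78, read_error = 0.01)
  mk <- simulate_marker_map(spec, seed = 11)
  tr <- simulate_f2_cohort(mk, 2, spec, seed = 12)
  ct <- simulate_allele_counts(tr, mk, spec, seed = 13)
  m <- nrow(mk) * 2
  expect_lt(abs(mean(ct$nA + ct$nB) - 0.78), 3 * sqrt(0.78 / m))
  expect_identical(ct$nA,
                   simulate_allele_counts(tr, mk, spec, seed = 13)$nA)
  # coverage 0: empty sequencing
  spec0 <- genome_spec(c(chr1 = 1e7), marker_density = 1 / 1000, coverage = 0)
  ct0 <- simulate_allele_counts(tr, mk, spec0, seed = 13)
  expect_true(all(ct0$nA == 0L & ct0$nB == 0L))
  # error-free limit: AA genotypes only ever emit A reads
  specE <- genome_spec(c(chr1 = 1e7), marker_density = 1 / 1000,
                       coverage = 2, read_error = 0)
  ctE <- simulate_allele_counts(tr, mk, specE, seed = 14)
  expect_true(all(ctE$nB[tr$geno == 2L] == 0L))
  expect_true(all(ctE$nA[tr$geno == 0L] == 0L))
})

test_that("reference bias monotonically raises the A-read fraction at AB sites", {
  spec <- genome_spec(c(chr1 = 5e6), marker_density = 1 / 1000, coverage = 2)
  mk <- simulate_marker_map(spec, seed = 21)
  tr <- simulate_f2_cohort(mk, 20, spec, seed = 22)
  frac_A_het <- vapply(c(0, 0.1, 0.2), function(delta) {
    sp <- genome_spec(c(chr1 = 5e6), marker_density = 1 / 1000, coverage = 2,
                      ref_bias = delta)
    ct <- simulate_allele_counts(tr, mk, sp, seed = 23)
    het <- tr$geno == 1L
    sum(ct$nA[het]) / sum((ct$nA + ct$nB)[het])
  }, 0)
  expect_true(all(diff(frac_A_het) > 0))
})

test_that("phenotypes follow the additive QTL model with arrhythmia halving", {
  spec <- tiny_spec()
  mk <- simulate_marker_map(spec, seed = 31)
  tr <- simulate_f2_cohort(mk, 120, spec, seed = 32)
  # degenerate generative model: exact baselines
  ph0 <- simulate_phenotypes(tr, qtls = NULL, noise_sd = 0,
                             arrhythmia_rate = 0, seed = 33)
  expect_equal(ph0$hr21, rep(90, 120))
  expect_equal(ph0$hr35, rep(170, 120))
  # additive coding: dosage difference 2 between AA and BB
  q <- qtl_spec("chr1", 5e5, additive = 10)
  ph1 <- simulate_phenotypes(tr, q, noise_sd = 0, arrhythmia_rate = 0,
                             seed = 34)
  dos <- qtl_genotypes(tr, q)[1L, ]
  expect_equal(mean(ph1$hr28[dos == 2L]) - mean(ph1$hr28[dos == 0L]), 20)
  # arrhythmia: recorded rate is half the latent rate, flag set
  ph2 <- simulate_phenotypes(tr, q, noise_sd = 5, arrhythmia_rate = 1,
                             seed = 35)
  expect_true(all(ph2$arrhythmia))
  expect_equal(as.numeric(ph2$hr21), unname(attr(ph2, "latent")[, 1L]) / 2)
  expect_error(simulate_phenotypes(tr, noise_sd = -1), "invalid")
})
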