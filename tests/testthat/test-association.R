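# Variance phenotype, kinship, mixed-model scan and permutation thresholds.

sim_truth_gm <- function(n, seed, lens = c(chr1 = 10e6, chr2 = 10e6),
                         density = 1 / 5000, xrate = 1.5, grid = 10000) {
  spec <- genome_spec(lens, marker_density = density, crossover_rate = xrate)
  mk <- simulate_marker_map(spec, seed = seed)
  tr <- simulate_f2_cohort(mk, n, spec, seed = seed + 1L)
  list(spec = spec, truth = tr, gm = genotype_matrix_from_truth(tr, grid))
}

test_that("the variance phenotype is the mean absolute pairwise difference", {
  ph <- data.frame(sample = c("a", "b", "c"),
                   hr21 = c(120, 100, 100), hr28 = c(120, 140, 220),
                   hr35 = c(120, 220, 140))
  v <- variance_phenotype(ph)
  expect_equal(unname(v), c(0, 80, 80))  # constant; (40+120+80)/3; permuted
  # alternative dispersion summaries behind the flag
  expect_equal(unname(variance_phenotype(ph, "range")), c(0, 120, 120))
  expect_equal(unname(variance_phenotype(ph, "variance")),
               c(0, var(c(100, 140, 220)), var(c(100, 220, 140))))
  ph$hr28[2L] <- NA
  expect_message(v2 <- variance_phenotype(ph), "excluded")
  expect_named(v2, c("a", "c"))
})

test_that("kinship is a symmetric PSD matrix of standardized dosages", {
  sim <- sim_truth_gm(80, seed = 101)
  K <- estimate_kinship(sim$gm)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_lt(abs(mean(diag(K)) - 1), 0.1)
  # identical dosage profiles give K12 = K11
  bl <- make_blocks_df("chr1", c(0, 20000), c(20000, 40000))
  dos <- matrix(c(2L, 2L, 0L, 1L, 1L, 2L), nrow = 2L, byrow = TRUE)
  gm2 <- make_gm(bl, cbind(dos[, 1L], dos[, 1L], dos[, 2L], dos[, 3L]),
                 c(chr1 = 40000))
  K2 <- estimate_kinship(gm2)
  expect_equal(K2[1L, 2L], K2[1L, 1L])
  # all-monomorphic input is degenerate
  gm3 <- make_gm(bl, matrix(1L, 2L, 4L), c(chr1 = 40000))
  expect_error(estimate_kinship(gm3), "monomorphic")
})

test_that("the zero-kinship limit reproduces closed-form OLS tests", {
  sim <- sim_truth_gm(60, seed = 111, lens = c(chr1 = 10e6))
  gm <- sim$gm
  set.seed(112)
  y <- rnorm(60, 130, 10)
  sc <- lmm_scan(gm, y, K = NULL, phenotype_name = "hr28")
  dose <- geno_dosage(gm)
  for (i in sample(nrow(gm$blocks), 25L)) {
    g <- dose[i, ]
    if (sd(g) == 0) next
    fit <- summary(lm(y ~ g))
    expect_equal(sc$p[i], fit$coefficients["g", "Pr(>|t|)"], tolerance = 1e-8)
    expect_equal(sc$beta[i], fit$coefficients["g", "Estimate"], tolerance = 1e-8)
  }
  expect_equal(attr(sc, "h2"), 0)
})

test_that("a noiseless planted signal is recovered exactly", {
  sim <- sim_truth_gm(50, seed = 121, lens = c(chr1 = 10e6))
  gm <- sim$gm
  j <- which.max(apply(geno_dosage(gm), 1L, sd))
  y <- 5 * geno_dosage(gm)[j, ]
  sc <- lmm_scan(gm, y, K = NULL)
  expect_equal(sc$p[j], min(sc$p))
  expect_equal(sc$beta[j], 5, tolerance = 1e-6)
  expect_true(all(sc$p > 0 & sc$p <= 1))
  expect_equal(sc$neg_log10_p, -log10(sc$p))
})

test_that("jointly relabeling individuals leaves all p-values unchanged", {
  sim <- sim_truth_gm(60, seed = 131)
  gm <- sim$gm
  K <- estimate_kinship(gm)
  set.seed(132)
  y <- rnorm(60) + 0.5 * geno_dosage(gm)[10L, ]
  sc1 <- lmm_scan(gm, y, K)
  perm <- sample(60L)
  gm_p <- gm
  gm_p$states <- gm$states[, perm]
  gm_p$samples <- gm$samples[perm]
  sc2 <- lmm_scan(gm_p, y[perm], estimate_kinship(gm_p))
  expect_equal(sc2$p, sc1$p, tolerance = 1e-10)
  expect_equal(attr(sc2, "h2"), attr(sc1, "h2"), tolerance = 1e-6)
})

test_that("non-finite phenotypes are rejected", {
  sim <- sim_truth_gm(20, seed = 141, lens = c(chr1 = 5e6))
  expect_error(lmm_scan(sim$gm, c(rep(1, 19), NA)), "finite")
  expect_error(lmm_scan(sim$gm, rep(1, 7)), "finite|per individual")
})

test_that("permutation thresholds are deterministic and reject n_perm < 1", {
  sim <- sim_truth_gm(60, seed = 151, lens = c(chr1 = 10e6))
  gm <- sim$gm
  set.seed(152)
  y <- rnorm(60, 130, 10)
  th1 <- permutation_thresholds(gm, y, NULL, n_perm = 20, seed = 153)
  th2 <- permutation_thresholds(gm, y, NULL, n_perm = 20, seed = 153)
  expect_identical(th1, th2)
  expect_gte(th1$neg_log10_p[th1$level == 0.01],
             th1$neg_log10_p[th1$level == 0.05])
  expect_error(permutation_thresholds(gm, y, NULL, n_perm = 0), "n_perm")
})

test_that("the scan is calibrated on effectively independent null blocks", {
  sim <- sim_truth_gm(150, seed = 161, lens = c(chr1 = 25e6, chr2 = 25e6))
  gm <- sim$gm
  K <- estimate_kinship(gm)
  set.seed(162)
  hits <- 0L; tot <- 0L
  for (rep in 1:8) {
    y <- rnorm(150, 130, 10)
    sc <- lmm_scan(gm, y, K)
    keep <- !duplicated(paste(sc$chrom, sc$start %/% 2e6))
    hits <- hits + sum(sc$p[keep] <= 0.05)
    tot <- tot + sum(keep)
  }
  frac <- hits / tot
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / tot))
})
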