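# Single-variance-component linear mixed model association scan over
# recombination blocks, in the EMMA/EMMAX style: the polygenic variance
# ratio h2 is estimated once on the null model by restricted maximum
# likelihood over a grid with local refinement (one eigendecomposition of
# the kinship matrix), then every block's additive dosage is tested by
# generalized least squares under the fitted covariance, and significance
# thresholds are set by phenotype permutation.

#' Dispersion summary of repeated heart-rate measurements
#'
#' Collapses the three per-temperature rates of each individual into one
#' dispersion score. The default is the mean absolute pairwise difference
#' `(|x21-x28| + |x21-x35| + |x28-x35|) / 3`; `"range"` (max minus min) and
#' `"variance"` (sample variance) are available alternatives. Individuals
#' with any missing measurement are excluded with a message.
#'
#' @param phenotypes A `phenotype_table` (or any data frame with columns
#'   `sample`, `hr21`, `hr28`, `hr35`).
#' @param method One of `"pairwise"`, `"range"`, `"variance"`.
#' @return Named numeric vector (one value per retained individual).
#' @export
variance_phenotype <- function(phenotypes,
                               method = c("pairwise", "range", "variance")) {
  method <- match.arg(method)
  x <- as.matrix(phenotypes[, c("hr21", "hr28", "hr35")])
  ok <- complete.cases(x)
  if (!all(ok)) {
    message(sum(!ok), " individual(s) excluded from the variance phenotype ",
            "(missing measurements)")
  }
  x <- x[ok, , drop = FALSE]
  val <- switch(method,
    pairwise = (abs(x[, 1] - x[, 2]) + abs(x[, 1] - x[, 3]) +
                abs(x[, 2] - x[, 3])) / 3,
    range = apply(x, 1L, max) - apply(x, 1L, min),
    variance = apply(x, 1L, var))
  setNames(val, phenotypes$sample[ok])
}

#' Genomic kinship from standardized block dosages
#'
#' `K = Z %*% t(Z) / m` where `Z` is the individuals-by-blocks dosage
#' matrix with each block column centered and scaled to unit variance
#' (monomorphic blocks are skipped). `K` is symmetric positive
#' semi-definite up to numerical tolerance.
#'
#' @param gm A `genotype_matrix` with at least two individuals.
#' @return An n-by-n kinship matrix with attribute `m` (blocks used).
#' @export
estimate_kinship <- function(gm) {
  if (length(gm$samples) < 2L) stopf("invalid-argument: need >= 2 individuals")
  Z <- t(geno_dosage(gm))            # individuals x blocks
  svec <- apply(Z, 2L, sd)
  keep <- which(svec > 0)
  if (!length(keep)) stopf("degenerate-input: all blocks are monomorphic")
  Z <- scale(Z[, keep, drop = FALSE])
  K <- tcrossprod(Z) / length(keep)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(gm$samples, gm$samples)
  attr(K, "m") <- length(keep)
  K
}

# Restricted log-likelihood of the null model y = mu + u + e with
# cov = sigma2 * (h2 K + (1-h2) I), profiled over sigma2, on the rotated
# scale (U'y, U'X).
reml_loglik <- function(h2, yr, xr, lambda) {
  n <- length(yr)
  d <- h2 * lambda + (1 - h2)
  w <- 1 / d
  xtx <- sum(w * xr^2)
  beta <- sum(w * xr * yr) / xtx
  rss <- sum(w * (yr - xr * beta)^2)
  -0.5 * ((n - 1) * log(2 * pi * rss / (n - 1)) + (n - 1) +
            sum(log(d)) + log(xtx))
}

# Null-model REML fit: eigendecompose K once, maximize over h2 on a grid
# with local refinement. Returns the rotation and fitted weights reused by
# the per-block scan and the permutations.
lmm_null_fit <- function(y, K) {
  n <- length(y)
  if (is.null(K)) K <- matrix(0, n, n)
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  xr <- drop(crossprod(U, rep(1, n)))
  if (all(lambda <= 1e-12)) {
    # no genetic covariance: the model is ordinary least squares (h2 = 0)
    return(list(U = U, lambda = lambda, h2 = 0, d = rep(1, n),
                yr = yr, xr = xr))
  }
  grid <- seq(0, 0.99, by = 0.01)
  ll <- vapply(grid, reml_loglik, 0, yr = yr, xr = xr, lambda = lambda)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  h2 <- if (hi > lo) {
    opt <- optimize(reml_loglik, c(lo, hi), maximum = TRUE,
                    yr = yr, xr = xr, lambda = lambda, tol = 1e-6)
    if (opt$objective > ll[i]) opt$maximum else grid[i]
  } else grid[i]
  d <- h2 * lambda + (1 - h2)
  list(U = U, lambda = lambda, h2 = h2, d = d, yr = yr, xr = xr)
}

# Vectorized per-block GLS Wald tests under fixed weights. Gr is the
# rotated blocks-by-individuals dosage matrix transposed to individuals x
# blocks. Returns beta, se, p per block.
scan_core <- function(yr, xr, Gr, w, n) {
  a11 <- sum(w * xr^2)
  a12 <- colSums(w * xr * Gr)
  a22 <- colSums(w * Gr^2)
  b1 <- sum(w * xr * yr)
  b2 <- colSums(w * Gr * yr)
  det <- a11 * a22 - a12^2
  mono <- det <= .Machine$double.eps * a11 * pmax(a22, 1)
  det[mono] <- NA_real_
  beta1 <- (a22 * b1 - a12 * b2) / det
  beta2 <- (a11 * b2 - a12 * b1) / det
  rss <- sum(w * yr^2) - (beta1 * b1 + beta2 * b2)
  rss <- pmax(rss, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a11 / det)
  tstat <- beta2 / se
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[mono] <- 1
  beta2[mono] <- 0
  se[mono] <- NA_real_
  p[p <= 0] <- .Machine$double.xmin   # keep p in (0, 1]
  list(beta = beta2, se = se, p = p)
}

#' Mixed-model association scan over recombination blocks
#'
#' Fits the null model `y = mu + u + e`, `u ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)` by REML over `h2 = sigma_g^2 /
#' (sigma_g^2 + sigma_e^2)` (grid plus local refinement, one
#' eigendecomposition of `K`), then tests each block's additive dosage by
#' generalized least squares Wald tests with the variance components held
#' fixed across blocks. With `K = NULL` (or a zero matrix) the scan
#' reduces exactly to ordinary least squares.
#'
#' @param gm A `genotype_matrix`.
#' @param phenotype Numeric phenotype vector, one finite value per
#'   individual (order of `gm$samples`), or a named vector matched by name.
#' @param K Kinship matrix from [estimate_kinship()], or `NULL`.
#' @param phenotype_name Label stored in the output.
#' @return An `association_scan` data frame (`block_id`, `chrom`, `start`,
#'   `end`, `phenotype`, `beta`, `se`, `p`, `neg_log10_p`) with attributes
#'   `h2` (the REML estimate) and `n`.
#' @export
lmm_scan <- function(gm, phenotype, K = NULL, phenotype_name = "trait") {
  n <- length(gm$samples)
  if (!is.null(names(phenotype))) phenotype <- phenotype[gm$samples]
  if (length(phenotype) != n || any(!is.finite(phenotype))) {
    stopf("input error: phenotype must hold one finite value per individual")
  }
  fit <- lmm_null_fit(phenotype, K)
  if (fit$h2 >= 0.99) message("heritability estimate at the grid boundary (h2 = 0.99)")
  w <- 1 / fit$d
  Gr <- crossprod(fit$U, t(geno_dosage(gm)))   # individuals x blocks (rotated)
  res <- scan_core(fit$yr, fit$xr, Gr, w, n)
  out <- data.frame(block_id = gm$blocks$block_id, chrom = gm$blocks$chrom,
                    start = gm$blocks$start, end = gm$blocks$end,
                    phenotype = phenotype_name,
                    beta = res$beta, se = res$se, p = res$p,
                    neg_log10_p = -log10(res$p),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, h2 = fit$h2, n = n,
            class = c("association_scan", "data.frame"))
}

#' Permutation-based FDR significance thresholds
#'
#' Permutes the phenotype across individuals `n_perm` times, re-scanning
#' each permutation with the variance components of the unpermuted null
#' fit. For a candidate threshold `t` (the observed p-values), the
#' estimated FDR is the mean permuted discovery count at `t` divided by
#' the observed discovery count at `t`; the reported threshold per level
#' is the most lenient such `t` (the largest p-value cut-off) whose
#' estimated FDR is at or below the level, the standard choice that
#' maximizes discoveries under the FDR budget. When no candidate
#' qualifies, a finite sentinel stricter than every observed and permuted
#' p-value is reported, so no block passes. The threshold for the
#' stricter level is clamped to be at least that of the looser level.
#'
#' @param gm A `genotype_matrix`.
#' @param phenotype Phenotype vector as in [lmm_scan()].
#' @param K Kinship matrix or `NULL`.
#' @param n_perm Number of permutations (>= 1).
#' @param levels FDR levels, default `c(0.01, 0.05)`.
#' @param seed Integer seed; identical seeds give identical thresholds.
#' @param phenotype_name Label stored in the output.
#' @return An `fdr_thresholds` data frame (`level`, `p_threshold`,
#'   `neg_log10_p`) with attributes `n_perm`, `seed`, `phenotype`.
#' @export
permutation_thresholds <- function(gm, phenotype, K = NULL, n_perm = 100,
                                   levels = c(0.01, 0.05), seed = NULL,
                                   phenotype_name = "trait") {
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    stopf("invalid-argument: 'n_perm' must be >= 1")
  }
  n_perm <- as.integer(n_perm)
  if (any(levels <= 0 | levels >= 1)) stopf("invalid-argument: levels must lie in (0, 1)")
  n <- length(gm$samples)
  if (!is.null(names(phenotype))) phenotype <- phenotype[gm$samples]
  fit <- lmm_null_fit(phenotype, K)
  w <- 1 / fit$d
  Gr <- crossprod(fit$U, t(geno_dosage(gm)))
  p_obs <- scan_core(fit$yr, fit$xr, Gr, w, n)$p
  p_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- phenotype[sample.int(n)]
      scan_core(drop(crossprod(fit$U, yp)), fit$xr, Gr, w, n)$p
    }, numeric(length(p_obs)))
  })
  p_perm_sorted <- sort(as.numeric(p_perm))
  cand <- sort(unique(p_obs))
  n_perm_le <- findInterval(cand, p_perm_sorted) / n_perm
  n_obs_le <- findInterval(cand, sort(p_obs))
  fdr <- n_perm_le / pmax(1, n_obs_le)
  pick <- function(level) {
    ok <- which(fdr <= level)
    if (!length(ok)) min(c(p_obs, p_perm_sorted[1L])) / 10 else cand[max(ok)]
  }
  levels <- sort(levels, decreasing = TRUE)   # looser level first
  thr <- vapply(levels, pick, 0)
  if (length(thr) > 1L) thr <- cummin(thr)    # stricter levels at least as strict
  out <- data.frame(level = levels, p_threshold = thr,
                    neg_log10_p = -log10(thr),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$level), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_perm = n_perm, seed = seed, phenotype = phenotype_name,
            class = c("fdr_thresholds", "data.frame"))
}

#' Look up one level's p-value threshold
#'
#' @param thresholds An `fdr_thresholds` object.
#' @param level FDR level (must be one of the computed levels).
#' @return The p-value threshold (scalar).
#' @export
threshold_at <- function(thresholds, level) {
  i <- which(abs(thresholds$level - level) < 1e-12)
  if (!length(i)) stopf("invalid-argument: level %g was not computed", level)
  thresholds$p_threshold[i]
}
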