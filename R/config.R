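# Analysis configuration: one validated object holding every stage's
# parameters and seeds, loadable from YAML.

#' Build an analysis configuration
#'
#' Collects the parameters of the full simulate - genotype - blocks -
#' scan - finemap - rank chain. All defaults are the package's scaled
#' study design: two 25 Mb chromosomes, one marker per kb, 0.78x coverage,
#' 300 individuals, 5 kb HMM windows, 10 kb segmentation grid, 100
#' permutations at FDR levels 1% and 5%, LD pruning at r^2 0.5 within
#' 500 kb, candidate filter -log10 p > 3 with DE gates FDR 0.01 / fold
#' change 2. Seeds are explicit; there is no wall-clock seeding.
#'
#' @param genome A [genome_spec()].
#' @param n_individuals Cohort size.
#' @param qtls Optional [qtl_spec()] of planted QTLs.
#' @param baselines,noise_sd,arrhythmia_rate Phenotype-generator settings
#'   (see [simulate_phenotypes()]).
#' @param window_size,hmm_error HMM settings (see [hmm_params()]).
#' @param grid Segmentation grid in bp.
#' @param phenotypes Phenotypes to scan; subset of
#'   `c("hr21", "hr28", "hr35", "variance")`.
#' @param n_perm Permutations per phenotype.
#' @param fdr_levels Permutation-FDR levels.
#' @param fdr_level FDR level used for collapsing.
#' @param r2_threshold,merge_distance LD-collapse settings.
#' @param min_log10p,de_fdr,de_fc Candidate-selection thresholds.
#' @param seed Base seed; per-stage seeds are derived from it.
#' @param gff,de_table,lof_table Optional paths to a GFF3 annotation and
#'   evidence TSVs (`gene_id`, `log2fc`, `padj` / `gene_id`, `lof_count`).
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(genome = default_genome_spec(),
                            n_individuals = 300,
                            qtls = NULL,
                            baselines = c(hr21 = 90, hr28 = 130, hr35 = 170),
                            noise_sd = 10,
                            arrhythmia_rate = 0.01,
                            window_size = 5000,
                            hmm_error = 0.02,
                            grid = 10000,
                            phenotypes = c("hr21", "hr28", "hr35", "variance"),
                            n_perm = 100,
                            fdr_levels = c(0.01, 0.05),
                            fdr_level = 0.05,
                            r2_threshold = 0.5,
                            merge_distance = 5e5,
                            min_log10p = 3,
                            de_fdr = 0.01,
                            de_fc = 2,
                            seed = 1,
                            gff = NULL,
                            de_table = NULL,
                            lof_table = NULL) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  if (!inherits(cfg$genome, "genome_spec")) {
    stopf("config validation error: field 'genome' must be a genome_spec")
  }
  check_scalar_number(cfg$n_individuals, "n_individuals", lower = 1)
  check_scalar_number(cfg$n_perm, "n_perm", lower = 1)
  check_scalar_number(cfg$grid, "grid", lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$seed, "seed", lower = -2^31, upper = 2^31)
  if (any(cfg$fdr_levels <= 0 | cfg$fdr_levels >= 1)) {
    stopf("config validation error: field 'fdr_levels' must lie in (0, 1)")
  }
  if (!cfg$fdr_level %in% cfg$fdr_levels) {
    stopf("config validation error: field 'fdr_level' must be one of 'fdr_levels'")
  }
  bad <- setdiff(cfg$phenotypes, c("hr21", "hr28", "hr35", "variance"))
  if (length(bad)) {
    stopf("config validation error: unknown phenotype(s) in field 'phenotypes': %s",
          paste(bad, collapse = ", "))
  }
  for (f in c("gff", "de_table", "lof_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stopf("config validation error: field '%s' names a missing file: %s",
            f, cfg[[f]])
    }
  }
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Scalar fields map one-to-one onto [analysis_config()] arguments; the
#' genome is given as a `genome:` mapping (`chromosomes:` name-length
#' pairs plus the [genome_spec()] scalars) and planted QTLs as a list of
#' `chrom`/`pos0`/`additive`/`dominance` mappings.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$genome)) {
    g <- y$genome
    args$genome <- genome_spec(
      chromosomes = unlist(g$chromosomes),
      marker_density = g$marker_density %||% 1 / 1000,
      coverage = g$coverage %||% 0.78,
      read_error = g$read_error %||% 0.01,
      ref_bias = g$ref_bias %||% 0,
      crossover_rate = g$crossover_rate %||% 1.5)
  }
  if (!is.null(y$qtls)) {
    args$qtls <- do.call(rbind, lapply(y$qtls, function(q) {
      qtl_spec(q$chrom, q$pos0, unlist(q$additive),
               unlist(q$dominance %||% 0))
    }))
  }
  scalars <- c("n_individuals", "noise_sd", "arrhythmia_rate", "window_size",
               "hmm_error", "grid", "n_perm", "fdr_level", "r2_threshold",
               "merge_distance", "min_log10p", "de_fdr", "de_fc", "seed",
               "gff", "de_table", "lof_table")
  for (f in scalars) if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$baselines)) args$baselines <- unlist(y$baselines)
  if (!is.null(y$fdr_levels)) args$fdr_levels <- unlist(y$fdr_levels)
  if (!is.null(y$phenotypes)) args$phenotypes <- unlist(y$phenotypes)
  do.call(analysis_config, args)
}
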