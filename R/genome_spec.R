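#' Specify the genome and sequencing regime of a simulated cross
#'
#' Bundles the parameters that define a simulated F2 intercross: chromosome
#' lengths, expected marker density, sequencing depth, per-read error, a
#' signed reference-bias shift, and the meiotic crossover rate. The defaults
#' (see [default_genome_spec()]) are a desk-scale analogue of a large
#' low-pass intercross: two 25 Mb chromosomes at one marker per kb,
#' sequenced at 0.78x.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param marker_density Expected markers per bp (e.g. `1/1000`).
#' @param coverage Expected reads overlapping a marker site (dimensionless
#'   depth; `0.78` emulates ultra-low-pass sequencing).
#' @param read_error Probability that a read reports the wrong allele;
#'   must lie in `[0, 0.5)`.
#' @param ref_bias Signed shift `delta` in `(-0.5, 0.5)` added to the
#'   probability that a sampled read supports allele A. Positive values
#'   over-represent AA calls, emulating reference bias toward the
#'   non-reference founder when its reads align preferentially.
#' @param crossover_rate Expected crossovers per gamete per chromosome
#'   (Poisson mean; no interference).
#'
#' @return An object of class `genome_spec`.
#' @seealso [simulate_marker_map()], [simulate_f2_cohort()]
#' @export
genome_spec <- function(chromosomes,
                        marker_density,
                        coverage = 0.78,
                        read_error = 0.01,
                        ref_bias = 0,
                        crossover_rate = 1.5) {
  if (!is.numeric(chromosomes) || length(chromosomes) < 1L ||
      is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    stopf("invalid-spec: 'chromosomes' must be a named numeric vector of lengths")
  }
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0)) {
    stopf("invalid-spec: chromosome lengths must be positive")
  }
  if (anyDuplicated(names(chromosomes))) {
    stopf("invalid-spec: duplicated chromosome names")
  }
  check_scalar_number(marker_density, "marker_density", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(coverage, "coverage", lower = 0)
  check_scalar_number(read_error, "read_error", lower = 0, upper = 0.5,
                      strict_upper = TRUE)
  check_scalar_number(ref_bias, "ref_bias", lower = -0.5, upper = 0.5,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(crossover_rate, "crossover_rate", lower = 0)
  structure(
    list(chromosomes = chromosomes,
         marker_density = marker_density,
         coverage = coverage,
         read_error = read_error,
         ref_bias = ref_bias,
         crossover_rate = crossover_rate),
    class = "genome_spec"
  )
}

#' Default desk-scale genome specification
#'
#' Two 25 Mb chromosomes, one marker per kb, 0.78x coverage, 1% read error,
#' no reference bias, 1.5 crossovers per gamete per chromosome.
#'
#' @param ... Overrides passed to [genome_spec()].
#' @return A `genome_spec`.
#' @export
default_genome_spec <- function(...) {
  args <- list(chromosomes = c(chr1 = 25e6, chr2 = 25e6),
               marker_density = 1 / 1000,
               coverage = 0.78,
               read_error = 0.01,
               ref_bias = 0,
               crossover_rate = 1.5)
  over <- list(...)
  args[names(over)] <- over
  do.call(genome_spec, args)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chromosomes), "chromosome(s),",
      fmt_num(sum(x$chromosomes) / 1e6), "Mb total\n")
  cat("  marker_density:", fmt_num(x$marker_density),
      " coverage:", fmt_num(x$coverage),
      " read_error:", fmt_num(x$read_error), "\n")
  cat("  ref_bias:", fmt_num(x$ref_bias),
      " crossover_rate:", fmt_num(x$crossover_rate), "\n")
  invisible(x)
}
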