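# Shared internal helpers: state coding, validation, deterministic formatting.

# Genotype states are coded 1 = AA, 2 = AB, 3 = BB throughout; AA is the
# non-reference founder state, BB the reference founder state. The additive
# dosage is the count of A alleles: AA = 2, AB = 1, BB = 0.
GENO_STATES <- c("AA", "AB", "BB")

state_to_dosage <- function(state) 3L - as.integer(state)

dosage_to_state <- function(dosage) 3L - as.integer(dosage)

state_labels <- function(state) GENO_STATES[as.integer(state)]

state_codes <- function(labels) {
  code <- match(labels, GENO_STATES)
  if (anyNA(code)) {
    stop("unknown genotype state label(s): ",
         paste(unique(labels[is.na(code)]), collapse = ", "))
  }
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("invalid-spec: '%s' must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("invalid-spec: '%s' = %g is outside its valid range", name, x)
  }
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stopf("invalid-argument: 'seed' must be a single finite number")
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

# Deterministic text representation for floating-point fields (10 significant
# digits) so reruns with identical inputs produce byte-identical files.
fmt_num <- function(x) {
  out <- formatC(signif(as.numeric(x), digits = 10L), format = "g",
                 digits = 10L, width = 1L)
  out[!is.finite(as.numeric(x))] <- as.character(x[!is.finite(as.numeric(x))])
  gsub(" ", "", out)
}

# Snap a position to the nearest grid multiple, half-up.
snap_to_grid <- function(pos, grid) floor(pos / grid + 0.5) * grid

chrom_lengths_of <- function(x) {
  len <- attr(x, "chrom_lengths")
  if (is.null(len)) stopf("object carries no 'chrom_lengths' attribute")
  len
}
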