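---
title: "Recombination-block QTL mapping for low-coverage F2 intercrosses"
author: "blockqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination-block QTL mapping for low-coverage F2 intercrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockqtl)
```

## The design

An F2 intercross of two inbred founder strains is the classical engine for
mapping quantitative traits: every F2 individual carries a unique mosaic of
the two founder genomes produced by one round of meiotic recombination per
gamete. When the founders are fully inbred, any SNP at which they are
homozygous for different alleles (a *homozygous-divergent* marker) reads
out the local founder origin unambiguously — each F2 genotype is AA, AB or
BB, where A denotes the non-reference founder allele and B the
reference-strain allele. Sequencing each embryo at a fraction of 1x
coverage is enough, because genotypes are not called per site: information
is pooled along the chromosome, first into fixed windows and then across
the cohort into recombination blocks.

`blockqtl` implements this chain end to end:

1. **Windowed observations.** Per-marker allele counts are summed in fixed
   5 kb windows (`aggregate_windows()`). At 0.78x coverage and one marker
   per kb a window holds about four reads.
2. **Three-state HMM.** `viterbi_decode()` finds each individual's most
   probable AA/AB/BB path and `call_crossovers()` places breakpoints at
   window boundaries.
3. **Recombination blocks.** Cohort breakpoints, snapped to a 10 kb grid,
   segment the genome into blocks within which no individual recombines
   (`segment_genome()`, `fill_genotype_matrix()`); 1:2:1 segregation
   diagnostics flag reference bias (`segregation_diagnostics()`).
4. **Mixed-model scan.** Every block's additive dosage is tested against
   each phenotype with a single-variance-component linear mixed model
   (`lmm_scan()`), with significance thresholds set by phenotype
   permutation (`permutation_thresholds()`).
5. **Fine mapping.** Significant blocks collapse into distinct regions by
   LD clumping (`collapse_loci()`), regions are annotated with genes
   (`annotate_regions()`) and candidates ranked with differential
   expression and loss-of-function evidence (`rank_candidates()`).

A forward simulator (`simulate_marker_map()`, `simulate_f2_cohort()`,
`simulate_allele_counts()`, `simulate_phenotypes()`) generates
truth-labelled inputs under the same design, so every stage is validated
against a known answer.

## The hidden Markov model

The hidden chain per individual and chromosome is the diploid genotype
over consecutive windows. Because an F2 genotype is the union of two
independent gametes, each recombining with per-window probability $r$,
the transition matrix between adjacent windows is

$$
P = \begin{pmatrix}
(1-r)^2 & 2r(1-r) & r^2 \\
r(1-r) & (1-r)^2 + r^2 & r(1-r) \\
r^2 & 2r(1-r) & (1-r)^2
\end{pmatrix},
\qquad \pi = (\tfrac14, \tfrac12, \tfrac14),
$$

with states ordered (AA, AB, BB) and the Mendelian prior as initial
distribution. The default $r$ is derived as
`crossover_rate * window_size / chromosome_length`; it is clamped to
$[10^{-9}, 0.5)$ so that log-space arithmetic never meets a zero
transition probability.

**Emission.** A window with $n = n_A + n_B$ reads emits
$n_A \sim \mathrm{Binomial}(n, p_A)$ with $p_A = 1-e$, $0.5$, $e$ for AA,
AB, BB, where $e$ (default 0.02) absorbs sequencing error, mismapping and
light reference bias. We deliberately emit on the raw counts rather than
on the proportion $n_A/n$: at 0.78x most windows hold 0–5 reads, and the
proportion destroys depth information (one read of A and ten reads of A
give the same proportion but very different evidence). Empty windows emit
likelihood one for every state and are decoded rather than dropped, which
keeps paths coordinate-addressable and lets transitions bridge coverage
gaps. Decoding is exact Viterbi in log space; ties prefer the same-state
predecessor so that an exact score tie never fabricates a crossover. No
emission/transition re-estimation is performed by default: $e$ and $r$
are explicit parameters with stated defaults, which keeps decoding
deterministic and auditable.

The decoder is validated two ways: against exhaustive enumeration of all
$3^T$ paths on random instances with up to eight windows (log-probability
agreement to $10^{-9}$), and against simulation truth, where deep
error-free data must reproduce every window state and localize every
isolated crossover to within one window.

## Blocks and the segregation diagnostics

Crossover positions are snapped to the segmentation grid (default 10 kb,
the mapping resolution; the HMM windows stay at 5 kb) with half-up
rounding, merged across the cohort, and the genome is cut at every
boundary. A useful identity guides the implementation: with half-up
snapping, an individual's snapped path equals its original path evaluated
at grid-cell midpoints, counting breakpoints strictly before the
midpoint. `fill_genotype_matrix()` uses exactly this rule, so each
(individual, block) cell is provably constant when blocks and paths come
from the same crossover set and chromosome lengths are grid multiples;
any violation raises an internal-consistency error rather than silently
picking a state. Re-expanding blocks onto windows reproduces the decoded
paths exactly when the grid equals the window size; with a 10 kb grid over
5 kb windows the snap is intentionally lossy — that is the stated mapping
resolution.

Per block, genotype counts are tested against the Mendelian 1:2:1
expectation with a 2-df chi-square; the mean AA-fraction excess over 0.25
summarizes reference bias, which the simulator can induce mechanistically
through a signed shift $\delta$ on the probability that a read supports
allele A. Shifting read sampling (rather than flipping calls post hoc)
reproduces the empirically observed AA over-representation with a single
parameter and leaves the HMM's emission model honest about its cause.

## The mixed model and permutation FDR

The scan is an EMMA/EMMAX-style single-variance-component linear mixed
model. Kinship is $K = ZZ^\top/m$ over column-standardized block dosages.
The null model $y = \mu + u + \varepsilon$, $u \sim N(0, \sigma_g^2 K)$,
$\varepsilon \sim N(0, \sigma_e^2 I)$ is fitted by REML over
$h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$ on a 0.01-spaced grid with
local refinement, after one eigendecomposition of $K$. Each block is then
tested by generalized least squares under the fitted covariance (Wald
test, $t_{n-2}$), with variance components held fixed across blocks — the
EMMAX approximation; exact per-block REML is out of scope. With
$\sigma_g^2 = 0$ the scan reduces *exactly* to ordinary least squares,
which the tests verify against `lm()` to $10^{-8}$. Additive dosage
coding (0/1/2 copies of A) is used throughout; no dominance term is
fitted, since one association statistic per block is reported.

Repeated heart-rate measurements at 21, 28 and 35 degrees Celsius are
scanned separately, plus a dispersion ("variance") phenotype. The phrase
"absolute differences in repeated measurements" is ambiguous between at
least three summaries; the default is the mean absolute pairwise
difference $(|x_{21}-x_{28}| + |x_{21}-x_{35}| + |x_{28}-x_{35}|)/3$,
with `"range"` and `"variance"` available behind the `method` flag. No
claim is made about which summary the original analysis used.

**Permutation FDR.** The phenotype is permuted across individuals (full
siblings, hence exchangeable under the null) `n_perm` times, reusing the
null variance components. For a candidate threshold $t$ drawn from the
observed p-values, $\widehat{\mathrm{FDR}}(t)$ is the mean permuted
discovery count divided by the observed discovery count; the reported
threshold is the most lenient $t$ with
$\widehat{\mathrm{FDR}}(t) \le$ level. This standard choice maximizes
discoveries under the FDR budget and is what produces the characteristic
picture of many significant blocks per locus that LD collapsing then
reduces to a handful of regions. When no candidate qualifies — the
typical null outcome — a finite sentinel stricter than every observed and
permuted p-value is reported, so nothing passes. Raw phenotypes (not
residuals) are permuted; residual permutation is a documented alternative
that is not implemented.

## Fine mapping and candidate ranking

Significant blocks (any phenotype, at the chosen FDR level) are clumped
greedily, best p first: the seed absorbs every significant block on its
chromosome with dosage $r^2 \ge 0.5$ or within 500 kb, the region spans
its members, and overlapping regions merge. The procedure is
deterministic and idempotent; the defaults are exposed because no
canonical pruning parameters exist for this design. Genes (GFF3 `gene`
features, converted to 0-based half-open coordinates) join a region on
any 1 bp overlap; each gene is assigned to the single region with the
largest overlap (ties to the earlier region) so per-region counts add up
to the number of distinct overlapping genes. Candidates inherit their
region's lead $-\log_{10} p$ (regions at or below 3 are excluded,
strictly) and score

$$ w_1 \min(-\log_{10} p,\ 10) + w_2\,[\mathrm{DE}] + w_3\,[\mathrm{LoF} > 0], $$

with the DE gate at adjusted $p < 0.01$ and fold change $\ge 2$. DE and
LoF evidence are consumed as tables; computing them is upstream of this
package. Qualitative selection criteria (novelty, human relevance) are
not computable here and are excluded from the score.

## What the simulator emulates — and what it does not

The generator reproduces the study conditions at desk scale: two 25 Mb
chromosomes (a stand-in for a ~734 Mb genome), one marker per kb
(scaling the ~10^6-marker system), 0.78x coverage, 1% read error,
optional reference bias, 1.5 crossovers per gamete per chromosome, 300
individuals (scaling ~1200), per-temperature baselines 90/130/170 bpm
with 10 bpm residual noise, planted additive QTLs, and rare arrhythmic
outliers whose recorded rate is half the latent rate (2:1
atrioventricular conduction). The genetic map length behind the real
design is not stated anywhere authoritative, so the crossover rate is an
explicit free parameter.

Deliberate simplifications: Poisson crossover counts with uniform
placement (no interference — consistent with the HMM's Markov
transitions, Haldane map function), per-marker Poisson depth with
independent reads (no read pairs, no alignability structure), no sex
chromosomes, no genotype-by-temperature interactions beyond
per-temperature effect vectors, no circadian dynamics. Passing tests
therefore demonstrate correctness of the inference under its own
generative assumptions plus robustness to the modelled noise — not
immunity to alignment artefacts, segmental duplications or batch
structure in real data.

## Numerical choices and problem sizes

* Log-space Viterbi; $r$ clamped to $[10^{-9}, 0.5 - 10^{-9}]$; ties
  prefer the incumbent state.
* Grid snapping is half-up (`floor(x/g + 0.5) * g`); sub-grid remainders
  at chromosome ends merge leftward.
* REML grid 0 to 0.99 by 0.01 with `optimize()` refinement in the
  winning bracket; a kinship matrix that is numerically zero short-cuts
  to $h^2 = 0$ (ordinary regression).
* Monomorphic blocks are skipped in kinship and reported with $p = 1$ in
  scans; p-values are floored at the smallest positive double so
  $-\log_{10} p$ stays finite.
* Floating-point fields serialize with 10 significant digits; identical
  configurations reproduce byte-identical artifacts, verified by MD5 in
  the manifest.
* Test-suite problem sizes: the decoding-accuracy cohort is the full
  scaled design (300 individuals, 2 x 25 Mb, ~50,000 markers, ~10,000
  windows); association calibration uses 20 power replicates and 50 null
  replicates at n = 300 with 100 permutations each; the end-to-end
  determinism run uses 60 individuals over 2 x 10 Mb with 25
  permutations. These sizes give stable estimates of every reported
  rate while keeping the whole suite to a few minutes.

## Known limitations

Viterbi returns the single best path; per-window posterior probabilities
(forward-backward) are intentionally out of scope, so downstream stages
see hard genotype calls without uncertainty. The EMMAX approximation
slightly mis-calibrates very strong loci (variance components are not
re-estimated per block). Permutation of raw phenotypes assumes full
exchangeability, which would be violated by family or batch structure
beyond an F2 sibship. Collapsed regions are interval unions, not credible
sets; Bayesian fine-mapping is a non-goal. Covariate hooks in the scan
are untested surface.

## A minimal session

```{r example, eval = FALSE}
spec <- default_genome_spec()
markers <- simulate_marker_map(spec, seed = 1)
truth <- simulate_f2_cohort(markers, n = 300, spec, seed = 2)
counts <- simulate_allele_counts(truth, markers, spec, seed = 3)
phen <- simulate_phenotypes(truth, qtl_spec("chr1", 12.5e6, additive = 6),
                            seed = 4)

paths <- viterbi_decode(aggregate_windows(counts, 5000),
                        hmm_params(error = 0.02, crossover_rate = 1.5))
gm <- fill_genotype_matrix(
  segment_genome(call_crossovers(paths), spec$chromosomes, 10000), paths)

K <- estimate_kinship(gm)
y <- setNames(phen$hr28, phen$sample)
scan <- lmm_scan(gm, y, K, phenotype_name = "hr28")
thr <- permutation_thresholds(gm, y, K, n_perm = 100, seed = 5)
collapse_loci(scan, gm, thr, level = 0.05)
```

Or, equivalently, `run_pipeline(analysis_config(...), "out/")` for the
orchestrated, manifest-tracked version.
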