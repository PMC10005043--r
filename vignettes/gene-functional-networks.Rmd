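---
title: "Estimating robust gene functional networks from multi-genotype time-course profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating robust gene functional networks from multi-genotype time-course profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfnet)
library(dplyr)
```

## The problem

A co-expression edge estimated in a single experiment conflates three very
different things: genuine functional relation, genotype-particular
regulation, and chance. With genome-wide time-course expression available
for a *panel of independent genotypes* — the motivating design is a
chili-pepper fruit-development study with 12 accessions (6 domesticated, 4
wild, 2 F1 hybrids) sampled at 7 development times — the three can be
separated: a functional relation should reappear, genotype after genotype,
even though the *shape* of the shared profile differs between genotypes.
`gfnet` turns that idea into an estimator with a quantifiable error rate.

## Data model

The unit of analysis is the standardized expression profile (SEP): for one
(genotype, gene) pair, the vector of expression values over the shared
time grid, centred and scaled to sample standard deviation 1
(`standardize_sep()`). Pearson correlation is invariant to this affine
rescaling, so the particular standardization convention cannot change any
network downstream; standardization matters only for profile *plots* and
for the pattern-average profiles below. Two consequences of the data
model:

* **one value per (genotype, gene, time)** — replicate libraries are
  assumed averaged upstream, since the correlations are taken between
  single per-genotype profiles;
* **complete-case gene universe** — a gene enters an analysis only with a
  full profile in every genotype analysed (`complete_genes()`). This keeps
  the replication denominator *a* identical for every pair, which the
  binomial error calculus below assumes. Zero-variance profiles cannot be
  standardized and are flagged missing rather than erroring.

Time grids with fewer than five points trigger a loud warning: with T − 2
degrees of freedom behind every correlation test, T < 5 leaves the
individual tests too weak to be useful.

## The estimator

For g input genes (typically the genes annotated to one biological
process, `select_genes_by_bp()`) and a genotypes, `gene2gene()` works in
two steps.

**Step 1 — per-genotype statistics** (`pair_stats()`). All g(g−1)/2 pairs
are tested in each genotype: Pearson r̂ over the T time points; two-sided
p-value from t = r̂√(T−2)/√(1−r̂²) on T−2 df; q-values by the
Benjamini–Hochberg step-up over exactly the testable pairs *of that
genotype*. The FDR universe is deliberately per-genotype and per-gene-set,
matching the practice of analysing each process separately. A Storey-type
variant that rescales by an estimated null proportion (λ = 0.5) is
available as `fdr_method = "storey"`; it is less conservative when many
pairs are truly related.

**Step 2 — filtering and replication.** In each genotype a pair passes iff

* q̂ ≤ *f* (FDR threshold, default 0.1),
* r̂² ≥ *mr2* (determination floor, default 0.7 — under the default
  positive-sign policy this means r̂ ≥ 0.837),
* it is not outlier-driven at level *q* (default 0.05, below),
* its sign is admissible.

An edge is emitted iff the pair passes in at least *x* of the *a*
genotypes (default: all of them). Support is counted against all genotypes
analysed — a genotype where the pair is untestable counts as non-support.
The output may legitimately be empty.

### The outlier screen

The threshold "eliminate putative regression outliers at level q" needs an
operational statistic; two are provided.

* `outlier_rule = "rstudent"` (default): regress the lexicographically
  larger gene on the smaller (a fixed, documented orientation), compute
  externally studentized residuals at the T points, and flag the pair when
  the maximum absolute value exceeds the two-sided t critical value at
  level q/T (Bonferroni over the points) on T − 3 df. This gives a clean
  per-pair error rate ≈ q per genotype.
* `outlier_rule = "loo_r2"`: flag the pair when its minimum leave-one-out
  r² falls below the *mr2* threshold, i.e. when deleting a single time
  point can break the correlation.

Both operationalize the same idea — a correlation carried by one aberrant
time point is not evidence of co-expression. They trade off differently,
and the difference matters at full stringency: the studentized screen
false-flags ≈ q of perfectly valid regressions in *each* genotype, so at
x = a = 12 and q = 0.05 roughly 1 − 0.95¹² ≈ 46% of true noisy edges are
lost to the screen alone (exactly collinear pairs are never flagged, since
their residuals vanish). The leave-one-out rule has essentially no false
flags on strongly correlated pairs and preserves true edges at full
support; its error rate is not tunable by q. The package keeps the
studentized rule as the default for its interpretable level, and the test
suite pins the attrition behaviour of both so the trade-off stays visible.
Users running at x = a with noisy data who find the output too sparse
should try `outlier_rule = "loo_r2"` before relaxing *f* or *mr2*.

### Sign policies

`mr2 = 0.7` was framed in the motivating analysis as implying r̂ ≥ 0.83,
i.e. only positive co-expression; `sign_policy = "positive"` is therefore
the default. `"consistent"` accepts either sign but requires every
supporting genotype to agree (ties between the signs resolve toward
positive); `"any"` counts support regardless of sign. Whether
sign-discordant genotypes should count toward support is genuinely
undecidable from the published description; the default takes the
conservative reading.

## The robustness calculus

If a fortuitous pair passes the per-genotype filter with probability *f*
independently in each of *a* genotypes, its support is Binomial(a, f) and
the chance rate of it being reported at support ≥ x is the upper binomial
tail, computed by direct log-space summation in `pred_error_g2g()`
(log-space so that extreme tails such as fᵃ do not underflow; the x = a
tail is returned as fᵃ exactly). Reading the per-genotype rate as the FDR
threshold *f* is conservative — the mr2 floor and the outlier screen only
reduce the per-genotype pass probability further. `error_grid()` explores
the (a, f, x) design space for planning how many genotypes an experiment
needs; `pattern_profiles()` and the run report print the "one in N"
framing (e.g. one in 5436 at a = 12, f = 0.05, x = 5).

## Transcription-factor candidates and meta-networks

`gene2tf()` applies the identical per-genotype filters to (target gene ×
TF) pairs, with q-values over that pair universe, and reports TFs
supported in ≥ x genotypes; targets are excluded from their own candidate
pool, and `hub_genes()` ranks targets by degree. `augment_network()`
re-runs the network over the union of the original genes and the
candidates. Because q-values depend on the pair universe, a naive re-run
over the larger universe could drop an edge the original network
supported; with `fixed_universe = TRUE` (default) pairs among the original
input genes reuse the original run's statistics and only TF-involving
pairs are tested over their own universe, which guarantees that
augmentation never removes a previously supported edge.

`build_metanetwork()` unions several networks over a shared gene
namespace, recording per-node membership, per-edge sources, and the count
of genes shared by each pair of member networks. Connected components of
the union ("patterns" P = 1..k, labelled by decreasing size with ties
broken by the smallest member gene) each carry one characteristic profile
shape; `pattern_profiles()` averages the standardized expression over all
(gene in pattern) × (genotype in group) observations per time point, with
a t interval mean ± t(0.975, n−1)·sd/√n. Treating gene × genotype
observations as independent is a simplification (genes in a pattern are
correlated by construction); a bootstrap percentile oracle in the test
suite confirms the t interval is not grossly miscalibrated on synthetic
data, but the intervals should be read as descriptive, not inferential.
The alternative convention — intervals over per-genotype averages — is
narrower and was not chosen because group sizes (4–6 genotypes) would
leave very few degrees of freedom.

## The synthetic-data generator

`sim_spec()` / `generate_sep()` emulate the motivating design: 12
genotypes named D1–D6 (domesticated), W1–W4 (wild), H1–H2 (F1), 7 times at
0–60 days after anthesis. Null genes draw independent standard-normal
profiles. A planted module draws **one fresh latent profile per supporting
genotype** — deliberately, because that is the phenomenon the method
exploits: the same gene pair shows different shapes in different
genotypes yet is internally correlated within each. Member genes observe
latent + Normal(0, noise_sd) noise on the latent scale; the default
noise_sd = 0.05 yields within-module correlations around 0.99, the order
of magnitude reported for real surviving edges. Modules supported in only
a few genotypes act as decoys that the replication filter must reject;
planted outlier pairs (collinear except one point shifted by 3
latent-scale units) exercise the outlier screen. Everything is
reproducible from a single integer seed, and generation does not disturb
the caller's RNG stream.

What the generator does *not* emulate: RNA-Seq count noise (negative
binomial dispersion, library-size effects), correlated noise across genes,
or missing time points. Passing tests therefore demonstrate correctness of
the algorithmic machinery on idealized profiles, not performance on raw
sequencing data — deriving SEPs from counts is upstream of this package by
design.

## Numerical and design choices

* Standardization uses the sample standard deviation (denominator T − 1);
  zero variance ⇒ profile flagged missing, never an error.
* The pair-statistics kernel is closed-form vectorised: with standardized
  profiles the regression of y on x has slope r̂ and intercept 0 and
  leverages 1/T + x²/(T−1), so studentized residuals for all pairs of a
  genotype are computed with dense matrix arithmetic (verified against
  `rstudent(lm(...))` in the tests). Exact fits (SSE < 1e−20) get residual
  statistic 0.
* Correlations are cached per (gene set, genotype); threshold filtering is
  pure, so `sensitivity_grid()` re-filters without re-estimating. The
  outlier statistic is cached as the max |studentized residual|, making
  the flag re-derivable for any q.
* Determinism throughout: genes, genotypes, edges and nodes are sorted
  lexicographically; component labels are size-then-smallest-member;
  repeated exports are byte-identical, and every output file starts with a
  provenance header (package version, configuration, input checksums).
* Degenerate inputs: T < 4 disables the studentized screen (with a
  warning) since no residual degrees of freedom remain; single-observation
  groups get NA interval bounds; an empty network prints an explicit null
  output.

## Problem sizes used in the checks

The automated checks run the full pipeline at the study scale (12
genotypes × 7 times) with gene universes of 20–50 genes, 200 replicate
null datasets for the chance-rate bound, 10,000 simulated pairs for the
null-correlation distribution check, and 10,000 bootstrap resamples for
the interval oracle — sizes chosen so every stochastic assertion has
comfortable Monte-Carlo margin while the whole suite stays quick on one
CPU.

## Known limitations

* The binomial calculus assumes independent genotypes; related accessions
  (e.g. an F1 and its parents) violate this mildly, making the predicted
  chance rate optimistic.
* The per-genotype FDR universe means q-values (and hence edges) depend on
  the input gene set; two analyses of overlapping gene sets are not
  guaranteed consistent except under the fixed-universe augmentation path.
* At full stringency (x = a) the default outlier screen's per-genotype
  false-flag rate compounds, as quantified above.
* Correlation of standardized profiles detects linear, simultaneous
  co-expression only — lagged or nonlinear relations are invisible.
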