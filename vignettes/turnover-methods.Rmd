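---
title: "Methods: window-based transcriptome turnover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based transcriptome turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txturnover)
```

## The problem

When several closely related taxa are sequenced (poly-A+ RNA) against one
shared reference genome, the transcribed portion of the genome can be
compared directly across lineages: which parts are transcribed everywhere,
which in a single lineage only, and how quickly transcription is gained and
lost along the phylogeny. `txturnover` implements this comparison as a
window-based presence/absence pipeline: the reference is tiled into fixed
200-bp windows, each aligned fragment is assigned to exactly one window,
counts are thresholded into presence/absence, and all downstream analyses —
sharing classes, transcriptome-sharing trees, rarefaction and saturation
fits, run-length and enrichment analyses — operate on those binary
profiles.

Three design elements keep cross-taxon comparisons honest:

* **The common genome.** Only windows detectably covered by genomic (DNA)
  reads in every required taxon enter the analysis, so absence of
  transcription is never confounded with absence (or unmappability) of the
  underlying sequence. The threshold is one genomic fragment per taxon by
  default (`min_count`), configurable because "covered" is not sharply
  defined at very low depth.
* **Depth normalization.** Samples are subsampled without replacement to a
  common fragment total (`normalize_by_subsampling()`, an exact
  multivariate hypergeometric draw), so presence calls at a given read
  threshold are comparable across samples.
* **Fixed windows, one fragment one window.** Fragments are assigned to the
  window containing their midpoint — equivalent to "the window holding more
  than half the fragment" for a fragment spanning two windows, and
  well-defined for any span. Mate pairs are expected as single fragment
  intervals and count once. Trailing sub-window chromosome ends are
  dropped so every window has the same length and coverage fractions share
  one denominator.

Coordinates are 0-based half-open (BED convention) throughout; strand is
ignored, since presence of poly-A+ coverage is the assayed quantity.

## Presence, sharing and the singleton argument

Presence is "at least tau reads" with tau in {1, 10, 100} by default: tau = 1
is maximally inclusive (and maximally exposed to sampling noise), the higher
thresholds isolate progressively more abundant transcription. Per-taxon
presence sums each taxon's tissues and replicates before thresholding (a
per-sample mode exists, because thresholding before or after aggregation is
a genuine choice).

Transcribed windows are classified by how many taxa show them: `single`,
`intermediate` (2 to T−1) or `all`. Classes are assigned on the tau = 1
matrix and then cross-tabulated by the highest threshold each taxon
reaches, so a window's class never depends on its abundance.

Sampling failure is quantified analytically: a window truly expressed at a
mean of lambda fragments per sample yields zero fragments with Poisson
probability `exp(-lambda * k)` across `k` independent samples.
`detection_miss_probability(1, 1)` is `r round(detection_miss_probability(1, 1), 4)`
— a singleton observed in one sample is missed in a second equally deep
sample about 37% of the time — while across nine further samples the miss
probability collapses to about 0.01%. This is why single-taxon calls are
trustworthy at the taxon level even when individual singletons are not.

## Transcriptome-sharing trees

Between-taxon similarity is the phi coefficient (Pearson correlation of two
binary columns, computed from the 2x2 contingency table) on presence
profiles; Spearman correlation on raw counts is available as an
alternative. Each taxon is then represented by its row of correlations and
rows are compared by Manhattan distance, and neighbor joining (Saitou-Nei,
Studier-Keppler Q-criterion) builds the unrooted tree. NJ is implemented
in-package with a deterministic tie-break (lexicographically smallest pair
among minimal Q) and negative branch lengths clamped to zero after being
counted; it is exact on additive distances, which the test suite verifies
against randomly generated trees.

Numerical conventions worth knowing:

* A presence column with no variance leaves phi undefined; the pipeline
  records 0 with a warning and flags the taxon, and the Manhattan sum skips
  an entry only when it is flagged in both rows of a pair. This keeps
  degenerate simulations total while making the pathology visible.
* Bootstrap supports resample windows (the only exchangeable unit) with
  replacement, rerun the full correlation-to-NJ pipeline, and annotate each
  internal edge of the point tree with the percentage of replicates
  containing the same bipartition. Supports below 70% are listed in a
  report attribute; the point tree's own bipartitions are annotated rather
  than a consensus.
* Sampling variance of terminal branches is estimated from disjoint
  replicate subsets of the same samples (`split_replicates()`): one tree
  per subset, and per taxon the minimum terminal length across subsets is
  taken as the sampling-robust portion, the mean minus the minimum as the
  sampling-variable portion. The min/mean definition is a declared
  interpretation of "the portion shared across sets"; the package reports
  it together with the replicate trees and their majority-rule consensus so
  other definitions can be computed from the same objects.

## Rarefaction and saturation

Two accumulation axes are contrasted. Over **taxa**: random orders of taxon
addition (100 by default), recording cumulative union coverage — the final
point is the all-taxa union for every order. Over **depth**: each taxon's
pooled fragments are subsampled without replacement to 10%..100% in 10%
steps. Depth series are computed from prefixes of one random fragment
permutation per taxon per draw: a prefix of length `floor(f * N)` is a
uniform without-replacement subset at every fraction, so the marginal
distribution at each depth is exactly that of independent subsampling while
one permutation serves the whole series. The fractions within a draw are
therefore nested — as they are in real re-subsampling of one sequencing
library — and the fit metadata records that points above 50% are not
statistically independent. Fraction 1.0 is computed exactly, without
resampling.

Each curve is fit by two models chosen to represent the competing
hypotheses: ever-increasing (`y = a + b log x`, least squares) and
saturating (`y = A + (R0 - A) exp(-exp(lrc) x)`, the `SSasymp`
parameterization of asymptotic regression). Both are Gaussian fits to the
curve means (n = number of curve points), the winner is the model with
minimum BIC, and evidence is summarized as the BIC-based Bayes factor
`exp(|dBIC| / 2)` with the conventional bands (1-3 weak, 3-20 positive,
20-150 strong, above 150 very strong). The asymptotic fit tries the
self-starting routine, then explicit starts
(`A = max(y) + 0.05 range(y)`, `R0 = min(y)`, `lrc = log(1/median(x))`),
then up to 20 jittered Levenberg-Marquardt restarts; if all fail the
logarithmic model wins by default with an explicit flag. The winner's
extrapolation to twice the current sampling is always reported, and the
estimated asymptote is checked against the plausible range (0, 1].

## Regions and enrichment

The union (any-taxon) presence track is segmented into maximal runs of
equal state. Runs break at chromosome boundaries and at common-genome mask
gaps, so within each contiguous masked block the run lengths sum exactly to
the block span — the longest non-transcribed run is the largest candidate
"transcriptional desert" the data supports.

Annotation enrichment uses interval shuffling: each feature is placed
uniformly at random along its own chromosome (length preserved; overlaps
among placed features allowed), optionally restricted to allowed blocks
such as the masked genome — the pipeline shuffles within the mask by
default, since all observed transcription lives there. The two-sided
empirical p doubles the smaller add-one tail (`p >= 2/(n+1)`; both
one-sided components are reported and attain `1/(n+1)`), and
Benjamini-Hochberg correction runs across the full feature-by-target
family. Because the placement scheme itself can be biased, the ratio band
observed against total transcription (`method_bias_band()`) flags
downstream ratios indistinguishable from method bias.

## The turnover simulator

`turnover_model()` + `simulate_dataset()` generate data with the structure
the pipeline assumes, plus full ground truth (true states, core labels,
expression levels, tree). Presence evolves as a two-state Markov chain
along the phylogeny — gain rate `g`, loss rate `l` per Myr, transition
probabilities `P(0->1) = pi1 (1 - e^{-(g+l)t})`,
`P(1->0) = (1 - pi1)(1 - e^{-(g+l)t})` with `pi1 = g/(g+l)` — with the root
drawn from the stationary distribution. A core fraction is immune to loss
(present in every taxon) and expressed `core_multiplier` times higher:
loss-immunity rather than mere slowness cleanly separates the conserved
class for testing. Expression per transcribed window is log-normal and
shared across taxa; sequencing is Poisson at a configurable depth per
sample. Genomic coverage for masking is simulated by independent per-taxon
window dropout.

### Why rate heterogeneity is a first-class parameter

The default tree spans splits from roughly 3,000 years to 10.6 Myr — 3.5
orders of magnitude. A single turnover rate cannot serve both ends: fast
enough to differentiate populations, it drives every deep branch to
stationarity (no signal separating the distant species); slow enough to
preserve deep signal, it leaves the population splits with essentially zero
expected changes among 10^4 windows. We verified both failure modes on
noise-free true states. The default generator therefore draws, per window,
two independent mean-1 log-normal multipliers (sdlog `rate_sdlog = 1.5`)
scaling the gain and the loss rate separately. This makes both the
turnover speed *and* the stationary presence probability vary across
windows, which is what real data show: volatile windows that differ
between populations, conserved intermediate-frequency windows that retain
deep-split signal, and a reservoir of rarely-transcribed windows. The
reservoir is also what makes coverage keep growing as taxa are added
(approximately logarithmically, as heterogeneous detection probabilities
classically produce) while depth accumulation saturates — the central
contrast the analysis is designed to detect. With `rate_sdlog = 0` the
model reduces to the homogeneous chain.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `gain`, `loss` | 0.5, 2.0 per Myr | mean stationary presence 0.2 |
| `rate_sdlog` | 1.5 | across-window gain/loss heterogeneity |
| `core_fraction` | 0.05 | loss-immune conserved core |
| `core_multiplier` | 10 | core expression scaling |
| `expr_meanlog`, `expr_sdlog` | log 5, 1 | log-normal expression; median transcribed window ~5 fragments/sample |
| `depth` | 1 | expected fragments per unit expression per sample |
| `n_windows` | 10,000 | windows (5 equal chromosomes, 200 bp) |
| `n_tissues`, `n_replicates` | 3, 1 | samples per taxon |

These were fixed once, at design time, to reproduce the qualitative
anchors the pipeline targets: the intermediate sharing class is the
largest, the all-taxa class holds roughly a fifth of transcribed windows,
taxa-axis rarefaction is classified logarithmic while per-taxon depth
curves are classified asymptotic, and the sharing tree recovers the
generating topology in at least 95% of seeded runs at 10^4 windows. The
rates are free parameters of the simulator, not estimates of the real
turnover rate.

### What the simulator does not emulate

No mapping noise or cross-mapping artifacts (an optional uniform background
could be layered on, but counts are zero wherever the true state is absent
by default); no repeat content or mappability structure beyond the
genomic-dropout knob; no sequence evolution — fragments are intervals, not
reads. Passing tests on simulated data therefore demonstrate that the
*procedures* behave as designed under the generative assumptions, not that
real libraries satisfy those assumptions.

## Study scales used by the tests and the acceptance script

Problem sizes are the package's own choices for a desk-scale study: 10
taxa, 10^4 windows and 100 seeds for topology recovery and the rarefaction
contrast (50 random taxon orders, 3 depth draws per fraction); 100 random
additive matrices of 5-10 taxa for NJ exactness; 100 synthetic curves per
generating family (noise sd = 1% of the curve range) for model selection;
200 null datasets at 200 shuffles for enrichment calibration; and, for the
sampling-variance ordering, 500 windows at depth 10 in a single tissue
split into three disjoint replicate sets — a deliberately deep, small
common space in which singleton presence is dominated by sampling noise,
the regime the replicate-splitting analysis is about. At 10^4 windows the
phi estimates are precise enough that replicate trees barely differ in
either mode, and the ordering, while real, is not measurable.

## Known limitations

* The min/mean branch-variance partition is one reading of "branch portion
  shared across replicates"; length-based partitions dilute when a stable
  noise baseline inflates all distances equally.
* Phi on near-degenerate columns (very sparse presence) is noisy; the
  flagged-zero convention keeps pipelines running but flagged taxa should
  be interpreted with care.
* BIC model selection compares exactly two curve families; neither may be
  adequate for curves with plateaus followed by renewed growth.
* The enrichment null places features independently and uniformly;
  clustered annotations (exons within genes) violate independence, which
  is why the method-bias band is computed and reported.
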