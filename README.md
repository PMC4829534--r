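# txturnover

Comparative analysis of transcriptome coverage turnover across closely
related taxa mapped to a single reference genome.

## The problem

Deep poly-A+ RNA sequencing shows that far more of a genome is transcribed
than its annotated exons. When several populations, subspecies and species
are sequenced against one reference, the interesting questions become
evolutionary: which transcribed regions are shared by all lineages, which
are lineage-specific, how fast is transcription gained and lost along the
phylogeny, and does genome coverage saturate with more sequencing or keep
growing with more taxa? `txturnover` implements this analysis for anyone
with per-sample aligned-fragment intervals (BED/TSV, derivable from BAM), a
set of taxon labels and, optionally, genomic-read coverage for
common-genome masking and annotation intervals for enrichment.

## What it computes

The genome is tiled into non-overlapping 200-bp windows; each fragment
increments the window containing its midpoint. Analyses are restricted to
the *common genome* — windows covered by genomic reads in every taxon — and
samples are equalized by exact without-replacement subsampling. On the
resulting presence/absence profiles (`count >= tau`, tau in {1, 10, 100}):

* **Coverage fractions and sharing classes** — windows transcribed in one,
  several or all taxa, cross-tabulated by coverage level.
* **Detection-miss probabilities** — the Poisson zero class
  `exp(-lambda k)`: a window expressed at one expected fragment is missed
  in a second sample ~37% of the time, but across nine taxa only ~0.01%.
* **Transcriptome-sharing trees** — phi correlations between taxa,
  Manhattan distances between correlation rows, neighbor joining, window
  bootstrap supports, and a replicate-split partition of terminal branches
  into sampling-robust and sampling-variable portions.
* **Rarefaction and saturation** — coverage accumulation over random taxon
  orders and over read-depth fractions, each fit by a logarithmic
  (ever-increasing) and an asymptotic (saturating) model, selected by BIC
  with a Bayes-factor evidence summary.
* **Regions and enrichment** — run lengths of transcribed and
  non-transcribed stretches (transcriptional deserts), and shuffle-based
  annotation enrichment with BH-FDR control and a method-bias ratio band.
* **A turnover simulator** — two-state gain/loss dynamics along a
  ten-taxon mouse phylogeny (splits from ~3 kyr to 10.6 Myr) with
  across-window rate heterogeneity, a conserved high-expression core,
  log-normal expression and Poisson sequencing, returning full ground
  truth for validation.

## Worked example

Simulate a ten-taxon dataset at the default study conditions, mask,
normalize, and run the main analyses:

```r
library(txturnover)

model <- turnover_model()           # ten-taxon tree, 10,000 windows
ds <- simulate_dataset(model, seed = 42, dropout = 0.05)

mask <- common_genome_mask(ds$genomic, required_taxa = model$tree$tip.label)
norm <- normalize_by_subsampling(ds$counts, min(colSums(ds$counts$counts)),
                                 seed = 1)
presence <- binarize(norm, tau = 1, mask = mask)

classify_sharing(presence)
#> Sharing profile over 5999 windows ( 3803 transcribed in >= 1 of 10 taxa)
#>   single            850  (22.4%)
#>   intermediate     2204  (58.0%)
#>   all               749  (19.7%)
```

Most transcribed windows are shared by some but not all taxa — the
signature of ongoing turnover — while about a fifth are shared by all ten,
dominated by the conserved high-expression core. The sharing tree recovers
the generating phylogeny with full bootstrap support:

```r
tree <- bootstrap_supports(presence, n_boot = 100, seed = 2)
ape::dist.topo(ape::unroot(model$tree), tree)
#> [1] 0                                  # identical topology to the truth
```

Rarefaction shows the study's central contrast — taxa keep adding coverage,
depth saturates:

```r
fit_saturation(rarefy_taxa(presence, n_orders = 100, seed = 3))
#> Saturation model comparison (axis: taxa , 10 points)
#>   BIC logarithmic -81.73 | asymptotic -62.94
#>   winner: logarithmic (Bayes factor 1.2e+04, very strong support)
#>   predicted coverage at 2x sampling (x = 20): 0.7187

fit_saturation(rarefy_depth(norm, mask = mask, n_draws = 5, seed = 4))
#> Saturation model comparison (axis: depth , 10 points)
#>   BIC logarithmic -65.67 | asymptotic -96.52
#>   winner: asymptotic (Bayes factor 5.01e+06, very strong support)
#>   estimated asymptote: 0.6325
#>   predicted coverage at 2x sampling (x = 2): 0.6325
```

Doubling the number of taxa is predicted to raise union coverage from 0.63
to 0.72, while doubling sequencing depth gains essentially nothing — the
per-taxon transcribed space is already saturated at its 0.63 asymptote.
The whole sequence (mask, normalize, binarize, sharing, tree, rarefaction,
regions, enrichment) can also be driven from one YAML config via
`run_pipeline()`, which writes TSV/BED/Newick/JSON artifacts and a
checksummed manifest.

## The methods vignette

`vignettes/turnover-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, the
simulator's design (including why across-window rate heterogeneity is
essential on a tree spanning 3 kyr to 10.6 Myr), numerical conventions and
known limitations.
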