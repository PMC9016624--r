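# pauseScape

Analysis toolkit for studies linking chromatin state to RNA polymerase II
promoter-proximal pausing. It covers the downstream computational layer of
a combined ChIP-seq / RNA-seq / promoter-capture Hi-C (PCHiC) study:

* **Pausing index.** For each gene, the ratio of mean per-bp Pol II density
  in the transcription-oriented promoter-proximal window (TSS−30 to
  TSS+300) to the density over the transcribed region (TSS+300 to TES),
  computed on a zero-clamped binned coverage track, with the standard
  exclusions (gene width < 1 kb, promoter density < 1.2, non-positive body
  density) and the PI > 2 paused / PI < 2 not-paused classification.
* **Expression layers.** FPKM = (RC_g × 10⁶)/(RC_p × L); four equal-sized
  expression categories; strict |FC| > 1.5 and adjusted p < 0.1 filtering
  of a supplied differential-expression table into factor-activated (down
  upon knockdown) and factor-repressed (up) gene sets.
* **Chromatin landscape.** Facultative vs constitutive heterochromatin by
  the sign of mean(H3K27me3) − mean(H3K9me3); enhancer seeds from H3K27ac
  peaks outside TSS windows, 12.5-kb stitching, and super-enhancer calling
  with the rank-curve slope-1 tangent cutoff.
* **Enrichment heatmaps.** Fisher exact tests of gene groups against
  equal-sized bins (PI quintiles, expression quartiles); score =
  log₂(odds ratio), stars by raw-p bands.
* **Metagene profiles.** Anchor-centered signal matrices, strand-aware or
  direction-agnostic, per-bin mean ± s.e.m. with 2-s.d. outlier-region
  removal.
* **PCHiC post-processing.** Strict per-replicate read (> 5) and distance
  (< 1.5 Mb) filters, quantile normalization of replicate counts,
  replicate-mean intensities, per-gene interaction summaries, and paired /
  unpaired Wilcoxon comparisons across conditions and gene groups.
* **Synthetic data.** A seeded, substreamed generator of toy genomes,
  coverage tracks, expression counts, peak clusters and two-replicate
  contact tables with the statistical structure the analyses assume, plus
  a deterministic pipeline driver (`runPipeline`) with an MD5 manifest.

Intervals live in `GRanges`; tracks in a small S4 class (`BinnedTrack`,
one value per fixed 50-bp bin); file formats are BED, bedGraph and
documented TSV layouts (0-based half-open on disk).

## Worked example

```r
library(pauseScape)

cfg    <- simConfig(nGenes = 300L, chromLength = 9e6, seed = 1L)
genome <- simulateGenome(cfg)
polII  <- clampNegative(simulateTrack(genome, cfg, "PolII"))

pt <- pausingIndex(polII, genome$genes)
#> pausingIndex: 300 genes; ok 300, excluded (width 0, low promoter 0, zero body 0)
pt$class <- classifyPaused(pt)
head(pt, 5)
#>   gene_id d_prom d_body    PI status      class
#> 1   g0001  1.897  2.044 0.928     ok not_paused
#> 2   g0002  2.077  1.973 1.053     ok not_paused
#> 3   g0003  2.217  2.027 1.094     ok not_paused
#> 4   g0004  9.809  2.003 4.897     ok     paused
#> 5   g0005 10.072  2.073 4.860     ok     paused
table(pt$class, genome$truth$paused)
#>              FALSE TRUE
#>   not_paused   150    0
#>   paused         0  150
```

Genes g0001–g0003 have flat Pol II coverage (promoter ≈ body density ≈ 2,
PI ≈ 1): elongating. g0004–g0005 carry the simulated 5× promoter
accumulation (PI ≈ 4.9): paused. Against the generator's ground truth the
classification is exact at this noise level (s.d. 20% of the body mean).

Gene-set overlap arithmetic works directly from printed counts — e.g.
combining 64/533 activated and 18/412 repressed cell-cycle genes over 945
deregulated genes:

```r
cc <- overlapPercentage(c(activated = 64, repressed = 18), total = 945)
cc$combined_pct          # 8.68 (%)
cc$combined_pct_rounded  # 9
```

A full synthetic run — tracks, pausing table, expression tiers,
deregulated sets, stitched enhancers, enrichment heatmap, metagene
profile, PCHiC summaries and tests, and an MD5 manifest:

```r
manifest <- runPipeline(list(seed = 1L, n_genes = 200L,
                             sim = list(chromLength = 6e6)), "out")
```

Re-running with the same configuration reproduces identical checksums.
A thin command-line wrapper is installed at
`inst/scripts/pipeline.R`.

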