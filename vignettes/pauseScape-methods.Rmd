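---
title: "Quantifying Pol II pausing and its chromatin context: methods and design"
author: "pauseScape"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Quantifying Pol II pausing and its chromatin context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(message = FALSE)
library(pauseScape)
library(GenomicRanges)
```

# Scope

pauseScape implements the downstream computational layer of a typical
ChIP-seq / RNA-seq / promoter-capture Hi-C study of promoter-proximal RNA
polymerase II pausing and its regulatory chromatin context — the part of
such a study that starts from binned, input-normalized coverage tracks,
peak sets, count tables and called interactions, and ends at pausing
indices, expression categories, enhancer/super-enhancer calls, log-odds
enrichment heatmaps, metagene profiles and per-gene contact summaries.
Read alignment, peak calling, differential-expression model fitting and
interaction calling are deliberately upstream of this package: it consumes
their tabular and track outputs.

Because those upstream outputs are large and platform-bound, the package
carries its own seeded generator of toy data with the statistical structure
the analyses assume. The generator is first-class, tested code: every
analysis can be exercised, and its parameter recovery measured, without any
external file.

# The pausing index

For a gene $g$ with transcription start site (TSS) and end site (TES), the
pausing index is

$$\mathrm{PI}_g \;=\; \frac{\bar d_{\mathrm{prom}}}{\bar d_{\mathrm{body}}},$$

where $\bar d_{\mathrm{prom}}$ is the mean per-bp Pol II density over the
transcription-oriented window from TSS$-30$ to TSS$+300$ and
$\bar d_{\mathrm{body}}$ the mean density from TSS$+300$ to the TES.
Densities come from a zero-clamped track: input-subtracted coverage can be
negative, and negative values are replaced by zeros before any density is
formed. A gene is excluded (no PI) when

* its width is below 1 kb (the promoter window would dominate the body);
* its promoter density is below 1.2 (not detectably transcribed with
  promoter-bound Pol II); or
* its body density is not positive (the ratio is undefined).

Genes with $\mathrm{PI} > 2$ are called paused, genes with
$\mathrm{PI} \le 2$ not paused; excluded genes are unclassified. The
threshold is strict on the paused side: pausing is defined as PI *above* 2
and a PI of exactly 2 therefore falls in the not-paused class. Flat
coverage gives PI $= 1$ exactly, and PI is invariant to rescaling the
track, which makes the statistic robust to global normalization factors.

Window orientation matters: the $(-30, +300)$ window is asymmetric, so it
is laid out along the direction of transcription (mirrored for minus-strand
genes). The body window runs from the downstream edge of the promoter
window to the TES.

## Coverage quantification

Tracks are fixed-bin vectors (50 bp by default, the conventional export
width of binned bigWig files). The signal of a region is the bin-value
weighted sum of overlapped bases divided by the region width; bins partially
overlapped by a region contribute in proportion to the bases they overlap.
This pro-rating is a pinned choice — summing whole bins would make region
means depend on how a window happens to sit on the grid — and makes region
signal exactly additive over adjacent disjoint regions.

# Expression layers

FPKM is computed as $\mathrm{FPKM}_g = 10^6\,RC_g /(RC_p\,L_g)$ with
$RC_g$ the gene's count, $RC_p$ the total over all provided genes and
$L_g$ the gene length in bp. Genes are ranked into four equal-sized
categories (silent, low, medium, high), ties broken by gene id so the
binning is stable and order-invariant. The same equal-frequency binning
machinery produces the five PI quintiles used by the enrichment heatmaps.

The differential-expression filter consumes an externally fitted
statistics table and keeps genes with $|FC| > 1.5$ and adjusted
$p < 0.1$, both strict. Fold changes are read as linear expression ratios
(knockdown over control): down means ratio $< 1/1.5$. A `log2Scale`
switch tolerates tables exported on the log2 scale. Genes *down* upon
knockdown form the factor-*activated* set (the factor promotes their
expression); genes up form the *repressed* set. The linear-ratio reading is
a pinned choice documented here because printed cutoffs of this form do not
state their scale.

# Heterochromatin flavours and enhancers

Facultative versus constitutive heterochromatin is scored per domain as the
sign of $D = \overline{\mathrm{H3K27me3}} - \overline{\mathrm{H3K9me3}}$:
$D > 0$ facultative-like, $D \le 0$ constitutive-like. The boundary at zero
presumes both tracks are input-normalized and mutually comparable; no
threshold beyond the sign is imposed because none is canonical.

Enhancer candidates are H3K27ac peaks outside TSS windows (±2 kb for the
plain enhancer definition; the super-enhancer preset uses ±2.5 kb — both
conventions circulate and both are shipped). Seeds with gaps of at most
12.5 kb are stitched transitively; a gap of exactly the stitch distance
merges. Super-enhancers are called with the standard rank-curve geometry:
signals sorted ascending, ranks and signals rescaled to the unit square,
cutoff at the point where a slope-1 line is tangent to the curve from below
(computed as the point most below the unit diagonal, rightmost on ties);
regions with signal strictly above the cutoff are flagged. With all-equal
signals there is no elbow and nothing is flagged. Two properties worth
noting: the flags are invariant to rescaling all signals (the geometry
lives in the unit square), but the *number* of flagged regions is **not**
monotone in the top signal — shrinking the strongest region rescales the
curve and can move the tangent point down, flagging more regions. The
tests therefore check the tangent point against a brute-force scan rather
than any monotonicity heuristic.

# Fisher log-odds enrichment

Each heatmap cell is a Fisher exact test of one gene group against one bin
of an equal-frequency partition, within the universe of binned genes:
$a = |A \cap B|$, $b = |A \setminus B|$, $c = |B \setminus A|$,
$d = |U| - a - b - c$. The two-sided $p$ is the sum of hypergeometric
probabilities of all margin-fixed tables no more probable than the observed
one. The displayed score is $\mathrm{LOR} = \log_2(ad/bc)$; tables with a
zero cell get the Haldane–Anscombe correction (+0.5 on every cell) for
display only, flagged as such — the $p$-value stays exact. Stars follow the
raw-$p$ bands (* ≤ 0.05 through **** ≤ 0.0001); no multiplicity layer is
added, matching how such heatmaps are conventionally annotated, and the
caveat is that neighbouring cells are correlated by construction.

# Metagene profiles

Anchor matrices hold one row per region and one fixed-width bin per column
spanning anchor ± flank. When strand orientation is requested, bins of
minus-strand rows are placed as exact genomic mirrors, so a feature at
transcription offset $+x$ lands in the same column on both strands; without
it, gene directionality is ignored (bodies all to the right). Rows partially
off-chromosome are zero-padded and flagged rather than dropped.

The profile is the per-column mean ± s.e.m. over retained rows. Outlier
regions — rows whose mean over the plotted window deviates from the grand
mean of row-means by more than 2 s.d. — are removed first. The removal is
one pass: the threshold is computed once, on all rows. An iterated filter
would keep shrinking the s.d. and eating into the distribution's tails,
which is not what a 2-s.d. rule is meant to do; the one-pass filter is
idempotent exactly when the retained rows are homogeneous, which is the
designed situation (a few gross outliers over a well-behaved majority).
Whether such a filter should act per-region or per-bin is genuinely open;
per-region is pinned here because the profile averages regions, so the
natural unit of removal is the region.

# Promoter-capture interaction post-processing

Called interactions pass three strict filters: more than 5 raw reads in
*each* biological replicate, and bait-to-other-end distance (midpoint to
midpoint; anchor points are a pinned choice, as calling tools report
fragments, not points) below 1.5 Mb. Filtering precedes normalization —
the read floor is a sequencing-evidence criterion and belongs on raw
counts. Replicate counts are then quantile normalized (via
`limma::normalizeBetweenArrays`, the standard implementation of the
sorted-mean substitution with tie averaging) and averaged per interaction
("intensity"). When two conditions are compared the replicate columns of
both are normalized jointly, so between-condition intensity differences are
not absorbed into condition-specific scales. Per-gene summaries count kept
interactions and average their intensities per bait; group contrasts use
paired Wilcoxon tests across conditions on matched baits and unpaired
Wilcoxon tests between gene groups within a condition. One caveat of tie
averaging: with heavily tied integer counts the post-normalization column
distributions agree only up to the tie pattern; exact distribution equality
holds for tie-free data.

# The synthetic-data generator

One integer seed expands into fixed per-component substreams (genome,
each track kind, expression, contacts, DE table), so regenerating one
component never perturbs the draws of another, and every generator is
byte-deterministic under its configuration. The generator encodes the
contrasts the analyses are meant to detect:

* **Genome** — non-overlapping genes of 2–20 kb, alternating strands, on
  one toy chromosome (defaults: 1,000 genes on 30 Mb); per-gene truth:
  paused flag, regulation class (activated / repressed / neutral),
  expression tier.
* **Pol II track** — gene bodies at density 2, promoter-proximal windows at
  `pause ratio` × body (5 for paused, 1 for elongating genes). The body
  density of 2 sits above the 1.2 promoter floor so elongating genes are
  classifiable rather than excluded. Painting acts on whole bins, so with
  zero noise the mean over a painted region's bin-aligned extent equals its
  configured density exactly.
* **Histone-variant track** — a Gaussian bump (s.d. 500 bp) at the TSS of
  activated genes (TSS-confined binding) versus a promoter-to-TES plateau
  over repressed genes (promoter-plus-body binding).
* **H3K27me3 / H3K9me3** — anti-correlated alternating 100-kb domains
  (where one is high the other is low), the structure the sign-of-$D$
  score discriminates.
* **H3K27ac** — intergenic clusters of 2–4 constituent peaks within 8 kb,
  with log-normal cluster heights so that stitched signals have the
  heavy-tailed, elbow-forming distribution super-enhancer calling assumes.
* **Expression** — negative-binomial counts with per-kb tier means
  (0, 5, 50, 500) and dispersion 0.1; silent genes are exactly zero.
* **Contacts** — per-bait contact numbers Poisson around 8, distances
  log-uniform on 20 kb–2 Mb (so the 1.5-Mb cap bites), expected reads
  decaying as (distance/100 kb)$^{-0.3}$ from 30; activated-gene baits get
  2× the contacts at 0.5× the intensity of repressed-gene baits — the
  "more but weaker" contrast the per-gene summaries recover.

Gaussian i.i.d. noise (s.d. 0.4, i.e. 20% of the body mean) is added to
every track bin; negative values occur, as in input-subtracted real tracks,
and exercise the clamping path. Defaults were chosen once as the study
conditions of the test suite: effect sizes large enough to be the designed
signal, noise large enough that the exclusion and outlier rules do real
work. Class fractions default to 25% activated / 20% repressed so that
group-wise tests retain power at desk-scale gene counts.

What the generator does **not** emulate: mappability artefacts, copy-number
and GC biases, fragment-level read sampling, overlapping and nested genes,
multiple chromosomes, distance-dependent Hi-C noise structure beyond a
power-law mean. Passing tests therefore demonstrate correctness of the
computations under clean assumptions, not robustness to every artefact of
real sequencing data.

# Pipeline and reproducibility

`validateConfig()` injects the canonical defaults (PI > 2, |FC| > 1.5 with
adjusted p < 0.1, 12.5-kb stitching, ±2 kb / ±2.5 kb TSS exclusions, 5 PI
bins, 4 expression tiers, reads > 5 within 1.5 Mb, 2-s.d. outlier removal)
and warns when a supplied value deviates from them. `runPipeline()` writes
every stage output as a plain-text file, logs one line per stage, and ends
with an MD5 manifest; analysis stages re-read the files the simulation
stage wrote, so a run is reproducible from its own outputs and re-running
an unchanged configuration reproduces identical checksums. Test and
example runs use 150–1,000 genes on 5–30 Mb toy chromosomes — sizes chosen
so the whole suite exercises every code path in a couple of minutes while
keeping group sizes large enough for stable rank tests.

```{r pipeline-example, eval = FALSE}
cfg <- validateConfig(list(seed = 1L, n_genes = 200L,
                           sim = list(chromLength = 6e6)))
manifest <- runPipeline(cfg, "pipeline_out")
head(manifest)
```

# Numerical and degenerate-input choices

* Coordinates are GRanges-native (1-based closed) in memory; BED, bedGraph
  and the documented gene/interaction TSVs are 0-based half-open on disk
  and converted at the I/O boundary.
* The TSS of a minus-strand gene is its rightmost base; the TES its
  leftmost.
* Equal-frequency binning puts remainders in the lowest bins and breaks
  ties by id; all-equal keys still yield balanced bins.
* Empty windows (after clipping, or from inverted offsets) are errors, not
  empty results; fewer than three stitched enhancers make the tangent
  cutoff undefined and raise an error; an all-zero count vector makes FPKM
  undefined and raises an error.
* Paired Wilcoxon comparisons of identical summaries report p = 1 (there
  are no non-zero differences to rank); unpaired tests refuse groups of
  fewer than two genes.

# Known limitations

The package quantifies pausing from occupancy density ratios only;
GRO-seq/PRO-seq-style traveling-ratio variants are out of scope. Enhancer
calling is signal-geometry only (no H3K4me1 logic, no target-gene
assignment). The enrichment layer reports raw-p stars by convention; users
comparing many groups × bins should apply their own multiplicity control.
The interaction layer post-processes called interactions; it does not call
them.
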