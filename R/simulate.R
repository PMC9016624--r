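#' Simulation configuration
#'
#' A \code{SimConfig} fixes every knob of the synthetic-data generator: the
#' toy genome geometry, the Pol II promoter-to-body density contrast that
#' separates paused from elongating genes, histone-variant binding modes
#' (TSS-confined versus promoter-plus-body), heterochromatin domain mixtures,
#' H3K27ac enhancer clusters, negative-binomial expression tiers, and
#' distance-decaying two-replicate contact counts. One integer seed expands
#' into fixed per-component substreams (genome, each track kind, expression,
#' contacts) so that regenerating one component never perturbs another.
#'
#' Defaults encode the study conditions the analyses are exercised under:
#' half the genes paused with a 5x promoter-over-body Pol II density versus
#' 1x for elongating genes, body density 2 (above the 1.2 promoter-density
#' floor used by the pausing filter), Gaussian track noise with s.d. 0.4
#' (20\% of the body mean, so negative values occur and the zero-clamp is
#' exercised), four strictly increasing expression-tier means, and contacts
#' out to 2 Mb so the 1.5-Mb distance cap bites. Activated-gene (AG) baits
#' receive twice as many but half as intense contacts as repressed-gene (RG)
#' baits.
#'
#' @param nGenes number of genes
#' @param chromLength toy chromosome length (bp)
#' @param binSize coverage bin width (bp)
#' @param fractionPaused fraction of genes flagged paused
#' @param fractionAG,fractionRG fractions of activated / repressed genes
#'   (the remainder is neutral)
#' @param pauseRatioPaused,pauseRatioElongating promoter-to-body mean density
#'   ratios for paused and elongating genes
#' @param bodyMean mean Pol II density over gene bodies
#' @param noiseSD s.d. of the i.i.d. Gaussian per-bin track noise
#' @param tssBumpHeight,tssBumpSD height and s.d. (bp) of the TSS-confined
#'   histone-variant Gaussian bump on AG genes
#' @param plateauHeight promoter-plus-body plateau height on RG genes
#' @param domainSize heterochromatin domain width (bp)
#' @param markHigh,markLow high/low densities of the H3K27me3/H3K9me3
#'   anti-correlated domain mixture
#' @param nEnhancerClusters number of intergenic H3K27ac peak clusters
#' @param tierMeans strictly increasing per-kb mean counts of the four
#'   expression tiers (silent, low, medium, high)
#' @param nbDispersion negative-binomial dispersion (0 = Poisson-like)
#' @param contactMeanN mean number of contacts per RG/neutral bait
#' @param agCountFactor,agIntensityFactor AG multipliers on contact number
#'   and intensity
#' @param contactBaseIntensity mean read count of a reference contact at
#'   \code{contactRefDistance}
#' @param contactDecay power-law exponent of intensity decay with distance
#' @param contactRefDistance reference distance (bp) of the decay
#' @param contactMinDistance,contactMaxDistance contact distance range (bp)
#' @param seed master integer seed
#' @return a validated \code{SimConfig}
#' @export
simConfig <- function(nGenes = 1000L, chromLength = 3.0e7, binSize = 50L,
                      fractionPaused = 0.5, fractionAG = 0.25,
                      fractionRG = 0.20, pauseRatioPaused = 5,
                      pauseRatioElongating = 1, bodyMean = 2, noiseSD = 0.4,
                      tssBumpHeight = 5, tssBumpSD = 500,
                      plateauHeight = 3, domainSize = 1e5, markHigh = 3,
                      markLow = 0.3, nEnhancerClusters = 12L,
                      tierMeans = c(0, 5, 50, 500), nbDispersion = 0.1,
                      contactMeanN = 8, agCountFactor = 2,
                      agIntensityFactor = 0.5, contactBaseIntensity = 30,
                      contactDecay = 0.3, contactRefDistance = 1e5,
                      contactMinDistance = 2e4, contactMaxDistance = 2e6,
                      seed = 1L) {
    cfg <- new("SimConfig", nGenes = as.integer(nGenes),
               chromLength = as.numeric(chromLength),
               binSize = as.integer(binSize),
               fractionPaused = fractionPaused, fractionAG = fractionAG,
               fractionRG = fractionRG, pauseRatioPaused = pauseRatioPaused,
               pauseRatioElongating = pauseRatioElongating,
               bodyMean = bodyMean, noiseSD = noiseSD,
               tssBumpHeight = tssBumpHeight, tssBumpSD = tssBumpSD,
               plateauHeight = plateauHeight, domainSize = domainSize,
               markHigh = markHigh, markLow = markLow,
               nEnhancerClusters = as.integer(nEnhancerClusters),
               tierMeans = tierMeans, nbDispersion = nbDispersion,
               contactMeanN = contactMeanN, agCountFactor = agCountFactor,
               agIntensityFactor = agIntensityFactor,
               contactBaseIntensity = contactBaseIntensity,
               contactDecay = contactDecay,
               contactRefDistance = contactRefDistance,
               contactMinDistance = contactMinDistance,
               contactMaxDistance = contactMaxDistance,
               seed = as.integer(seed))
    methods::validObject(cfg)
    cfg
}

#' @rdname simConfig
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nGenes = "integer", chromLength = "numeric", binSize = "integer",
    fractionPaused = "numeric", fractionAG = "numeric",
    fractionRG = "numeric", pauseRatioPaused = "numeric",
    pauseRatioElongating = "numeric", bodyMean = "numeric",
    noiseSD = "numeric", tssBumpHeight = "numeric", tssBumpSD = "numeric",
    plateauHeight = "numeric", domainSize = "numeric", markHigh = "numeric",
    markLow = "numeric", nEnhancerClusters = "integer",
    tierMeans = "numeric", nbDispersion = "numeric",
    contactMeanN = "numeric", agCountFactor = "numeric",
    agIntensityFactor = "numeric", contactBaseIntensity = "numeric",
    contactDecay = "numeric", contactRefDistance = "numeric",
    contactMinDistance = "numeric", contactMaxDistance = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    pos <- c(nGenes = object@nGenes, chromLength = object@chromLength,
             binSize = object@binSize,
             pauseRatioPaused = object@pauseRatioPaused,
             pauseRatioElongating = object@pauseRatioElongating,
             bodyMean = object@bodyMean, domainSize = object@domainSize,
             contactMaxDistance = object@contactMaxDistance)
    bad <- pos <= 0
    if (any(bad))
        msg <- c(msg, paste("must be positive:",
                            paste(names(pos)[bad], collapse = ", ")))
    for (f in c("fractionPaused", "fractionAG", "fractionRG"))
        if (methods::slot(object, f) < 0 || methods::slot(object, f) > 1)
            msg <- c(msg, paste(f, "must lie in [0, 1]"))
    if (object@fractionAG + object@fractionRG > 1)
        msg <- c(msg, "fractionAG + fractionRG must not exceed 1")
    if (length(object@tierMeans) != 4L || any(diff(object@tierMeans) <= 0))
        msg <- c(msg, "tierMeans must be 4 strictly increasing values")
    if (object@noiseSD < 0 || object@nbDispersion < 0)
        msg <- c(msg, "noiseSD and nbDispersion must be non-negative")
    if (object@contactMinDistance >= object@contactMaxDistance)
        msg <- c(msg, "contactMinDistance must be below contactMaxDistance")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d genes on %.3g bp (bin %d bp), seed %d\n",
        "  paused %.0f%% (ratio %g vs %g, body %g, noise sd %g)\n",
        "  classes: AG %.0f%%, RG %.0f%%; tiers %s; dispersion %g\n",
        "  contacts: mean n %g (AG x%g), intensity %g (AG x%g), <= %.3g bp\n"),
        object@nGenes, object@chromLength, object@binSize, object@seed,
        100 * object@fractionPaused, object@pauseRatioPaused,
        object@pauseRatioElongating, object@bodyMean, object@noiseSD,
        100 * object@fractionAG, 100 * object@fractionRG,
        paste(object@tierMeans, collapse = "/"), object@nbDispersion,
        object@contactMeanN, object@agCountFactor,
        object@contactBaseIntensity, object@agIntensityFactor,
        object@contactMaxDistance))
    invisible(NULL)
})

# fixed substream offsets; draw order within each generator is documented by
# its code and never reordered, so adding a generator cannot perturb others
.streams <- c(genome = 101L, PolII = 211L, mH2A1.1 = 223L, H3K27ac = 227L,
              H3K27me3 = 229L, H3K9me3 = 233L, expression = 307L,
              pchic = 401L, de = 503L)

withStream <- function(config, stream, extra = 0L, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed((config@seed + .streams[[stream]] + extra) %% .Machine$integer.max)
    expr
}

simChrom <- "chrS"

#' Simulate a toy genome with ground truth
#'
#' Places \code{nGenes} non-overlapping genes of width 2--20 kb on one
#' chromosome, strands alternating, separated by 1--8 kb gaps, and draws the
#' per-gene ground truth: paused flag, regulation class (AG / RG / neutral),
#' expression tier and true per-kb expression mean. Intergenic H3K27ac
#' enhancer clusters (2--4 constituent peaks within an 8-kb span) are planted
#' in gaps. Class and flag counts are exact (rounded fractions), their
#' assignment to genes random. Deterministic under the config seed.
#'
#' @param config a \code{SimConfig}
#' @return list with \code{genes} (named, stranded \code{GRanges}),
#'   \code{truth} (data.frame: gene_id, paused, class, tier, true_mean,
#'   pause_ratio) and \code{enhancers} (\code{GRanges} of planted constituent
#'   peaks with \code{cluster} and \code{height} mcols)
#' @export
simulateGenome <- function(config) {
    withStream(config, "genome", expr = {
        n <- config@nGenes
        widths <- round(stats::runif(n, 2000, 20000))
        gaps <- round(stats::runif(n, 1000, 8000))
        starts <- cumsum(c(2000, (widths + gaps)[-n]))
        ends <- starts + widths - 1
        if (ends[n] + 2000 > config@chromLength)
            stop("genes cannot fit the chromosome: need ",
                 ends[n] + 2000, " bp, have ", config@chromLength)
        ids <- sprintf("g%04d", seq_len(n))
        genes <- GenomicRanges::GRanges(
            simChrom, IRanges::IRanges(starts, ends),
            strand = rep_len(c("+", "-"), n))
        names(genes) <- ids
        S4Vectors::mcols(genes)$gene_id <- ids

        paused <- sample(rep_len(
            c(rep(TRUE, round(config@fractionPaused * n)),
              rep(FALSE, n)), n))
        nAG <- round(config@fractionAG * n)
        nRG <- round(config@fractionRG * n)
        cls <- sample(c(rep("AG", nAG), rep("RG", nRG),
                        rep("neutral", n - nAG - nRG)))
        tier <- sample(rep_len(c("silent", "low", "medium", "high"), n))
        tierIdx <- match(tier, c("silent", "low", "medium", "high"))
        truth <- data.frame(
            gene_id = ids, paused = paused, class = cls, tier = tier,
            true_mean = config@tierMeans[tierIdx],
            pause_ratio = ifelse(paused, config@pauseRatioPaused,
                                 config@pauseRatioElongating))

        # enhancer clusters in intergenic gaps, away from gene starts
        k <- config@nEnhancerClusters
        enh <- NULL
        if (k > 0L) {
            gapIdx <- sample(seq_len(n - 1L), k)
            anchors <- ends[gapIdx] + 200
            parts <- lapply(seq_len(k), function(i) {
                m <- sample(2:4, 1L)
                offs <- sort(sample(seq(0, 7200, by = 400), m))
                w <- round(stats::runif(m, 300, 800))
                GenomicRanges::GRanges(
                    simChrom,
                    IRanges::IRanges(anchors[i] + offs, width = w),
                    cluster = i,
                    height = stats::rlnorm(1, log(8), 0.8))
            })
            enh <- do.call(c, parts)
        } else {
            enh <- GenomicRanges::GRanges(cluster = integer(),
                                          height = numeric())
        }
        list(genes = genes, truth = truth, enhancers = enh)
    })
}

paintBins <- function(v, s, e, value, binSize, add = FALSE) {
    b1 <- (s - 1) %/% binSize + 1
    b2 <- (e - 1) %/% binSize + 1
    if (add) v[b1:b2] <- v[b1:b2] + value else v[b1:b2] <- value
    v
}

#' Simulate a binned coverage track of a given kind
#'
#' Signal shapes: \code{PolII} paints each gene body at \code{bodyMean} and
#' the oriented promoter-proximal window (TSS-30 to TSS+300) at
#' \code{pause_ratio * bodyMean}; \code{mH2A1.1} adds a Gaussian bump of s.d.
#' \code{tssBumpSD} at AG TSSs (TSS-confined binding) and a flat
#' promoter-to-TES plateau over RG genes (promoter-plus-body binding);
#' \code{H3K27me3}/\code{H3K9me3} form an anti-correlated alternating domain
#' mixture (where one is high the other is low); \code{H3K27ac} paints the
#' planted enhancer constituent peaks at their cluster heights. I.i.d.
#' Gaussian noise of s.d. \code{noiseSD} is then added to every bin, so
#' negative values occur and downstream clamping is exercised.
#'
#' Painting acts on whole bins (every bin intersecting a region takes the
#' region's density; the promoter value overrides the body value in the
#' straddling bin), so with zero noise the mean signal over the bin-aligned
#' extent of a painted region equals its configured density exactly.
#'
#' @param genome output of \code{\link{simulateGenome}}
#' @param config the \code{SimConfig}
#' @param kind one of \code{"PolII"}, \code{"mH2A1.1"}, \code{"H3K27ac"},
#'   \code{"H3K27me3"}, \code{"H3K9me3"}
#' @return a \code{\linkS4class{BinnedTrack}}
#' @export
simulateTrack <- function(genome, config,
                          kind = c("PolII", "mH2A1.1", "H3K27ac",
                                   "H3K27me3", "H3K9me3")) {
    kind <- match.arg(kind)
    B <- config@binSize
    sl <- stats::setNames(config@chromLength, simChrom)
    nbins <- ceiling(config@chromLength / B)
    v <- numeric(nbins)
    genes <- genome$genes
    truth <- genome$truth
    str <- as.character(GenomicRanges::strand(genes))
    tss <- tssPositions(genes)
    tes <- tesPositions(genes)

    if (kind == "PolII") {
        for (i in seq_along(genes)) {
            body <- config@bodyMean
            s <- GenomicRanges::start(genes)[i]
            e <- GenomicRanges::end(genes)[i]
            v <- paintBins(v, s, e, body, B)
            pw <- if (str[i] == "+") c(tss[i] - 30, tss[i] + 299) else
                c(tss[i] - 299, tss[i] + 30)
            v <- paintBins(v, max(pw[1], 1), pw[2],
                           truth$pause_ratio[i] * body, B)
        }
    } else if (kind == "mH2A1.1") {
        centers <- (seq_len(nbins) - 0.5) * B
        for (i in seq_along(genes)) {
            if (truth$class[i] == "AG") {
                lo <- max(tss[i] - 4 * config@tssBumpSD, 1)
                hi <- min(tss[i] + 4 * config@tssBumpSD, config@chromLength)
                b1 <- (lo - 1) %/% B + 1; b2 <- (hi - 1) %/% B + 1
                d <- centers[b1:b2] - tss[i]
                v[b1:b2] <- v[b1:b2] + config@tssBumpHeight *
                    exp(-d^2 / (2 * config@tssBumpSD^2))
            } else if (truth$class[i] == "RG") {
                v <- paintBins(v, GenomicRanges::start(genes)[i],
                               GenomicRanges::end(genes)[i],
                               config@plateauHeight, B, add = TRUE)
            }
        }
    } else if (kind %in% c("H3K27me3", "H3K9me3")) {
        domBins <- max(1, round(config@domainSize / B))
        domain <- ((seq_len(nbins) - 1L) %/% domBins) %% 2L  # 0 = facultative
        hi <- config@markHigh; lo <- config@markLow
        v <- if (kind == "H3K27me3") ifelse(domain == 0L, hi, lo) else
            ifelse(domain == 0L, lo, hi)
    } else if (kind == "H3K27ac") {
        enh <- genome$enhancers
        if (length(enh)) {
            h <- S4Vectors::mcols(enh)$height
            for (i in seq_along(enh))
                v <- paintBins(v, GenomicRanges::start(enh)[i],
                               GenomicRanges::end(enh)[i], h[i], B,
                               add = TRUE)
        }
    }
    if (config@noiseSD > 0)
        v <- withStream(config, kind,
                        expr = v + stats::rnorm(nbins, 0, config@noiseSD))
    BinnedTrack(stats::setNames(list(v), simChrom), binSize = B,
                seqlengths = sl)
}

#' Simulate a gene-level count table
#'
#' Counts are negative binomial with mean \code{true_mean * width/1kb} and
#' dispersion \code{nbDispersion} (dispersion 0 falls back to Poisson);
#' silent-tier genes have mean 0 and therefore zero counts.
#'
#' @param genome output of \code{\link{simulateGenome}}
#' @param config the \code{SimConfig}
#' @return data.frame: gene_id, length, count
#' @export
simulateExpression <- function(genome, config) {
    withStream(config, "expression", expr = {
        len <- GenomicRanges::width(genome$genes)
        mu <- genome$truth$true_mean * len / 1000
        counts <- if (config@nbDispersion > 0)
            stats::rnbinom(length(mu), mu = mu,
                           size = 1 / config@nbDispersion)
        else stats::rpois(length(mu), mu)
        data.frame(gene_id = genome$truth$gene_id, length = len,
                   count = counts)
    })
}

#' Simulate a differential-expression statistics table
#'
#' Convenience generator of the DESeq2-style statistics table the expression
#' filter consumes: AG genes get linear fold changes well below 1/1.5 with
#' small adjusted p, RG genes well above 1.5, neutral genes hover around 1
#' with large p. Fold changes are on the linear ratio scale.
#'
#' @param genome output of \code{\link{simulateGenome}}
#' @param config the \code{SimConfig}
#' @return data.frame: gene_id, fold_change, adjusted_p
#' @export
simulateDETable <- function(genome, config) {
    withStream(config, "de", expr = {
        cls <- genome$truth$class
        n <- length(cls)
        fc <- exp(stats::rnorm(n, 0, 0.08))
        fc[cls == "AG"] <- exp(stats::rnorm(sum(cls == "AG"), log(0.4), 0.2))
        fc[cls == "RG"] <- exp(stats::rnorm(sum(cls == "RG"), log(2.5), 0.2))
        padj <- stats::runif(n, 0.2, 1)
        padj[cls != "neutral"] <- stats::runif(sum(cls != "neutral"),
                                               0, 0.05)
        data.frame(gene_id = genome$truth$gene_id, fold_change = fc,
                   adjusted_p = padj)
    })
}

#' Simulate a two-replicate promoter-capture interaction table
#'
#' Each gene is a bait (bait interval = TSS +/- 2.5 kb). The number of
#' contacts per bait is Poisson with mean \code{contactMeanN}, multiplied by
#' \code{agCountFactor} for AG baits; contact distances follow a log-uniform
#' law on [\code{contactMinDistance}, \code{contactMaxDistance}] (so
#' distances beyond the 1.5-Mb analysis cap occur); the expected read count
#' of a contact decays as \code{(distance/contactRefDistance)^-contactDecay}
#' from \code{contactBaseIntensity}, multiplied by \code{agIntensityFactor}
#' for AG baits; replicate counts are independent negative binomials around
#' that intensity. AG baits therefore carry more but weaker contacts than RG
#' baits, the contrast the per-gene summaries are meant to recover.
#'
#' @param genome output of \code{\link{simulateGenome}}
#' @param config the \code{SimConfig}
#' @param nFactor,intensityFactor global multipliers applied to every bait's
#'   contact number and intensity (e.g. to derive a perturbed condition)
#' @param streamOffset extra offset added to the contact substream so
#'   different conditions draw independent streams
#' @return data.frame in the interaction-table layout (see
#'   \code{\link{readInteractions}}) plus \code{true_intensity}
#' @export
simulatePCHiC <- function(genome, config, nFactor = 1, intensityFactor = 1,
                          streamOffset = 0L) {
    withStream(config, "pchic", extra = streamOffset, expr = {
        genes <- genome$genes
        truth <- genome$truth
        tss <- tssPositions(genes)
        isAG <- truth$class == "AG"
        nMean <- config@contactMeanN * ifelse(isAG, config@agCountFactor, 1) *
            nFactor
        nPer <- stats::rpois(length(genes), nMean)
        tot <- sum(nPer)
        if (tot == 0L)
            return(data.frame(bait_chrom = character(),
                              bait_start = integer(), bait_end = integer(),
                              bait_id = character(), oe_chrom = character(),
                              oe_start = integer(), oe_end = integer(),
                              count_rep1 = integer(), count_rep2 = integer(),
                              true_intensity = numeric()))
        bait <- rep(seq_along(genes), nPer)
        u <- stats::runif(tot)
        d <- round(config@contactMinDistance *
                   (config@contactMaxDistance / config@contactMinDistance)^u)
        side <- sample(c(-1, 1), tot, replace = TRUE)
        mid <- pmin(pmax(tss[bait] + side * d, 5000),
                    config@chromLength - 5000)
        intensity <- config@contactBaseIntensity *
            ifelse(isAG[bait], config@agIntensityFactor, 1) *
            intensityFactor *
            (abs(mid - tss[bait]) / config@contactRefDistance)^
                (-config@contactDecay)
        size <- if (config@nbDispersion > 0) 1 / config@nbDispersion else Inf
        r1 <- stats::rnbinom(tot, mu = intensity, size = size)
        r2 <- stats::rnbinom(tot, mu = intensity, size = size)
        data.frame(
            bait_chrom = simChrom,
            bait_start = pmax(tss[bait] - 2500, 0),
            bait_end = tss[bait] + 2500,
            bait_id = truth$gene_id[bait],
            oe_chrom = simChrom,
            oe_start = as.integer(mid - 2500),
            oe_end = as.integer(mid + 2500),
            count_rep1 = r1, count_rep2 = r2,
            true_intensity = intensity)
    })
}
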