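# Small in-code fixtures shared across tests.

# a single-chromosome track from a bin-value vector
makeTrack <- function(values, binSize = 50L, chrom = "chr1",
                      chromLength = length(values) * binSize) {
    BinnedTrack(stats::setNames(list(values), chrom), binSize = binSize,
                seqlengths = stats::setNames(chromLength, chrom))
}

# a stranded gene set from parallel vectors (1-based closed coordinates)
makeGenes <- function(start, end, strand = "+", chrom = "chr1",
                      ids = sprintf("g%02d", seq_along(start))) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    names(gr) <- ids
    S4Vectors::mcols(gr)$gene_id <- ids
    gr
}

# per-bp expansion of a track chromosome: the brute-force signal oracle
expandTrack <- function(track, chrom = names(trackBins(track))[1]) {
    v <- trackBins(track)[[chrom]]
    L <- seqlengths(track)[[chrom]]
    rep(v, each = binSize(track))[seq_len(L)]
}

# mean per-bp signal by direct expansion (oracle for regionSignal)
bruteSignal <- function(track, chrom, start, end) {
    bp <- expandTrack(track, chrom)
    mean(bp[start:end])
}

# exhaustive fixed-margin two-sided Fisher p oracle via lchoose arithmetic
enumFisherP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    x <- max(0, c1 - r2):min(r1, c1)
    logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
    probs <- exp(logp)
    pObs <- probs[x == a]
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# brute-force slope-1 tangent scan (super-enhancer cutoff oracle):
# for each candidate, count points strictly below the unit-square slope-1
# line through it; tangent-from-below candidates have none below; the
# rightmost such point is the cutoff.
oracleSuperFlags <- function(signal) {
    n <- length(signal)
    if (max(signal) == min(signal)) return(rep(FALSE, n))
    sorted <- sort(signal)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (sorted - min(sorted)) / (max(sorted) - min(sorted))
    below <- vapply(seq_len(n), function(j)
        sum(y < x + (y[j] - x[j]) - 1e-12), numeric(1))
    idx <- max(which(below == 0))
    signal > sorted[idx]
}
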