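#' Facultative- vs constitutive-like heterochromatin scoring
#'
#' For each domain, computes the mean H3K27me3 and H3K9me3 densities and
#' their difference D = k27_mean - k9_mean. Domains where H3K27me3 dominates
#' (D > 0) are facultative-like heterochromatin; otherwise (D <= 0, including
#' the boundary) constitutive-like. The boundary at D = 0 presumes
#' input-normalized, mutually comparable tracks.
#'
#' @param k27Track,k9Track \code{BinnedTrack}s of H3K27me3 and H3K9me3
#' @param domains \code{GRanges} of domains to score
#' @return data.frame: k27_mean, k9_mean, D, class (one row per domain;
#'   zero rows for an empty input)
#' @export
scoreDomains <- function(k27Track, k9Track, domains) {
    if (length(domains) == 0L)
        return(data.frame(k27_mean = numeric(), k9_mean = numeric(),
                          D = numeric(), class = character()))
    k27 <- regionSignal(k27Track, domains)
    k9 <- regionSignal(k9Track, domains)
    D <- k27 - k9
    data.frame(k27_mean = k27, k9_mean = k9, D = D,
               class = ifelse(D > 0, "facultative_like",
                              "constitutive_like"))
}

#' Enhancer seeds: H3K27ac peaks outside TSS windows
#'
#' Removes peaks overlapping any TSS +/- \code{tssExclusion} window (to
#' avoid promoter H3K27ac bias) and returns the remainder sorted.
#'
#' @param peaks \code{GRanges} of H3K27ac peaks
#' @param genes stranded \code{GRanges}; may be empty (no exclusion)
#' @param tssExclusion flank in bp (default 2000; the super-enhancer preset
#'   uses 2500, see \code{\link{superEnhancerPipeline}})
#' @return sorted \code{GRanges} of retained peaks
#' @export
callEnhancerSeeds <- function(peaks, genes, tssExclusion = 2000L) {
    if (length(genes)) {
        tss <- tssPositions(genes)
        win <- GenomicRanges::GRanges(
            as.character(GenomicRanges::seqnames(genes)),
            IRanges::IRanges(pmax(tss - tssExclusion, 1),
                             tss + tssExclusion))
        keep <- GenomicRanges::countOverlaps(peaks, win,
                                             ignore.strand = TRUE) == 0L
        peaks <- peaks[keep]
    }
    GenomicRanges::sort(peaks, ignore.strand = TRUE)
}

#' Stitch enhancer seeds into (super-)enhancer candidates
#'
#' Seeds separated by gaps of at most \code{stitchDistance} (measured
#' between half-open interval ends; a gap of exactly the distance merges)
#' are merged transitively. The stitched signal is the sum of the
#' constituents' \code{signal} metadata column.
#'
#' @param seeds \code{GRanges} with a numeric \code{signal} mcol (e.g. from
#'   \code{\link{peakSignal}})
#' @param stitchDistance maximum gap in bp (default 12500)
#' @return \code{GRanges} of stitched regions with mcols
#'   \code{n_constituents} and \code{signal}
#' @export
stitchEnhancers <- function(seeds, stitchDistance = 12500L) {
    if (is.null(S4Vectors::mcols(seeds)$signal))
        stop("seeds need a 'signal' metadata column")
    red <- GenomicRanges::reduce(seeds,
                                 min.gapwidth = stitchDistance + 1L,
                                 with.revmap = TRUE, ignore.strand = TRUE)
    rev <- S4Vectors::mcols(red)$revmap
    S4Vectors::mcols(red) <- NULL
    S4Vectors::mcols(red)$n_constituents <- lengths(rev)
    S4Vectors::mcols(red)$signal <- vapply(
        rev, function(i) sum(S4Vectors::mcols(seeds)$signal[i]), numeric(1))
    red
}

#' Super-enhancer call by the rank-curve tangent cutoff
#'
#' Standard rank-curve geometry: stitched enhancers are sorted by signal
#' ascending, ranks and signals are rescaled to the unit square, and the
#' cutoff sits at the point where a slope-1 line is tangent to the curve
#' from below (the point most below the unit diagonal; rightmost on ties).
#' Enhancers with signal strictly above the cutoff signal are flagged
#' super-enhancers. With all-equal signals there is no elbow and nothing is
#' flagged.
#'
#' @param stitched output of \code{\link{stitchEnhancers}} (at least 3
#'   regions, otherwise the cutoff is undefined)
#' @return \code{stitched} with added mcols \code{rank} (1 = strongest) and
#'   \code{is_super}; the cutoff signal is stored in
#'   \code{S4Vectors::metadata()$cutoff}
#' @export
callSuperEnhancers <- function(stitched) {
    n <- length(stitched)
    if (n < 3L)
        stop("need at least 3 stitched enhancers to place a cutoff; have ",
             n)
    s <- S4Vectors::mcols(stitched)$signal
    S4Vectors::mcols(stitched)$rank <- as.integer(rank(-s,
        ties.method = "first"))
    if (max(s) == min(s)) {
        S4Vectors::mcols(stitched)$is_super <- rep(FALSE, n)
        S4Vectors::metadata(stitched)$cutoff <- max(s)
        return(stitched)
    }
    sorted <- sort(s)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (sorted - min(sorted)) / (max(sorted) - min(sorted))
    d <- y - x
    idx <- max(which(d <= min(d) + 1e-12))
    cutoff <- sorted[idx]
    S4Vectors::mcols(stitched)$is_super <- s > cutoff
    S4Vectors::metadata(stitched)$cutoff <- cutoff
    stitched
}

#' Enhancer / super-enhancer pipeline preset
#'
#' Seeds from peaks outside TSS windows, constituent signal from the
#' H3K27ac track, stitching at 12.5 kb, tangent-cutoff super-enhancer call.
#' The TSS exclusion defaults to the super-enhancer preset of 2.5 kb (the
#' plain enhancer definition uses 2 kb).
#'
#' @param peaks H3K27ac peak \code{GRanges}
#' @param genes stranded gene \code{GRanges}
#' @param track H3K27ac \code{BinnedTrack}
#' @param tssExclusion flank in bp (default 2500)
#' @param stitchDistance stitching gap in bp (default 12500)
#' @return the \code{GRanges} of \code{\link{callSuperEnhancers}}
#' @export
superEnhancerPipeline <- function(peaks, genes, track, tssExclusion = 2500L,
                                  stitchDistance = 12500L) {
    seeds <- callEnhancerSeeds(peaks, genes, tssExclusion)
    S4Vectors::mcols(seeds)$signal <- peakSignal(track, seeds)
    callSuperEnhancers(stitchEnhancers(seeds, stitchDistance))
}
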