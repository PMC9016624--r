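#' Anchor-centered signal matrix
#'
#' One row per anchor (e.g. a TSS), one column per fixed-width bin spanning
#' anchor - flank to anchor + flank. With \code{orientByStrand}, rows of
#' minus-strand anchors are reversed so downstream-of-anchor is always
#' rightward; without it, gene directionality is ignored. Rows partially
#' outside the chromosome are zero-padded and flagged rather than dropped.
#'
#' @param track a \code{\linkS4class{BinnedTrack}}
#' @param anchors stranded \code{GRanges}; the anchor point of each range is
#'   its TSS (strand-aware 5' end)
#' @param flank half-window in bp (multiple of \code{binSize})
#' @param binSize matrix column width in bp (default the track's bin size)
#' @param orientByStrand reverse minus-strand rows (default TRUE)
#' @return numeric matrix (rownames = anchor names) with attributes
#'   \code{binSize}, \code{flank}, \code{binCenters} (bp relative to
#'   anchor), \code{clipped} (logical per row), \code{oriented}
#' @export
buildMatrix <- function(track, anchors, flank = 2000L,
                        binSize = NULL, orientByStrand = TRUE) {
    if (is.null(binSize)) binSize <- binSize(track)
    if (flank < binSize)
        stop("flank must be at least one bin wide")
    if (flank %% binSize != 0L)
        stop("flank must be a multiple of binSize")
    ncol <- as.integer(2L * flank / binSize)
    a <- tssPositions(anchors)
    chrom <- as.character(GenomicRanges::seqnames(anchors))
    if (any(!chrom %in% names(trackBins(track))))
        stop("anchors on chromosomes absent from the track")
    str <- as.character(GenomicRanges::strand(anchors))
    sl <- seqlengths(track)
    n <- length(anchors)
    mat <- matrix(0, nrow = n, ncol = ncol)
    clipped <- logical(n)
    # all (row, bin) windows at once, then clip; matrix columns are in
    # transcription order when orienting, so for minus-strand anchors bin j
    # covers the mirrored genomic interval (exact strand symmetry)
    rowIdx <- rep(seq_len(n), each = ncol)
    binIdx <- rep(seq_len(ncol), n)
    minus <- orientByStrand & str[rowIdx] == "-"
    st <- ifelse(minus,
                 a[rowIdx] + flank - binIdx * binSize + 1L,
                 a[rowIdx] - flank + (binIdx - 1L) * binSize)
    en <- st + binSize - 1L
    ch <- chrom[rowIdx]
    inside <- st >= 1L & en <= sl[ch]
    clipped <- tapply(!inside, rowIdx, any)
    if (any(inside)) {
        gr <- GenomicRanges::GRanges(ch[inside],
                                     IRanges::IRanges(st[inside],
                                                      en[inside]))
        mat[cbind(rowIdx[inside], binIdx[inside])] <- regionSignal(track, gr)
    }
    rownames(mat) <- names(anchors)
    attr(mat, "binSize") <- binSize
    attr(mat, "flank") <- flank
    attr(mat, "binCenters") <- -flank + (seq_len(ncol) - 0.5) * binSize
    attr(mat, "clipped") <- as.logical(clipped)
    attr(mat, "oriented") <- orientByStrand
    mat
}

#' Metagene profile: per-bin mean and s.e.m. with outlier removal
#'
#' Rows whose row-mean deviates from the grand mean of row-means by more
#' than \code{outlierSD} standard deviations are treated as outlier regions
#' and removed; the profile is the per-column mean and standard error
#' (sd / sqrt(n)) over the retained rows.
#'
#' @param mat an anchor matrix from \code{\link{buildMatrix}} (any numeric
#'   matrix works)
#' @param outlierSD z-score threshold on row means (default 2)
#' @return data.frame: bin_center (bp, when the matrix carries bin centers),
#'   mean, sem; the retained row count is in \code{attr(, "n_used")} and the
#'   kept-row mask in \code{attr(, "kept")}
#' @export
metageneProfile <- function(mat, outlierSD = 2) {
    if (!is.matrix(mat) || nrow(mat) == 0L)
        stop("need a non-empty matrix")
    rm <- rowMeans(mat)
    s <- stats::sd(rm)
    kept <- if (is.na(s) || s == 0) rep(TRUE, nrow(mat)) else
        abs(rm - mean(rm)) <= outlierSD * s
    if (!any(kept))
        stop("outlier removal dropped every row")
    sub <- mat[kept, , drop = FALSE]
    n <- nrow(sub)
    mu <- colMeans(sub)
    sem <- if (n > 1L) apply(sub, 2L, stats::sd) / sqrt(n) else
        rep(NA_real_, ncol(sub))
    centers <- attr(mat, "binCenters")
    if (is.null(centers)) centers <- seq_len(ncol(mat))
    out <- data.frame(bin_center = centers, mean = mu, sem = sem,
                      row.names = NULL)
    attr(out, "n_used") <- n
    attr(out, "kept") <- kept
    out
}

#' Rank matrix rows by a key
#'
#' Stable descending sort (ties by row name), e.g. ranking genes by their
#' TSS-proximal ChIP signal for heatmap display.
#'
#' @param mat numeric matrix with row names
#' @param key numeric vector aligned with rows
#' @return the row-permuted matrix (attributes preserved)
#' @export
rankMatrix <- function(mat, key) {
    stopifnot(length(key) == nrow(mat))
    ord <- order(-key, rownames(mat))
    out <- mat[ord, , drop = FALSE]
    for (at in c("binSize", "flank", "binCenters", "oriented"))
        attr(out, at) <- attr(mat, at)
    attr(out, "clipped") <- attr(mat, "clipped")[ord]
    out
}
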