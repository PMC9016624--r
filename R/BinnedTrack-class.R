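#' BinnedTrack: fixed-bin genomic coverage signal
#'
#' A \code{BinnedTrack} stores one real-valued signal value per fixed-width
#' genomic bin, per chromosome. It is the in-memory surrogate of a binned,
#' input-normalized coverage track (a bedGraph/bigWig exported at a fixed bin
#' width, 50 bp by default). Values may be negative: input-subtracted RPKM
#' tracks routinely dip below zero, and \code{\link{clampNegative}} exists to
#' zero them where an analysis requires non-negative densities.
#'
#' @slot bins named list, one numeric vector per chromosome; element
#'   \code{i} of a vector is the signal over bases
#'   \code{[(i-1)*binSize + 1, i*binSize]} (1-based, clipped at the
#'   chromosome end for the last bin).
#' @slot binSize integer bin width in base pairs.
#' @slot seqlengths named integer vector of chromosome lengths in bp.
#'
#' @aliases BinnedTrack-class
#' @exportClass BinnedTrack
setClass("BinnedTrack",
    representation(bins = "list", binSize = "integer", seqlengths = "integer"))

setValidity("BinnedTrack", function(object) {
    msg <- character()
    if (length(object@binSize) != 1L || is.na(object@binSize) ||
        object@binSize <= 0L)
        msg <- c(msg, "binSize must be a single positive integer")
    if (is.null(names(object@bins)) || is.null(names(object@seqlengths)) ||
        !identical(sort(names(object@bins)), sort(names(object@seqlengths))))
        msg <- c(msg, "bins and seqlengths must share chromosome names")
    else {
        for (chrom in names(object@bins)) {
            v <- object@bins[[chrom]]
            expected <- as.integer(
                ceiling(object@seqlengths[[chrom]] / object@binSize))
            if (length(v) != expected)
                msg <- c(msg, sprintf(
                    "chromosome '%s': %d bins, expected %d", chrom,
                    length(v), expected))
            if (anyNA(v) || any(!is.finite(v)))
                msg <- c(msg, sprintf(
                    "chromosome '%s': non-finite bin values", chrom))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BinnedTrack
#'
#' @param bins named list of numeric vectors (one per chromosome), or a single
#'   numeric vector when \code{seqlengths} names a single chromosome.
#' @param binSize bin width in bp (default 50, the conventional export width).
#' @param seqlengths named vector of chromosome lengths in bp.
#' @return A \code{\linkS4class{BinnedTrack}}.
#' @examples
#' tr <- BinnedTrack(list(chr1 = c(2, 4)), binSize = 50,
#'                   seqlengths = c(chr1 = 100))
#' regionSignal(tr, GenomicRanges::GRanges("chr1:1-100"))
#' @export
BinnedTrack <- function(bins, binSize = 50L, seqlengths) {
    if (is.numeric(bins) && !is.list(bins)) {
        if (length(seqlengths) != 1L)
            stop("a bare numeric 'bins' vector needs a single chromosome")
        bins <- stats::setNames(list(as.numeric(bins)), names(seqlengths))
    }
    bins <- lapply(bins, as.numeric)
    new("BinnedTrack", bins = bins, binSize = as.integer(binSize),
        seqlengths = stats::setNames(as.integer(seqlengths),
                                     names(seqlengths)))
}

#' @describeIn BinnedTrack bin width in bp
#' @param x,object a \code{BinnedTrack}
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedTrack
#' @export
setMethod("binSize", "BinnedTrack", function(x) x@binSize)

#' @describeIn BinnedTrack per-chromosome bin vectors (named list)
#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))

#' @rdname BinnedTrack
#' @export
setMethod("trackBins", "BinnedTrack", function(x) x@bins)

#' @rdname BinnedTrack
#' @importFrom GenomeInfoDb seqlengths
#' @export
setMethod("seqlengths", "BinnedTrack", function(x) x@seqlengths)

setMethod("show", "BinnedTrack", function(object) {
    cat(sprintf("BinnedTrack with %d chromosome(s), bin size %d bp\n",
                length(object@bins), object@binSize))
    for (chrom in names(object@bins)) {
        v <- object@bins[[chrom]]
        cat(sprintf("  %s: %d bp, %d bins, signal range [%.4g, %.4g]\n",
                    chrom, object@seqlengths[[chrom]], length(v),
                    if (length(v)) min(v) else NA, if (length(v)) max(v)
                    else NA))
    }
    invisible(NULL)
})

#' Mean per-bp signal over genomic regions
#'
#' The signal over a region is the bin-value-weighted sum of overlapped bases
#' divided by the region width, i.e. the mean per-bp signal with partial bins
#' pro-rated by the number of bases they contribute. This is the binned
#' equivalent of summing a coverage track over a region and normalizing to the
#' region's width.
#'
#' @param x a \code{\linkS4class{BinnedTrack}}
#' @param regions a \code{GRanges} of query regions, all within the track's
#'   chromosome bounds
#' @return numeric vector, one mean per-bp value per region
#' @export
setGeneric("regionSignal", function(x, regions) standardGeneric("regionSignal"))

#' @rdname regionSignal
#' @importFrom GenomicRanges seqnames start end width
#' @export
setMethod("regionSignal", "BinnedTrack", function(x, regions) {
    chroms <- as.character(GenomicRanges::seqnames(regions))
    bad <- !(chroms %in% names(x@bins))
    if (any(bad))
        stop("regions on chromosomes absent from the track: ",
             paste(unique(chroms[bad]), collapse = ", "))
    s <- GenomicRanges::start(regions)
    e <- GenomicRanges::end(regions)
    if (any(s < 1L) || any(e > x@seqlengths[chroms]))
        stop("regions outside chromosome bounds")
    B <- x@binSize
    out <- numeric(length(regions))
    for (chrom in unique(chroms)) {
        idx <- which(chroms == chrom)
        v <- x@bins[[chrom]]
        cs <- cumsum(v)
        si <- s[idx]; ei <- e[idx]
        b1 <- (si - 1L) %/% B + 1L
        b2 <- (ei - 1L) %/% B + 1L
        same <- b1 == b2
        tot <- numeric(length(idx))
        # single-bin regions
        tot[same] <- v[b1[same]] * (ei[same] - si[same] + 1)
        if (any(!same)) {
            i <- which(!same)
            left <- v[b1[i]] * (b1[i] * B - si[i] + 1)
            right <- v[b2[i]] * (ei[i] - (b2[i] - 1L) * B)
            mid <- ifelse(b2[i] - b1[i] > 1L,
                          (cs[b2[i] - 1L] - cs[b1[i]]) * B, 0)
            tot[i] <- left + mid + right
        }
        out[idx] <- tot / (ei - si + 1)
    }
    out
})

#' Replace negative bin values by zero
#'
#' Input-subtracted coverage can be negative; pausing-index densities are
#' computed on the zero-clamped track.
#'
#' @param x a \code{\linkS4class{BinnedTrack}}
#' @return a \code{BinnedTrack} with every bin value \code{max(value, 0)}
#' @export
setGeneric("clampNegative", function(x) standardGeneric("clampNegative"))

#' @rdname clampNegative
#' @export
setMethod("clampNegative", "BinnedTrack", function(x) {
    x@bins <- lapply(x@bins, pmax, 0)
    x
})

#' Scale every bin value by a constant
#'
#' @param x a \code{BinnedTrack}
#' @param factor multiplicative constant
#' @return the rescaled track
#' @export
scaleTrack <- function(x, factor) {
    stopifnot(is(x, "BinnedTrack"), is.numeric(factor), length(factor) == 1L)
    x@bins <- lapply(x@bins, `*`, factor)
    x
}

#' An all-zero track over given chromosomes
#'
#' @param seqlengths named chromosome lengths (bp)
#' @param binSize bin width (bp)
#' @return a \code{BinnedTrack} of zeros
#' @export
emptyTrack <- function(seqlengths, binSize = 50L) {
    bins <- lapply(seqlengths, function(L) numeric(ceiling(L / binSize)))
    BinnedTrack(bins, binSize = binSize, seqlengths = seqlengths)
}
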