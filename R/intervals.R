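#' Strand-oriented anchor positions of genes
#'
#' The transcription start site (TSS) of a plus-strand gene is its leftmost
#' base; of a minus-strand gene its rightmost base. The transcription end site
#' (TES) is the opposite terminus. Positions are 1-based.
#'
#' @param genes a stranded \code{GRanges} (strand strictly \code{+} or
#'   \code{-})
#' @return integer vector of 1-based positions
#' @export
tssPositions <- function(genes) {
    str <- checkStrand(genes)
    ifelse(str == "+", GenomicRanges::start(genes), GenomicRanges::end(genes))
}

#' @rdname tssPositions
#' @export
tesPositions <- function(genes) {
    str <- checkStrand(genes)
    ifelse(str == "+", GenomicRanges::end(genes), GenomicRanges::start(genes))
}

checkStrand <- function(genes) {
    str <- as.character(GenomicRanges::strand(genes))
    if (any(!str %in% c("+", "-")))
        stop("genes must be stranded ('+' or '-')")
    str
}

#' Strand-aware window around a gene anchor
#'
#' Builds, for each gene, the interval covering transcription-direction
#' offsets \code{[offset5, offset3)} relative to the chosen anchor (TSS or
#' TES), where negative offsets point upstream. The canonical promoter-
#' proximal window is \code{strandWindow(genes, -30, 300, "TSS")} and the
#' transcribed-region window is \code{strandWindow(genes, 300, width, "TSS")}.
#' Windows are clipped to chromosome bounds when \code{seqlengths} is given;
#' clipping is recorded in the \code{clipped} metadata column.
#'
#' @param genes stranded \code{GRanges}
#' @param offset5,offset3 offsets in bp along the direction of transcription;
#'   the window spans offsets \code{offset5} (inclusive) to \code{offset3}
#'   (exclusive), so its width is \code{offset3 - offset5}
#' @param anchor \code{"TSS"} or \code{"TES"}
#' @param seqlengths optional named chromosome lengths used for clipping
#' @return \code{GRanges} of windows, unstranded width \code{offset3 -
#'   offset5} (less where clipped), with mcols \code{gene_id} (names of
#'   \code{genes}, if any) and \code{clipped}
#' @export
strandWindow <- function(genes, offset5, offset3, anchor = c("TSS", "TES"),
                         seqlengths = NULL) {
    anchor <- match.arg(anchor)
    offset5 <- rep_len(offset5, length(genes))
    offset3 <- rep_len(offset3, length(genes))
    if (any(offset3 <= offset5))
        stop("empty window: offset3 must exceed offset5")
    str <- checkStrand(genes)
    a <- if (anchor == "TSS") tssPositions(genes) else tesPositions(genes)
    plus <- str == "+"
    st <- ifelse(plus, a + offset5, a - offset3 + 1)
    en <- ifelse(plus, a + offset3 - 1, a - offset5)
    chrom <- as.character(GenomicRanges::seqnames(genes))
    clipped <- rep(FALSE, length(genes))
    clipped[st < 1L] <- TRUE
    st <- pmax(st, 1)
    if (!is.null(seqlengths)) {
        lim <- seqlengths[chrom]
        clipped[en > lim] <- TRUE
        en <- pmin(en, lim)
    }
    if (any(en < st))
        stop("window empty after clipping for gene(s): ",
             paste(utils::head(which(en < st)), collapse = ", "))
    out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
    S4Vectors::mcols(out)$clipped <- clipped
    if (!is.null(names(genes)))
        S4Vectors::mcols(out)$gene_id <- names(genes)
    names(out) <- names(genes)
    out
}

#' All overlapping pairs between two interval sets
#'
#' Thin surface over \code{GenomicRanges::findOverlaps}: returns every
#' (queryIndex, subjectIndex) pair overlapping by at least \code{minOverlap}
#' bases, under half-open-at-the-boundary semantics (a region ending where
#' another starts does not overlap it).
#'
#' @param setA,setB \code{GRanges}
#' @param minOverlap minimum overlap in bp (default 1)
#' @return data.frame with columns \code{queryIndex}, \code{subjectIndex}
#' @export
overlapPairs <- function(setA, setB, minOverlap = 1L) {
    hits <- GenomicRanges::findOverlaps(setA, setB,
                                        minoverlap = as.integer(minOverlap))
    data.frame(queryIndex = S4Vectors::queryHits(hits),
               subjectIndex = S4Vectors::subjectHits(hits))
}

#' Assign peaks to promoter / gene body / distal categories
#'
#' A peak overlapping any promoter window (TSS +/- \code{promoterFlank}) is a
#' promoter peak; otherwise, a peak overlapping any gene interval is a
#' gene-body peak; everything else is distal intergenic. The precedence
#' promoter > gene_body > distal_intergenic is applied per peak.
#'
#' @param peaks \code{GRanges} of peaks
#' @param genes stranded \code{GRanges} of genes
#' @param promoterFlank half-width of the promoter window in bp (default 1000)
#' @return \code{peaks} with an added \code{category} factor mcol; the
#'   category proportions are stored in
#'   \code{S4Vectors::metadata()$proportions}
#' @export
annotatePeaks <- function(peaks, genes, promoterFlank = 1000L) {
    if (length(genes) == 0L)
        stop("annotatePeaks needs a non-empty gene set")
    tss <- tssPositions(genes)
    chrom <- as.character(GenomicRanges::seqnames(genes))
    prom <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(pmax(tss - promoterFlank, 1),
                                tss + promoterFlank))
    inProm <- GenomicRanges::countOverlaps(peaks, prom) > 0L
    inBody <- GenomicRanges::countOverlaps(peaks, genes) > 0L
    category <- factor(
        ifelse(inProm, "promoter",
               ifelse(inBody, "gene_body", "distal_intergenic")),
        levels = c("promoter", "gene_body", "distal_intergenic"))
    S4Vectors::mcols(peaks)$category <- category
    props <- if (length(peaks)) table(category) / length(peaks) else
        table(category)
    S4Vectors::metadata(peaks)$proportions <- as.numeric(props) |>
        stats::setNames(names(props))
    peaks
}

#' Total (width-integrated) track signal over each peak
#'
#' \code{regionSignal} times the region width: the summed per-bp signal of a
#' peak, used as the constituent signal for enhancer stitching.
#'
#' @param track a \code{BinnedTrack}
#' @param peaks \code{GRanges}
#' @return numeric vector of total signal per peak
#' @export
peakSignal <- function(track, peaks) {
    regionSignal(track, peaks) * GenomicRanges::width(peaks)
}
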