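#' Read a gene annotation table
#'
#' The gene table is a tab-separated file with header
#' \code{chrom, start, end, strand, gene_id}; coordinates are 0-based
#' half-open (BED convention). Records are validated one by one and rejected
#' with the offending line number (header = line 1).
#'
#' @param path file path
#' @return named, stranded \code{GRanges}; names and the \code{gene_id} mcol
#'   carry the gene identifiers, input order is preserved
#' @export
readGeneTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "gene_id")
    if (!all(need %in% names(df)))
        stop("gene table must have columns: ", paste(need, collapse = ", "))
    lineNo <- seq_len(nrow(df)) + 1L
    bad <- !df$strand %in% c("+", "-")
    if (any(bad))
        stop("invalid strand at line ", lineNo[which(bad)[1L]],
             " (must be '+' or '-')")
    bad <- !is.finite(df$start) | !is.finite(df$end) | df$start < 0 |
        df$end <= df$start
    if (any(bad))
        stop("invalid coordinates (need 0 <= start < end) at line ",
             lineNo[which(bad)[1L]])
    dup <- duplicated(df$gene_id)
    if (any(dup))
        stop("duplicate gene_id '", df$gene_id[which(dup)[1L]],
             "' at line ", lineNo[which(dup)[1L]])
    gr <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start + 1L, df$end),
        strand = df$strand)
    names(gr) <- df$gene_id
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    gr
}

#' @rdname readGeneTable
#' @param genes named, stranded \code{GRanges}
#' @export
writeGeneTable <- function(genes, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                     start = GenomicRanges::start(genes) - 1L,
                     end = GenomicRanges::end(genes),
                     strand = as.character(GenomicRanges::strand(genes)),
                     gene_id = names(genes))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a bedGraph file into a BinnedTrack
#'
#' Every record must be aligned to the bin grid (start and end multiples of
#' \code{binSize} in the file's 0-based half-open coordinates); a record may
#' span several bins, in which case all covered bins take its value. Bins not
#' covered by any record are zero.
#'
#' @param path bedGraph path
#' @param binSize bin width in bp (default 50)
#' @param chromSizes named chromosome lengths in bp
#' @return a \code{\linkS4class{BinnedTrack}}
#' @export
readBedGraph <- function(path, binSize = 50L, chromSizes) {
    track <- emptyTrack(chromSizes, binSize)
    if (file.info(path)$size == 0) return(track)
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) return(track)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (any(!chrom %in% names(chromSizes)))
        stop("bedGraph chromosome absent from chromSizes: ",
             paste(setdiff(unique(chrom), names(chromSizes)), collapse = ", "))
    s0 <- GenomicRanges::start(gr) - 1L   # back to 0-based half-open
    e0 <- GenomicRanges::end(gr)
    if (any(s0 %% binSize != 0L | e0 %% binSize != 0L))
        stop("bedGraph record not aligned to the ", binSize, "-bp bin grid")
    val <- S4Vectors::mcols(gr)$score
    if (!is.numeric(val) || anyNA(val))
        stop("bedGraph values must be numeric")
    bins <- track@bins
    for (i in seq_along(gr)) {
        b1 <- s0[i] %/% binSize + 1L
        b2 <- e0[i] %/% binSize
        bins[[chrom[i]]][b1:b2] <- val[i]
    }
    BinnedTrack(bins, binSize = binSize, seqlengths = chromSizes)
}

#' @rdname readBedGraph
#' @param track a \code{BinnedTrack}
#' @details \code{writeBedGraph} emits one record per non-zero bin, in
#'   coordinate order, so that read-then-write round-trips reproduce every
#'   non-zero record.
#' @export
writeBedGraph <- function(track, path) {
    B <- binSize(track)
    parts <- lapply(names(trackBins(track)), function(chrom) {
        v <- trackBins(track)[[chrom]]
        nz <- which(v != 0)
        if (!length(nz)) return(NULL)
        GenomicRanges::GRanges(
            chrom,
            IRanges::IRanges((nz - 1L) * B + 1L,
                             pmin(nz * B, seqlengths(track)[[chrom]])),
            score = v[nz])
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    gr <- if (length(parts)) do.call(c, parts) else
        GenomicRanges::GRanges(score = numeric())
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read/write peak intervals (BED)
#'
#' BED3/BED6 via rtracklayer; peaks are returned sorted by (chrom, start).
#'
#' @param path BED file path
#' @return \code{GRanges}, sorted, with any \code{name}/\code{score} columns
#'   preserved
#' @export
readPeaks <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname readPeaks
#' @param peaks \code{GRanges}
#' @export
writePeaks <- function(peaks, path) {
    rtracklayer::export(peaks, path, format = "BED")
    invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chromosome name and length (no header)
#' @return named integer vector
#' @export
readChromSizes <- function(path) {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("chrom", "length"),
                            stringsAsFactors = FALSE)
    stats::setNames(as.integer(df$length), df$chrom)
}

#' Read a two-replicate promoter-capture interaction table
#'
#' Tab-separated with header \code{bait_chrom, bait_start, bait_end, bait_id,
#' oe_chrom, oe_start, oe_end, count_rep1, count_rep2}; coordinates 0-based
#' half-open. The bait-to-other-end distance (midpoint to midpoint; infinite
#' for trans pairs) is computed on read.
#'
#' @param path file path
#' @return data.frame with the input columns plus \code{distance}
#' @export
readInteractions <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("bait_chrom", "bait_start", "bait_end", "bait_id", "oe_chrom",
              "oe_start", "oe_end", "count_rep1", "count_rep2")
    if (!all(need %in% names(df)))
        stop("interaction table must have columns: ",
             paste(need, collapse = ", "))
    if (any(df$count_rep1 < 0 | df$count_rep2 < 0))
        stop("negative interaction counts")
    df$distance <- interactionDistance(df)
    df
}

interactionDistance <- function(df) {
    midB <- (df$bait_start + df$bait_end) / 2
    midO <- (df$oe_start + df$oe_end) / 2
    ifelse(df$bait_chrom == df$oe_chrom, abs(midB - midO), Inf)
}

#' @rdname readInteractions
#' @param interactions data.frame in the interaction-table layout
#' @export
writeInteractions <- function(interactions, path) {
    cols <- c("bait_chrom", "bait_start", "bait_end", "bait_id", "oe_chrom",
              "oe_start", "oe_end", "count_rep1", "count_rep2")
    utils::write.table(interactions[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
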