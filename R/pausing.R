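#' Pol II pausing index per gene
#'
#' The pausing index (PI) of a gene is the ratio of mean per-bp Pol II
#' density in the promoter-proximal window (transcription-oriented offsets
#' -30 to +300 around the TSS) to the mean density over the transcribed
#' region (TSS+300 to the TES). Densities are taken from a zero-clamped
#' track; \code{pausingIndex} clamps defensively. Exclusion rules, applied in
#' this order per gene:
#' \itemize{
#'   \item \code{excluded_width}: gene width < \code{minWidth} (1 kb);
#'   \item \code{excluded_low_promoter}: promoter density <
#'     \code{minPromoterDensity} (1.2) — the gene is not detectably
#'     transcribed with Pol II at the promoter;
#'   \item \code{excluded_zero_body}: body density not positive (PI
#'     undefined);
#'   \item \code{ok}: PI = promoter density / body density.
#' }
#'
#' @param track a \code{\linkS4class{BinnedTrack}} of Pol II signal
#' @param genes named, stranded \code{GRanges}
#' @param promoterOffsets transcription-direction offsets of the
#'   promoter-proximal window around the TSS (default \code{c(-30, 300)})
#' @param minWidth minimum gene width in bp (default 1000)
#' @param minPromoterDensity minimum promoter density (default 1.2)
#' @return data.frame with one row per gene, input order: \code{gene_id},
#'   \code{d_prom}, \code{d_body}, \code{PI} (NA unless status ok),
#'   \code{status}
#' @export
pausingIndex <- function(track, genes, promoterOffsets = c(-30L, 300L),
                         minWidth = 1000L, minPromoterDensity = 1.2) {
    if (length(genes) == 0L)
        return(data.frame(gene_id = character(), d_prom = numeric(),
                          d_body = numeric(), PI = numeric(),
                          status = character()))
    chroms <- unique(as.character(GenomicRanges::seqnames(genes)))
    missing <- setdiff(chroms, names(trackBins(track)))
    if (length(missing))
        stop("genes on chromosomes absent from the track: ",
             paste(missing, collapse = ", "))
    track <- clampNegative(track)
    w <- GenomicRanges::width(genes)
    prom <- strandWindow(genes, promoterOffsets[1], promoterOffsets[2],
                         "TSS", seqlengths = seqlengths(track))
    dProm <- regionSignal(track, prom)
    # body window only defined when the gene extends past the promoter
    # offset; width-excluded genes never reach it
    dBody <- rep(NA_real_, length(genes))
    hasBody <- w > promoterOffsets[2]
    if (any(hasBody)) {
        body <- strandWindow(genes[hasBody], promoterOffsets[2], w[hasBody],
                             "TSS", seqlengths = seqlengths(track))
        dBody[hasBody] <- regionSignal(track, body)
    }
    status <- ifelse(w < minWidth, "excluded_width",
              ifelse(dProm < minPromoterDensity, "excluded_low_promoter",
              ifelse(is.na(dBody) | dBody <= 0, "excluded_zero_body", "ok")))
    pi <- ifelse(status == "ok", dProm / dBody, NA_real_)
    res <- data.frame(gene_id = names(genes), d_prom = dProm,
                      d_body = dBody, PI = pi, status = status,
                      row.names = NULL)
    counts <- table(factor(status, levels = c("ok", "excluded_width",
        "excluded_low_promoter", "excluded_zero_body")))
    message(sprintf(
        "pausingIndex: %d genes; ok %d, excluded (width %d, low promoter %d, zero body %d)",
        nrow(res), counts[["ok"]], counts[["excluded_width"]],
        counts[["excluded_low_promoter"]], counts[["excluded_zero_body"]]))
    res
}

#' Classify genes as paused / not paused by PI threshold
#'
#' Paused means PI strictly above the threshold (default 2); PI at or below
#' the threshold is not paused; genes without a PI (any exclusion) are
#' unclassified.
#'
#' @param piTable output of \code{\link{pausingIndex}}
#' @param threshold PI threshold (default 2)
#' @return character vector in \{paused, not_paused, unclassified\}, aligned
#'   with \code{piTable} rows
#' @export
classifyPaused <- function(piTable, threshold = 2) {
    ifelse(piTable$status != "ok", "unclassified",
           ifelse(piTable$PI > threshold, "paused", "not_paused"))
}

#' Equal-sized rank bins of a numeric key
#'
#' Sorts records by (key, id) ascending and slices them into \code{k}
#' contiguous bins whose sizes differ by at most one (earlier bins take the
#' remainder). Ties are broken by id, so the binning is stable and
#' permutation-invariant.
#'
#' @param key numeric vector
#' @param ids character ids, same length, used as tie-break and names
#' @param k number of bins
#' @param labels optional bin labels (default \code{Q1..Qk}, ascending key)
#' @return factor of bin labels aligned with \code{key}
#' @export
rankBins <- function(key, ids, k, labels = paste0("Q", seq_len(k))) {
    stopifnot(length(key) == length(ids), k >= 1L)
    if (length(key) < k)
        stop("need at least k = ", k, " records to form ", k, " bins")
    n <- length(key)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    ord <- order(key, ids)
    lab <- rep(labels, sizes)
    out <- factor(rep(NA_character_, n), levels = labels)
    out[ord] <- lab
    out
}

#' Five equal-sized PI bins over genes with a defined PI
#'
#' @param piTable output of \code{\link{pausingIndex}}
#' @param k number of bins (default 5)
#' @return factor aligned with \code{piTable} rows; \code{Q1} = lowest PI,
#'   \code{Qk} = highest; NA for excluded genes
#' @export
piQuantileBins <- function(piTable, k = 5L) {
    ok <- piTable$status == "ok"
    if (sum(ok) < k)
        stop("need at least ", k, " genes with a PI; have ", sum(ok))
    out <- factor(rep(NA_character_, nrow(piTable)),
                  levels = paste0("Q", seq_len(k)))
    out[ok] <- rankBins(piTable$PI[ok], piTable$gene_id[ok], k)
    out
}
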