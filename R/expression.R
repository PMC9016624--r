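#' FPKM from raw gene counts
#'
#' FPKM_g = (RC_g x 10^6) / (RC_p x L_g), where RC_g is the count of reads
#' on gene g, RC_p the total count over all provided (protein-coding) genes,
#' and L_g the gene length in bp.
#'
#' @param counts non-negative numeric vector of raw counts
#' @param lengths positive gene lengths in bp, same length
#' @return numeric FPKM vector (names carried over from \code{counts})
#' @export
computeFPKM <- function(counts, lengths) {
    stopifnot(length(counts) == length(lengths))
    counts <- as.numeric(counts)
    lengths <- as.numeric(lengths)
    if (any(counts < 0) || any(lengths <= 0))
        stop("counts must be non-negative and lengths positive")
    total <- sum(counts)
    if (total <= 0)
        stop("zero total counts: FPKM undefined")
    counts * 1e6 / (total * lengths)
}

#' Four equal-sized expression categories
#'
#' Rank-based binning of FPKM into (near-)equal categories ordered
#' silent, low, medium, high; ties broken by gene id.
#'
#' @param fpkm numeric FPKM vector
#' @param ids gene ids (tie-break), same length
#' @param k number of tiers (default 4; with other k the labels are
#'   \code{T1..Tk})
#' @return factor of tier labels aligned with \code{fpkm}
#' @export
expressionTiers <- function(fpkm, ids, k = 4L) {
    labels <- if (k == 4L) c("silent", "low", "medium", "high") else
        paste0("T", seq_len(k))
    rankBins(fpkm, ids, k, labels = labels)
}

#' Threshold filter of a differential-expression table
#'
#' Keeps genes with |fold change| above \code{fcCut} and adjusted p below
#' \code{padjCut}, both strict. Fold changes are linear expression ratios
#' (knockdown over control): down means ratio below \code{1/fcCut}, up means
#' ratio above \code{fcCut}. With \code{log2Scale = TRUE} the fold_change
#' column is read as log2 ratios instead. Genes down upon knockdown are the
#' factor-activated set (AG: the factor promotes their expression); genes up
#' are the factor-repressed set (RG).
#'
#' @param deTable data.frame with columns \code{gene_id},
#'   \code{fold_change}, \code{adjusted_p}
#' @param fcCut fold-change cutoff on the linear ratio scale (default 1.5)
#' @param padjCut adjusted-p cutoff (default 0.1)
#' @param log2Scale interpret \code{fold_change} as log2 ratios
#' @return list with character vectors \code{activated} (down) and
#'   \code{repressed} (up)
#' @export
filterDE <- function(deTable, fcCut = 1.5, padjCut = 0.1,
                     log2Scale = FALSE) {
    need <- c("gene_id", "fold_change", "adjusted_p")
    if (!all(need %in% names(deTable)))
        stop("DE table must have columns: ", paste(need, collapse = ", "))
    if (any(deTable$adjusted_p < 0 | deTable$adjusted_p > 1, na.rm = TRUE))
        stop("adjusted_p must lie in [0, 1]")
    ratio <- if (log2Scale) 2^deTable$fold_change else deTable$fold_change
    if (any(ratio <= 0, na.rm = TRUE))
        stop("linear fold changes must be positive")
    sig <- !is.na(ratio) & !is.na(deTable$adjusted_p) &
        deTable$adjusted_p < padjCut
    list(activated = deTable$gene_id[sig & ratio < 1 / fcCut],
         repressed = deTable$gene_id[sig & ratio > fcCut])
}
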