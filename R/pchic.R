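#' Filter promoter-capture interactions on replicate reads and distance
#'
#' Keeps interactions supported by strictly more than \code{minReads} raw
#' reads in each biological replicate and lying strictly closer than
#' \code{maxDistance} (bait midpoint to other-end midpoint; trans pairs have
#' infinite distance and are removed). Filtering happens on raw counts,
#' before any normalization.
#'
#' @param interactions data.frame from \code{\link{readInteractions}} (or
#'   \code{\link{simulatePCHiC}}); a missing \code{distance} column is
#'   computed
#' @param minReads strict per-replicate read floor (default 5)
#' @param maxDistance strict distance cap in bp (default 1.5e6)
#' @return the retained rows
#' @export
filterInteractions <- function(interactions, minReads = 5,
                               maxDistance = 1.5e6) {
    if (is.null(interactions$distance))
        interactions$distance <- interactionDistance(interactions)
    keep <- interactions$count_rep1 > minReads &
        interactions$count_rep2 > minReads &
        interactions$distance < maxDistance
    interactions[keep, , drop = FALSE]
}

#' Quantile normalization of count columns
#'
#' Each column's sorted values are replaced by the across-column means of
#' the sorted values; ties receive the average of the means at their tied
#' ranks; afterwards every column has the same distribution. Delegates to
#' \code{limma::normalizeBetweenArrays(method = "quantile")}.
#'
#' @param counts numeric matrix or data.frame of columns to normalize
#'   (at least 2 columns of equal length)
#' @return numeric matrix of normalized values, dimnames preserved
#' @export
quantileNormalize <- function(counts) {
    m <- as.matrix(counts)
    if (ncol(m) < 2L)
        stop("need at least 2 columns to quantile normalize")
    if (!is.numeric(m) || anyNA(m))
        stop("counts must be numeric without NAs")
    limma::normalizeBetweenArrays(m, method = "quantile")
}

#' Per-gene interaction summaries
#'
#' Normalizes the two replicate count columns of the (already filtered)
#' interactions jointly, averages replicates per interaction ("intensity"),
#' and aggregates per bait gene: the number of interactions and their mean
#' intensity. Baits listed in \code{baits} but absent from the records get
#' n = 0 and no intensity (NA).
#'
#' @param interactions filtered interaction data.frame
#' @param baits optional character vector of bait ids to report even when
#'   they have no interactions
#' @param normalized optional pre-normalized two-column matrix aligned with
#'   \code{interactions} rows (e.g. from a joint normalization across
#'   conditions); when NULL, the two replicate columns are quantile
#'   normalized here
#' @return data.frame: gene_id, n_interactions, mean_intensity
#' @export
summarizePerGene <- function(interactions, baits = NULL, normalized = NULL) {
    if (nrow(interactions)) {
        if (is.null(normalized))
            normalized <- quantileNormalize(
                interactions[, c("count_rep1", "count_rep2")])
        intensity <- rowMeans(normalized)
        agg <- stats::aggregate(intensity,
                                by = list(gene_id = interactions$bait_id),
                                FUN = mean)
        nn <- as.data.frame(table(interactions$bait_id),
                            stringsAsFactors = FALSE)
        names(nn) <- c("gene_id", "n_interactions")
        out <- merge(nn, agg, by = "gene_id")
        names(out)[3L] <- "mean_intensity"
    } else {
        out <- data.frame(gene_id = character(), n_interactions = integer(),
                          mean_intensity = numeric())
    }
    if (!is.null(baits)) {
        absent <- setdiff(baits, out$gene_id)
        if (length(absent))
            out <- rbind(out, data.frame(gene_id = absent,
                                         n_interactions = 0L,
                                         mean_intensity = NA_real_))
        out <- out[match(baits, out$gene_id), , drop = FALSE]
    } else {
        out <- out[order(out$gene_id), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

wilcoxP <- function(x, y, paired = FALSE) {
    if (paired && all(x == y)) return(1)
    suppressWarnings(stats::wilcox.test(x, y, paired = paired)$p.value)
}

#' Compare per-gene interaction summaries across conditions and groups
#'
#' For each gene group (e.g. activated / repressed / neutral): a paired
#' Wilcoxon test across conditions on baits present in both summaries
#' (identical summaries give p = 1), and unpaired Wilcoxon tests between
#' every pair of groups within each condition. Both are run on the
#' interaction count and on the mean intensity. Groups with fewer than 2
#' genes are refused for the unpaired tests.
#'
#' @param summaryCtrl,summaryKd outputs of \code{\link{summarizePerGene}}
#'   for the two conditions
#' @param groups character vector of group labels named by gene id
#' @return list of data.frames \code{paired} (group, metric, n, p,
#'   median_ctrl, median_kd) and \code{between} (condition, group_a,
#'   group_b, metric, p, median_a, median_b)
#' @export
compareConditions <- function(summaryCtrl, summaryKd, groups) {
    if (is.null(names(groups)))
        stop("'groups' must be named by gene id")
    metrics <- c("n_interactions", "mean_intensity")
    lvls <- unique(groups)
    paired <- list(); between <- list()
    for (g in lvls) {
        ids <- names(groups)[groups == g]
        common <- intersect(intersect(ids, summaryCtrl$gene_id),
                            summaryKd$gene_id)
        if (length(common) == 0L)
            stop("no matched baits for group '", g,
                 "': paired test impossible")
        iC <- match(common, summaryCtrl$gene_id)
        iK <- match(common, summaryKd$gene_id)
        for (m in metrics) {
            x <- summaryCtrl[[m]][iC]; y <- summaryKd[[m]][iK]
            keep <- !is.na(x) & !is.na(y)
            paired[[paste(g, m)]] <- data.frame(
                group = g, metric = m, n = sum(keep),
                p = wilcoxP(x[keep], y[keep], paired = TRUE),
                median_ctrl = stats::median(x[keep]),
                median_kd = stats::median(y[keep]))
        }
    }
    if (length(lvls) > 1L) {
        combos <- utils::combn(lvls, 2L, simplify = FALSE)
        for (cond in c("ctrl", "kd")) {
            su <- if (cond == "ctrl") summaryCtrl else summaryKd
            for (pr in combos) {
                idsA <- names(groups)[groups == pr[1L]]
                idsB <- names(groups)[groups == pr[2L]]
                a <- su[su$gene_id %in% idsA, , drop = FALSE]
                b <- su[su$gene_id %in% idsB, , drop = FALSE]
                if (nrow(a) < 2L || nrow(b) < 2L)
                    stop("group '", pr[if (nrow(a) < 2L) 1L else 2L],
                         "' has fewer than 2 genes in condition ", cond,
                         ": unpaired test refused")
                for (m in metrics) {
                    x <- a[[m]][!is.na(a[[m]])]
                    y <- b[[m]][!is.na(b[[m]])]
                    between[[paste(cond, pr[1L], pr[2L], m)]] <- data.frame(
                        condition = cond, group_a = pr[1L],
                        group_b = pr[2L], metric = m,
                        p = wilcoxP(x, y),
                        median_a = stats::median(x),
                        median_b = stats::median(y))
                }
            }
        }
    }
    list(paired = do.call(rbind, c(paired, list(make.row.names = FALSE))),
         between = if (length(between))
             do.call(rbind, c(between, list(make.row.names = FALSE))) else
             NULL)
}
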