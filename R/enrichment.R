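#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact conditional test with fixed margins: the p-value is the sum of the
#' hypergeometric probabilities of all tables (with the observed margins) no
#' more probable than the observed one (with the conventional 1 + 1e-7
#' relative slack on the comparison). Vectorized over tables.
#'
#' @param a,b,c,d cell counts (a = in both sets, b = first only, c = second
#'   only, d = neither)
#' @return two-sided p-value(s)
#' @export
fisherExactP <- function(a, b, c, d) {
    n <- length(a)
    stopifnot(length(b) == n, length(c) == n, length(d) == n)
    out <- numeric(n)
    for (i in seq_len(n)) {
        r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; c1 <- a[i] + c[i]
        x <- max(0, c1 - r2):min(r1, c1)
        probs <- stats::dhyper(x, r1, r2, c1)
        pObs <- stats::dhyper(a[i], r1, r2, c1)
        out[i] <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
    }
    out
}

#' Fisher exact enrichment of one gene set in another
#'
#' Builds the 2x2 table a = |A and B|, b = |A not B|, c = |B not A|,
#' d = |universe minus (A or B)|, computes the two-sided exact p, the
#' cross-product odds ratio OR = ad/bc and the log2 odds ratio (LOR). When
#' any cell is zero the displayed OR/LOR use the Haldane-Anscombe correction
#' (+0.5 on every cell) and \code{haldane} is set; the p-value stays exact.
#'
#' @param setA,setB character vectors, subsets of \code{universe}
#' @param universe character vector of all items
#' @return one-row data.frame: a, b, c, d, odds_ratio, LOR, p_value,
#'   stars, haldane
#' @export
fisherEnrichment <- function(setA, setB, universe) {
    if (length(universe) == 0L)
        stop("empty universe")
    universe <- unique(universe)
    setA <- unique(setA); setB <- unique(setB)
    if (!all(setA %in% universe) || !all(setB %in% universe))
        stop("sets must be subsets of the universe")
    a <- length(intersect(setA, setB))
    b <- length(setA) - a
    c <- length(setB) - a
    d <- length(universe) - a - b - c
    p <- fisherExactP(a, b, c, d)
    haldane <- any(c(a, b, c, d) == 0L)
    orr <- if (haldane) (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)) else
        a * d / (b * c)
    data.frame(a = a, b = b, c = c, d = d, odds_ratio = orr,
               LOR = log2(orr), p_value = p, stars = pStars(p),
               haldane = haldane)
}

#' Significance stars for p-value bands
#'
#' \code{*} p <= 0.05, \code{**} <= 0.01, \code{***} <= 0.001,
#' \code{****} <= 0.0001 (raw p; no multiplicity layer).
#'
#' @param p numeric p-values
#' @return character vector of stars (empty string when p > 0.05)
#' @export
pStars <- function(p) {
    ifelse(p <= 1e-4, "****", ifelse(p <= 1e-3, "***",
    ifelse(p <= 1e-2, "**", ifelse(p <= 0.05, "*", ""))))
}

#' Log-odds enrichment heatmap over equal-sized bins
#'
#' One Fisher exact test per (gene group, bin): group members against bin
#' members, within the universe of all binned genes. This is the machinery
#' behind LOR heatmaps of gene groups against e.g. PI quintiles or
#' expression quartiles.
#'
#' @param geneGroups named list of character vectors (each a subset of the
#'   binned genes)
#' @param bins factor or character vector of bin labels named by gene id
#'   (every gene in exactly one bin)
#' @return data.frame with one row per (group, bin):
#'   group, bin, a, b, c, d, odds_ratio, LOR, p_value, stars, haldane
#' @export
enrichmentHeatmap <- function(geneGroups, bins) {
    if (is.null(names(bins)))
        stop("'bins' must be named by gene id")
    universe <- names(bins)
    if (anyNA(bins)) {
        universe <- universe[!is.na(bins)]
        bins <- bins[!is.na(bins)]
    }
    binLevels <- if (is.factor(bins)) levels(bins) else
        sort(unique(as.character(bins)))
    rows <- lapply(names(geneGroups), function(g) {
        grp <- intersect(geneGroups[[g]], universe)
        if (length(grp) < length(unique(geneGroups[[g]])))
            warning("group '", g, "' trimmed to the binned universe")
        cells <- lapply(binLevels, function(b) {
            cell <- fisherEnrichment(grp, universe[bins == b], universe)
            cbind(group = g, bin = b, cell)
        })
        do.call(rbind, cells)
    })
    do.call(rbind, rows)
}

#' Overlap percentages of target sets with an annotation set
#'
#' For gene-ontology-style summaries: each target set's overlap with the
#' annotation set, and the combined percentage 100 * (sum of overlaps) /
#' total, reported unrounded and rounded to the nearest integer.
#' \code{targetSets} may be a list of character vectors (overlaps computed
#' against \code{annotationSet}) or a named numeric vector of pre-computed
#' overlap counts.
#'
#' @param targetSets list of character vectors, or numeric overlap counts
#' @param annotationSet character vector (ignored when counts are given)
#' @param total denominator of the combined percentage (e.g. the number of
#'   target genes across sets)
#' @return list: \code{per_set} data.frame (set, overlap, pct_of_total),
#'   \code{combined_pct} (unrounded), \code{combined_pct_rounded}
#' @export
overlapPercentage <- function(targetSets, annotationSet = NULL, total) {
    stopifnot(total > 0)
    if (is.numeric(targetSets)) {
        ov <- targetSets
        setNames <- names(ov)
    } else {
        if (is.null(annotationSet))
            stop("annotationSet required when targetSets are gene sets")
        ov <- vapply(targetSets,
                     function(s) length(intersect(unique(s),
                                                  unique(annotationSet))),
                     numeric(1))
        setNames <- names(targetSets)
    }
    if (is.null(setNames)) setNames <- paste0("set", seq_along(ov))
    combined <- 100 * sum(ov) / total
    list(per_set = data.frame(set = setNames, overlap = as.numeric(ov),
                              pct_of_total = 100 * as.numeric(ov) / total),
         combined_pct = combined,
         combined_pct_rounded = round(combined))
}
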