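interTable <- function(c1, c2, dist, bait = sprintf("b%02d",
                                                    seq_along(c1))) {
    data.frame(bait_chrom = "chr1", bait_start = 1000, bait_end = 6000,
               bait_id = bait, oe_chrom = "chr1",
               oe_start = 1000 + dist, oe_end = 6000 + dist,
               count_rep1 = c1, count_rep2 = c2)
}

test_that("interaction filtering is strict on reads and distance", {
    tab <- interTable(c(6, 5, 20, 6), c(7, 8, 30, 9),
                      c(1e6, 1e5, 2e6, 1.5e6))
    kept <- filterInteractions(tab)
    expect_equal(kept$bait_id, "b01")
    # counts (5, 8): removed by the strict > 5 rule
    # distance 2 Mb and exactly 1.5 Mb: removed by the strict < 1.5 Mb rule
})

test_that("raising the read floor never adds interactions", {
    set.seed(51)
    tab <- interTable(rpois(300, 8), rpois(300, 8),
                      sample(1e4:2e6, 300))
    prev <- nrow(filterInteractions(tab, minReads = 0))
    for (m in c(2, 5, 8, 12)) {
        cur <- nrow(filterInteractions(tab, minReads = m))
        expect_lte(cur, prev)
        prev <- cur
    }
})

test_that("quantile normalization equalizes column distributions", {
    got <- quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
    expect_equal(unname(got[, "a"]), c(2.5, 3.5, 4.5))
    expect_equal(unname(got[, "b"]), c(2.5, 3.5, 4.5))
    # identical columns are a fixed point
    m <- cbind(c(3, 1, 7), c(3, 1, 7))
    expect_equal(unname(quantileNormalize(m)), unname(m))
    # tie-free random columns: sorted columns exactly equal afterwards
    set.seed(52)
    r <- cbind(rnorm(100, 20, 4), rnorm(100, 30, 9))
    qn <- quantileNormalize(r)
    expect_identical(sort(qn[, 1]), sort(qn[, 2]))
    expect_error(quantileNormalize(r[, 1, drop = FALSE]), "2 columns")
})

test_that("tied counts receive the average of the tied-rank means", {
    # reference rank-average oracle, written independently of limma
    oracle <- function(m) {
        ref <- rowMeans(apply(m, 2, sort))
        apply(m, 2, function(col) {
            r <- rank(col, ties.method = "average")
            lo <- floor(r); hi <- ceiling(r)
            (ref[lo] + ref[hi]) / 2
        })
    }
    set.seed(53)
    m <- cbind(sample(1:8, 30, TRUE), sample(1:8, 30, TRUE),
               sample(1:8, 30, TRUE))
    expect_equal(unname(quantileNormalize(m)), unname(oracle(m)),
                 tolerance = 1e-12)
})

test_that("per-gene summaries aggregate intensities per bait", {
    tab <- interTable(c(10, 20, 30, 40), c(12, 18, 32, 38), rep(1e5, 4),
                      bait = c("gA", "gA", "gA", "gB"))
    norm <- cbind(tab$count_rep1, tab$count_rep2)  # pretend pre-normalized
    s <- summarizePerGene(tab, baits = c("gA", "gB", "gC"),
                          normalized = norm)
    expect_equal(s$gene_id, c("gA", "gB", "gC"))
    expect_equal(s$n_interactions, c(3L, 1L, 0L))
    expect_equal(s$mean_intensity[1], mean(c(11, 19, 31)))
    expect_equal(s$mean_intensity[2], 39)
    expect_true(is.na(s$mean_intensity[3]))
    # group-by oracle on random data
    set.seed(54)
    big <- interTable(rpois(200, 20), rpois(200, 20), rep(1e5, 200),
                      bait = sample(sprintf("g%02d", 1:30), 200, TRUE))
    sb <- summarizePerGene(big)
    intensity <- rowMeans(quantileNormalize(
        big[, c("count_rep1", "count_rep2")]))
    want <- tapply(intensity, big$bait_id, mean)
    expect_equal(sb$mean_intensity, as.numeric(want[sb$gene_id]))
    expect_equal(sb$n_interactions,
                 unname(table(big$bait_id)[sb$gene_id]), ignore_attr = TRUE)
})

test_that("condition comparisons handle identical, shifted and tiny groups", {
    s <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    n_interactions = rep(c(4L, 8L), 20),
                    mean_intensity = rep(c(20, 10), 20))
    groups <- stats::setNames(rep(c("RG", "AG"), 20), s$gene_id)
    same <- compareConditions(s, s, groups)
    expect_true(all(same$paired$p == 1))
    expect_equal(same$paired$median_ctrl, same$paired$median_kd)
    # AG has double the interactions, half the intensity
    btw <- same$between
    nAG <- btw[btw$metric == "n_interactions" & btw$condition == "ctrl", ]
    expect_lt(nAG$p, 0.01)
    # a single-gene group is refused for the unpaired test
    tiny <- stats::setNames(c(rep("big", 39), "solo"), s$gene_id)
    expect_error(compareConditions(s, s, tiny), "fewer than 2")
})

test_that("designed AG/RG contact contrast is recovered significantly", {
    cfg <- simConfig(nGenes = 400L, chromLength = 1.2e7, seed = 2L,
                     fractionAG = 0.5, fractionRG = 0.5)
    g <- simulateGenome(cfg)
    pc <- filterInteractions(simulatePCHiC(g, cfg))
    s <- summarizePerGene(pc, baits = g$truth$gene_id)
    cmp <- compareConditions(s, s, stats::setNames(g$truth$class,
                                                   g$truth$gene_id))
    btw <- cmp$between[cmp$between$condition == "ctrl", ]
    nRow <- btw[btw$metric == "n_interactions", ]
    iRow <- btw[btw$metric == "mean_intensity", ]
    agFirst <- nRow$group_a == "AG"
    expect_lt(nRow$p, 0.01)
    expect_lt(iRow$p, 0.01)
    expect_true(if (agFirst) nRow$median_a > nRow$median_b else
                nRow$median_b > nRow$median_a)
    expect_true(if (agFirst) iRow$median_a < iRow$median_b else
                iRow$median_b < iRow$median_a)
})
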