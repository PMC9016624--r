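smallCfg <- function(...) simConfig(nGenes = 30L, chromLength = 1.5e6, ...)

test_that("simulateGenome is deterministic and honours the config", {
    cfg <- smallCfg(seed = 4L)
    g1 <- simulateGenome(cfg)
    g2 <- simulateGenome(cfg)
    expect_identical(g1$truth, g2$truth)
    expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
    expect_equal(length(g1$genes), 30L)
    expect_equal(nrow(g1$truth), 30L)
    expect_true(all(GenomicRanges::width(g1$genes) >= 2000))
    # non-overlapping, alternating strands
    expect_true(all(GenomicRanges::start(g1$genes)[-1] >
                    GenomicRanges::end(g1$genes)[-30]))
    expect_equal(as.character(GenomicRanges::strand(g1$genes)),
                 rep_len(c("+", "-"), 30))

    none <- simulateGenome(smallCfg(seed = 4L, fractionPaused = 0))
    expect_false(any(none$truth$paused))
    expect_error(simulateGenome(simConfig(nGenes = 500L,
                                          chromLength = 1e6)), "fit")
})

test_that("different seeds give different genomes", {
    a <- simulateGenome(smallCfg(seed = 1L))
    b <- simulateGenome(smallCfg(seed = 2L))
    expect_false(identical(GenomicRanges::start(a$genes),
                           GenomicRanges::start(b$genes)))
})

test_that("noise-free Pol II tracks encode the configured pause ratio", {
    cfg <- smallCfg(seed = 2L, noiseSD = 0, pauseRatioPaused = 5)
    g <- simulateGenome(cfg)
    tr <- simulateTrack(g, cfg, "PolII")
    B <- cfg@binSize
    tss <- tssPositions(g$genes)
    str <- as.character(GenomicRanges::strand(g$genes))
    for (i in which(g$truth$paused)[1:5]) {
        # bin-aligned extents of the painted promoter and body regions
        pw <- if (str[i] == "+") c(tss[i] - 30, tss[i] + 299) else
            c(tss[i] - 299, tss[i] + 30)
        pa <- ((pw[1] - 1) %/% B) * B + 1
        pb <- ((pw[2] - 1) %/% B + 1) * B
        gs <- GenomicRanges::start(g$genes)[i]
        ge <- GenomicRanges::end(g$genes)[i]
        body <- if (str[i] == "+") c(pb + 1, ((ge - 1) %/% B) * B) else
            c(((gs - 1) %/% B + 1) * B + 1, pa - 1)
        dp <- regionSignal(tr, GenomicRanges::GRanges("chrS",
            IRanges::IRanges(pa, pb)))
        db <- regionSignal(tr, GenomicRanges::GRanges("chrS",
            IRanges::IRanges(body[1], body[2])))
        expect_equal(dp / db, 5, tolerance = 1e-6)
    }
    # neutral elongating gene: flat coverage across the whole gene
    i <- which(!g$truth$paused)[1]
    vals <- trackBins(tr)$chrS[
        ((GenomicRanges::start(g$genes)[i] - 1) %/% B + 2):
        ((GenomicRanges::end(g$genes)[i] - 1) %/% B)]
    expect_true(all(abs(vals - cfg@bodyMean) < 1e-9))
})

test_that("track generation is seed-deterministic and kind-checked", {
    cfg <- smallCfg(seed = 6L)
    g <- simulateGenome(cfg)
    expect_identical(trackBins(simulateTrack(g, cfg, "PolII")),
                     trackBins(simulateTrack(g, cfg, "PolII")))
    expect_error(simulateTrack(g, cfg, "H3K4me1"))
})

test_that("heterochromatin marks are anti-correlated, H3K27ac marks enhancers", {
    cfg <- smallCfg(seed = 3L, noiseSD = 0)
    g <- simulateGenome(cfg)
    k27 <- trackBins(simulateTrack(g, cfg, "H3K27me3"))$chrS
    k9 <- trackBins(simulateTrack(g, cfg, "H3K9me3"))$chrS
    expect_true(cor(k27, k9) < -0.9)
    expect_setequal(unique(k27 + k9), cfg@markHigh + cfg@markLow)
    ac <- simulateTrack(g, cfg, "H3K27ac")
    expect_true(all(regionSignal(ac, g$enhancers) > 0))
})

test_that("empirical promoter/body ratios track the configured means", {
    cfg <- simConfig(nGenes = 1000L, chromLength = 3e7, seed = 1L)
    g <- simulateGenome(cfg)
    tr <- clampNegative(simulateTrack(g, cfg, "PolII"))
    pt <- suppressMessages(pausingIndex(tr, g$genes))
    ratios <- tapply(pt$PI, g$truth$paused, mean, na.rm = TRUE)
    expect_lt(abs(ratios[["TRUE"]] - cfg@pauseRatioPaused) /
              cfg@pauseRatioPaused, 0.05)
    expect_lt(abs(ratios[["FALSE"]] - cfg@pauseRatioElongating) /
              cfg@pauseRatioElongating, 0.05)
})

test_that("expression counts follow the configured tiers", {
    cfg <- simConfig(nGenes = 1000L, chromLength = 3e7, seed = 1L)
    g <- simulateGenome(cfg)
    ex <- simulateExpression(g, cfg)
    expect_identical(ex, simulateExpression(g, cfg))
    perKb <- ex$count / (ex$length / 1000)
    emp <- tapply(perKb, g$truth$tier, mean)
    expect_equal(unname(emp["silent"]), 0)
    for (tier in c("low", "medium", "high")) {
        want <- cfg@tierMeans[match(tier, c("silent", "low", "medium",
                                            "high"))]
        expect_lt(abs(emp[[tier]] - want) / want, 0.1)
    }
    # dispersion -> 0: silent genes have exactly zero counts
    pois <- simulateExpression(g, smallCfg(seed = 1L, nbDispersion = 0))
    expect_true(all(pois$count[g$truth$tier == "silent"][1:5] == 0))
})

test_that("simulated contacts encode more-but-weaker interactions for AGs", {
    cfg <- simConfig(nGenes = 1000L, chromLength = 3e7, seed = 1L,
                     fractionAG = 0.5, fractionRG = 0.5)
    g <- simulateGenome(cfg)
    pc <- simulatePCHiC(g, cfg)
    expect_identical(pc, simulatePCHiC(g, cfg))
    cls <- g$truth$class[match(pc$bait_id, g$truth$gene_id)]
    nPer <- table(factor(pc$bait_id, levels = g$truth$gene_id))
    meanN <- tapply(as.numeric(nPer), g$truth$class, mean)
    expect_lt(abs(meanN[["AG"]] / meanN[["RG"]] - cfg@agCountFactor) /
              cfg@agCountFactor, 0.1)
    expect_lt(mean(pc$true_intensity[cls == "AG"]),
              mean(pc$true_intensity[cls == "RG"]))
    # distances extend beyond the 1.5 Mb analysis cap
    d <- abs((pc$oe_start + pc$oe_end) / 2 - (pc$bait_start + pc$bait_end) / 2)
    expect_gt(max(d), 1.5e6)

    none <- simulatePCHiC(g, smallCfg(seed = 1L, contactMeanN = 0))
    expect_equal(nrow(none), 0L)
})

test_that("generated files parse back through the package readers cleanly", {
    cfg <- smallCfg(seed = 8L)
    g <- simulateGenome(cfg)
    dir <- withr::local_tempdir()
    expect_no_warning({
        writeGeneTable(g$genes, file.path(dir, "genes.tsv"))
        genes <- readGeneTable(file.path(dir, "genes.tsv"))
        writeBedGraph(simulateTrack(g, cfg, "PolII"),
                      file.path(dir, "polII.bedGraph"))
        tr <- readBedGraph(file.path(dir, "polII.bedGraph"), cfg@binSize,
                           stats::setNames(cfg@chromLength, "chrS"))
        writeInteractions(simulatePCHiC(g, cfg),
                          file.path(dir, "pchic.tsv"))
        pc <- readInteractions(file.path(dir, "pchic.tsv"))
    })
    expect_equal(names(genes), g$truth$gene_id)
    expect_gt(nrow(pc), 0L)
})
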