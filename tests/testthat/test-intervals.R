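test_that("strandWindow places the promoter-proximal window by strand", {
    # 0-based TSS 1000 corresponds to 1-based position 1001
    plus <- makeGenes(1001, 6000, "+")
    w <- strandWindow(plus, -30, 300, "TSS")
    expect_equal(GenomicRanges::start(w), 971)   # 0-based [970, 1300)
    expect_equal(GenomicRanges::end(w), 1300)

    minus <- makeGenes(101, 1001, "-")           # 0-based TSS = 1000
    w <- strandWindow(minus, -30, 300, "TSS")
    expect_equal(GenomicRanges::start(w), 702)   # 0-based [701, 1031)
    expect_equal(GenomicRanges::end(w), 1031)

    expect_error(strandWindow(plus, 0, 0, "TSS"), "empty window")
    expect_error(strandWindow(plus, 300, 100, "TSS"), "empty window")
})

test_that("minus-strand windows are mirror images of plus-strand windows", {
    L <- 100000L
    set.seed(5)
    for (i in 1:25) {
        s <- sample(20000:60000, 1); e <- s + sample(2000:9000, 1)
        o5 <- sample(-500:100, 1); o3 <- o5 + sample(50:1000, 1)
        anchor <- sample(c("TSS", "TES"), 1)
        plus <- makeGenes(s, e, "+")
        mirrored <- makeGenes(L - e + 1, L - s + 1, "-")
        wP <- strandWindow(plus, o5, o3, anchor)
        wM <- strandWindow(mirrored, o5, o3, anchor)
        expect_equal(GenomicRanges::start(wM),
                     L - GenomicRanges::end(wP) + 1)
        expect_equal(GenomicRanges::end(wM),
                     L - GenomicRanges::start(wP) + 1)
    }
})

test_that("strandWindow clips to chromosome bounds and flags it", {
    g <- makeGenes(10, 2000, "+")
    w <- strandWindow(g, -30, 300, "TSS", seqlengths = c(chr1 = 5000))
    expect_equal(GenomicRanges::start(w), 1)
    expect_true(S4Vectors::mcols(w)$clipped)
    w2 <- strandWindow(g, 300, 1991, "TSS", seqlengths = c(chr1 = 1000))
    expect_equal(GenomicRanges::end(w2), 1000)
    expect_true(S4Vectors::mcols(w2)$clipped)
})

test_that("overlapPairs obeys half-open boundary semantics", {
    a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
    expect_equal(nrow(overlapPairs(a, b)), 1L)
    # 0-based [0,100) vs [100,200): adjacent, no overlap
    b2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
    expect_equal(nrow(overlapPairs(a, b2)), 0L)
})

test_that("overlapPairs equals the quadratic all-pairs oracle", {
    set.seed(9)
    rand <- function(n) {
        s <- sample(1:5000, n, replace = TRUE)
        GenomicRanges::sort(GenomicRanges::GRanges("chr1",
            IRanges::IRanges(s, s + sample(1:400, n, replace = TRUE))))
    }
    a <- rand(200); b <- rand(200)
    for (minov in c(1L, 50L)) {
        got <- overlapPairs(a, b, minov)
        got <- got[order(got$queryIndex, got$subjectIndex), ]
        pairs <- expand.grid(i = seq_along(a), j = seq_along(b))
        ov <- pmin(GenomicRanges::end(a)[pairs$i],
                   GenomicRanges::end(b)[pairs$j]) -
              pmax(GenomicRanges::start(a)[pairs$i],
                   GenomicRanges::start(b)[pairs$j]) + 1
        want <- pairs[ov >= minov, ]
        want <- want[order(want$i, want$j), ]
        expect_equal(got$queryIndex, want$i)
        expect_equal(got$subjectIndex, want$j)
    }
})

test_that("peak annotation applies promoter > gene_body > distal precedence", {
    genes <- makeGenes(c(10001, 50001), c(20000, 60000), c("+", "-"))
    peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(9900, 15000, 300000, 59500), c(10100, 15200, 300200, 60500)))
    ann <- annotatePeaks(peaks, genes, promoterFlank = 1000L)
    cat <- as.character(S4Vectors::mcols(ann)$category)
    # peak 1 centred on the + TSS; peak 2 mid-body; peak 3 far away;
    # peak 4 overlaps gene 1's body region? no - it spans the - gene TSS
    expect_equal(cat, c("promoter", "gene_body", "distal_intergenic",
                        "promoter"))
    props <- S4Vectors::metadata(ann)$proportions
    expect_equal(unname(props), c(0.5, 0.25, 0.25))
})

test_that("peak annotation equals full category enumeration on random data", {
    set.seed(21)
    genes <- makeGenes(seq(5000, 95000, by = 10000),
                       seq(5000, 95000, by = 10000) + 4000,
                       rep_len(c("+", "-"), 10))
    s <- sample(1:110000, 150)
    peaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(s, s + sample(100:2000, 150, replace = TRUE)))
    ann <- as.character(S4Vectors::mcols(
        annotatePeaks(peaks, genes))$category)
    tss <- tssPositions(genes)
    for (i in seq_along(peaks)) {
        ps <- GenomicRanges::start(peaks)[i]
        pe <- GenomicRanges::end(peaks)[i]
        inProm <- any(pe >= tss - 1000 & ps <= tss + 1000)
        inBody <- any(pe >= GenomicRanges::start(genes) &
                      ps <= GenomicRanges::end(genes))
        want <- if (inProm) "promoter" else if (inBody) "gene_body" else
            "distal_intergenic"
        expect_equal(ann[i], want)
    }
})
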