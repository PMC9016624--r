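test_that("domain scoring discriminates heterochromatin flavours", {
    k27 <- makeTrack(rep(5, 20)); k9 <- makeTrack(rep(2, 20))
    dom <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
    sc <- scoreDomains(k27, k9, dom)
    expect_equal(sc$D, 3)
    expect_equal(sc$class, "facultative_like")
    sc2 <- scoreDomains(makeTrack(rep(1, 20)), makeTrack(rep(4, 20)), dom)
    expect_equal(sc2$D, -3)
    expect_equal(sc2$class, "constitutive_like")
    # D = 0 boundary is constitutive-like
    eq <- scoreDomains(k27, k27, dom)
    expect_equal(eq$class, "constitutive_like")
    expect_equal(nrow(scoreDomains(k27, k9, dom[0])), 0L)
})

test_that("domain scoring is antisymmetric under track swap", {
    set.seed(19)
    a <- makeTrack(rnorm(50, 2)); b <- makeTrack(rnorm(50, 2))
    doms <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, 2001, by = 500), width = 400))
    expect_equal(scoreDomains(a, b, doms)$D, -scoreDomains(b, a, doms)$D)
})

test_that("enhancer seeds exclude TSS-proximal peaks", {
    genes <- makeGenes(10001, 20000, "+")
    peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(9500, 30000, 12050), width = 200))
    seeds <- callEnhancerSeeds(peaks, genes, tssExclusion = 2000L)
    expect_equal(GenomicRanges::start(seeds), c(12050, 30000))
    # peak 10 kb away from every TSS is kept
    expect_true(30000 %in% GenomicRanges::start(seeds))
    # no genes: everything kept, sorted
    all <- callEnhancerSeeds(peaks, genes[0])
    expect_equal(length(all), 3L)
    expect_equal(GenomicRanges::start(all), sort(GenomicRanges::start(peaks)))
})

withSignal <- function(start, width, signal) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start,
                                                          width = width))
    S4Vectors::mcols(gr)$signal <- signal
    gr
}

test_that("stitching merges at the distance boundary and sums signal", {
    # 0-based seeds [0,500) and [10000,10500): gap 9.5 kb <= 12.5 kb
    seeds <- withSignal(c(1, 10001), 500, c(2, 3))
    st <- stitchEnhancers(seeds)
    expect_equal(length(st), 1L)
    expect_equal(S4Vectors::mcols(st)$n_constituents, 2L)
    expect_equal(S4Vectors::mcols(st)$signal, 5)

    # gap of exactly 12,500 bp merges; one more base does not
    atBoundary <- withSignal(c(1, 13001), 500, c(1, 1))
    expect_equal(length(stitchEnhancers(atBoundary)), 1L)
    beyond <- withSignal(c(1, 13002), 500, c(1, 1))
    expect_equal(length(stitchEnhancers(beyond)), 2L)
})

test_that("stitching is idempotent, order-invariant and base-preserving", {
    set.seed(23)
    for (rep in 1:10) {
        s <- sample(1:200000, 40)
        seeds <- withSignal(s, sample(200:900, 40, replace = TRUE),
                            runif(40, 1, 10))
        st <- stitchEnhancers(seeds)
        # pairwise separation beyond the stitch distance
        if (length(st) > 1L)
            expect_true(all(GenomicRanges::start(st)[-1] -
                            GenomicRanges::end(st)[-length(st)] - 1 > 12500))
        st2 <- stitchEnhancers(st)
        expect_equal(as.data.frame(st2)[, 1:3], as.data.frame(st)[, 1:3])
        expect_equal(S4Vectors::mcols(st2)$signal,
                     S4Vectors::mcols(st)$signal)
        shuffled <- seeds[sample(length(seeds))]
        stS <- stitchEnhancers(shuffled)
        expect_equal(as.data.frame(stS)[, 1:3], as.data.frame(st)[, 1:3])
        expect_equal(sum(S4Vectors::mcols(stS)$signal),
                     sum(S4Vectors::mcols(seeds)$signal), tolerance = 1e-9)
        # union of constituent bases preserved
        expect_equal(sum(GenomicRanges::width(GenomicRanges::intersect(
            GenomicRanges::reduce(seeds, ignore.strand = TRUE), st))),
            sum(GenomicRanges::width(GenomicRanges::reduce(
                seeds, ignore.strand = TRUE))))
    }
})

test_that("super-enhancer cutoff flags the rank-curve elbow", {
    st <- withSignal(seq(1, by = 20000, length.out = 5), 500,
                     c(1, 1, 1, 1, 100))
    se <- callSuperEnhancers(stitchEnhancers(st))
    expect_equal(S4Vectors::mcols(se)$is_super,
                 S4Vectors::mcols(se)$signal == 100)
    expect_equal(S4Vectors::mcols(se)$rank[
        S4Vectors::mcols(se)$signal == 100], 1L)

    flat <- withSignal(seq(1, by = 20000, length.out = 6), 500, rep(4, 6))
    expect_false(any(S4Vectors::mcols(
        callSuperEnhancers(stitchEnhancers(flat)))$is_super))

    expect_error(callSuperEnhancers(stitchEnhancers(
        withSignal(c(1, 20001), 500, c(1, 2)))), "at least 3")
})

test_that("super-enhancer flags match the tangent-scan oracle", {
    set.seed(77)
    for (rep in 1:50) {
        n <- sample(5:60, 1)
        signal <- rlnorm(n, meanlog = sample(0:3, 1), sdlog = runif(1, .3, 2))
        st <- withSignal(seq(1, by = 20000, length.out = n), 500, signal)
        se <- callSuperEnhancers(stitchEnhancers(st))
        expect_equal(S4Vectors::mcols(se)$is_super, oracleSuperFlags(signal))
    }
})

test_that("super-enhancer flags are invariant to rescaling all signals", {
    set.seed(78)
    for (rep in 1:10) {
        signal <- rlnorm(30, 1, 1)
        st <- withSignal(seq(1, by = 20000, length.out = 30), 500, signal)
        ref <- S4Vectors::mcols(callSuperEnhancers(
            stitchEnhancers(st)))$is_super
        scaled <- withSignal(seq(1, by = 20000, length.out = 30), 500,
                             signal * runif(1, 0.1, 50))
        expect_equal(S4Vectors::mcols(callSuperEnhancers(
            stitchEnhancers(scaled)))$is_super, ref)
    }
})
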