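#' Validate and normalize a pipeline configuration
#'
#' Fills in defaults (the analysis' canonical parameter values: PI threshold
#' 2; |FC| > 1.5 and adjusted p < 0.1; 12.5 kb stitching; TSS exclusion 2 kb
#' for enhancers and 2.5 kb in the super-enhancer preset; 5 PI bins and 4
#' expression tiers; PCHiC reads > 5 per replicate within 1.5 Mb; 2-s.d.
#' metagene outlier removal), rejects out-of-range values, and warns when a
#' supplied value deviates from the default.
#'
#' @param config named list of overrides; entries under \code{sim} are
#'   passed to \code{\link{simConfig}}
#' @return normalized configuration list with a \code{sim} element holding
#'   the \code{SimConfig}
#' @export
validateConfig <- function(config = list()) {
    defaults <- list(
        seed = 1L, n_genes = 200L,
        pi_threshold = 2, fc_cut = 1.5, padj_cut = 0.1,
        stitch_distance = 12500, tss_exclusion = 2000,
        se_tss_exclusion = 2500, pi_bins = 5L, expression_tiers = 4L,
        min_reads = 5, max_distance = 1.5e6, outlier_sd = 2,
        promoter_flank = 1000, metagene_flank = 2000,
        genes_file = NULL, kd_intensity_factor = 0.8)
    unknown <- setdiff(names(config), c(names(defaults), "sim"))
    if (length(unknown))
        stop("unknown configuration entries: ",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config[names(config) != "sim"])
    positive <- c("pi_threshold", "stitch_distance", "tss_exclusion",
                  "se_tss_exclusion", "min_reads", "max_distance",
                  "outlier_sd", "promoter_flank", "metagene_flank",
                  "n_genes")
    for (f in positive)
        if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
            stop("'", f, "' must be positive")
    if (cfg$fc_cut <= 1) stop("'fc_cut' must exceed 1")
    if (cfg$padj_cut <= 0 || cfg$padj_cut > 1)
        stop("'padj_cut' must lie in (0, 1]")
    if (cfg$pi_bins < 2L || cfg$expression_tiers < 2L)
        stop("'pi_bins' and 'expression_tiers' must be at least 2")
    for (f in setdiff(names(defaults),
                      c("seed", "n_genes", "genes_file",
                        "kd_intensity_factor")))
        if (f %in% names(config) &&
            !isTRUE(all.equal(config[[f]], defaults[[f]])))
            warning("'", f, "' = ", config[[f]],
                    " deviates from the default ", defaults[[f]],
                    call. = FALSE)
    simArgs <- config$sim
    if (is.null(simArgs)) simArgs <- list()
    simArgs$seed <- cfg$seed
    simArgs$nGenes <- cfg$n_genes
    cfg$sim <- do.call(simConfig, simArgs)
    cfg
}

stageLog <- function(log, stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    message(line)
    if (!is.null(log)) cat(line, "\n", file = log, append = TRUE, sep = "")
    invisible(NULL)
}

runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, pausing-index, expression, enhancer, enrichment,
#' metagene and PCHiC stages in dependency order, writing every output as a
#' plain-text file under \code{outDir} and a manifest of file MD5 checksums.
#' Analysis stages re-read the files the simulate stage wrote, so the run is
#' exactly reproducible from its own outputs; re-running with the same
#' configuration reproduces identical checksums. Any stage error aborts with
#' the stage name.
#'
#' @param config a configuration list (passed through
#'   \code{\link{validateConfig}} unless already normalized)
#' @param outDir output directory (created if needed)
#' @return invisibly, the manifest data.frame (file, md5)
#' @export
runPipeline <- function(config = list(), outDir) {
    if (!methods::is(config$sim, "SimConfig"))
        config <- validateConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    path <- function(f) file.path(outDir, f)
    log <- path("run.log")
    cat("", file = log)
    outputs <- character()
    emit <- function(f) outputs <<- c(outputs, f)
    simCfg <- config$sim

    ## -- simulate -----------------------------------------------------
    genome <- NULL
    runStage("simulate", {
        if (is.null(config$genes_file)) {
            genome <- simulateGenome(simCfg)
            writeGeneTable(genome$genes, path("genes.tsv")); emit("genes.tsv")
            utils::write.table(genome$truth, path("truth.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            emit("truth.tsv")
            writePeaks(genome$enhancers, path("h3k27ac_peaks.bed"))
            emit("h3k27ac_peaks.bed")
            for (kind in c("PolII", "mH2A1.1", "H3K27ac", "H3K27me3",
                           "H3K9me3")) {
                f <- paste0(gsub("[^A-Za-z0-9]", "", kind), ".bedGraph")
                writeBedGraph(simulateTrack(genome, simCfg, kind), path(f))
                emit(f)
            }
            expr <- simulateExpression(genome, simCfg)
            utils::write.table(expr, path("expression.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            emit("expression.tsv")
            de <- simulateDETable(genome, simCfg)
            utils::write.table(de, path("de_table.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            emit("de_table.tsv")
            ctrl <- simulatePCHiC(genome, simCfg)
            kd <- simulatePCHiC(genome, simCfg,
                                intensityFactor = config$kd_intensity_factor,
                                streamOffset = 7L)
            writeInteractions(ctrl, path("pchic_ctrl.tsv"))
            writeInteractions(kd, path("pchic_kd.tsv"))
            emit("pchic_ctrl.tsv"); emit("pchic_kd.tsv")
            chromSizes <- data.frame(chrom = simChrom,
                                     length = simCfg@chromLength)
            utils::write.table(chromSizes, path("chrom.sizes"), sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               col.names = FALSE)
            emit("chrom.sizes")
            stageLog(log, "simulate",
                     "%d genes, 5 tracks, %d+%d interactions, seed %d",
                     simCfg@nGenes, nrow(ctrl), nrow(kd), simCfg@seed)
        } else {
            file.copy(config$genes_file, path("genes.tsv"), overwrite = TRUE)
            emit("genes.tsv")
            stageLog(log, "simulate", "using supplied gene table %s",
                     config$genes_file)
        }
    })

    ## -- pausing index ------------------------------------------------
    piTab <- NULL
    runStage("pi", {
        genes <- readGeneTable(path("genes.tsv"))
        chromSizes <- readChromSizes(path("chrom.sizes"))
        polII <- readBedGraph(path("PolII.bedGraph"), simCfg@binSize,
                              chromSizes)
        piTab <- suppressMessages(pausingIndex(polII, genes))
        piTab$class <- classifyPaused(piTab, config$pi_threshold)
        piTab$pi_bin <- as.character(piQuantileBins(piTab, config$pi_bins))
        utils::write.table(piTab, path("pi_table.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("pi_table.tsv")
        stageLog(log, "pi", "%d genes, %d paused, %d not paused",
                 nrow(piTab), sum(piTab$class == "paused"),
                 sum(piTab$class == "not_paused"))
    })

    ## -- expression ---------------------------------------------------
    deSets <- NULL
    runStage("expr", {
        expr <- utils::read.delim(path("expression.tsv"))
        expr$fpkm <- computeFPKM(expr$count, expr$length)
        expr$tier <- as.character(expressionTiers(expr$fpkm, expr$gene_id,
                                                  config$expression_tiers))
        utils::write.table(expr, path("fpkm.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("fpkm.tsv")
        de <- utils::read.delim(path("de_table.tsv"))
        deSets <- filterDE(de, config$fc_cut, config$padj_cut)
        reg <- data.frame(
            gene_id = c(deSets$activated, deSets$repressed),
            set = c(rep("activated", length(deSets$activated)),
                    rep("repressed", length(deSets$repressed))))
        utils::write.table(reg, path("deregulated.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("deregulated.tsv")
        stageLog(log, "expr", "%d activated, %d repressed (|FC|>%g, padj<%g)",
                 length(deSets$activated), length(deSets$repressed),
                 config$fc_cut, config$padj_cut)
    })

    ## -- enhancers ----------------------------------------------------
    runStage("enhancers", {
        genes <- readGeneTable(path("genes.tsv"))
        chromSizes <- readChromSizes(path("chrom.sizes"))
        peaks <- readPeaks(path("h3k27ac_peaks.bed"))
        track <- readBedGraph(path("H3K27ac.bedGraph"), simCfg@binSize,
                              chromSizes)
        se <- superEnhancerPipeline(peaks, genes, track,
                                    config$se_tss_exclusion,
                                    config$stitch_distance)
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(se)),
                         start = GenomicRanges::start(se) - 1L,
                         end = GenomicRanges::end(se),
                         n_constituents =
                             S4Vectors::mcols(se)$n_constituents,
                         signal = S4Vectors::mcols(se)$signal,
                         rank = S4Vectors::mcols(se)$rank,
                         is_super = S4Vectors::mcols(se)$is_super)
        utils::write.table(df, path("stitched_enhancers.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("stitched_enhancers.tsv")
        stageLog(log, "enhancers", "%d stitched, %d super", nrow(df),
                 sum(df$is_super))
    })

    ## -- enrichment ---------------------------------------------------
    runStage("enrich", {
        piTab <- utils::read.delim(path("pi_table.tsv"))
        ok <- piTab$pi_bin != "" & !is.na(piTab$pi_bin)
        bins <- stats::setNames(piTab$pi_bin[ok], piTab$gene_id[ok])
        groups <- list(activated = intersect(deSets$activated, names(bins)),
                       repressed = intersect(deSets$repressed, names(bins)))
        hm <- enrichmentHeatmap(groups, bins)
        utils::write.table(hm, path("enrichment_heatmap.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("enrichment_heatmap.tsv")
        stageLog(log, "enrich", "%d cells over %d bins", nrow(hm),
                 length(unique(hm$bin)))
    })

    ## -- metagene -----------------------------------------------------
    runStage("metagene", {
        genes <- readGeneTable(path("genes.tsv"))
        chromSizes <- readChromSizes(path("chrom.sizes"))
        polII <- readBedGraph(path("PolII.bedGraph"), simCfg@binSize,
                              chromSizes)
        mat <- buildMatrix(polII, genes, flank = config$metagene_flank,
                           orientByStrand = FALSE)
        prof <- metageneProfile(mat, config$outlier_sd)
        prof$n_used <- attr(prof, "n_used")
        utils::write.table(prof, path("metagene_polII.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("metagene_polII.tsv")
        stageLog(log, "metagene", "%d/%d regions retained",
                 attr(prof, "n_used"), nrow(mat))
    })

    ## -- pchic --------------------------------------------------------
    runStage("pchic", {
        truth <- utils::read.delim(path("truth.tsv"))
        ctrl <- filterInteractions(readInteractions(path("pchic_ctrl.tsv")),
                                   config$min_reads, config$max_distance)
        kd <- filterInteractions(readInteractions(path("pchic_kd.tsv")),
                                 config$min_reads, config$max_distance)
        # joint normalization across both conditions' replicates
        joint <- quantileNormalize(rbind(
            as.matrix(ctrl[, c("count_rep1", "count_rep2")]),
            as.matrix(kd[, c("count_rep1", "count_rep2")])))
        nC <- nrow(ctrl)
        sumC <- summarizePerGene(ctrl, baits = truth$gene_id,
                                 normalized = joint[seq_len(nC), ,
                                                    drop = FALSE])
        sumK <- summarizePerGene(kd, baits = truth$gene_id,
                                 normalized = joint[-seq_len(nC), ,
                                                    drop = FALSE])
        sumC$condition <- "ctrl"; sumK$condition <- "kd"
        utils::write.table(rbind(sumC, sumK), path("pchic_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("pchic_summary.tsv")
        groups <- stats::setNames(truth$class, truth$gene_id)
        cmp <- compareConditions(sumC, sumK, groups)
        utils::write.table(cmp$paired, path("pchic_paired_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cmp$between, path("pchic_between_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("pchic_paired_tests.tsv"); emit("pchic_between_tests.tsv")
        stageLog(log, "pchic", "%d ctrl + %d kd kept interactions",
                 nrow(ctrl), nrow(kd))
    })

    manifest <- data.frame(
        file = outputs,
        md5 = unname(tools::md5sum(file.path(outDir, outputs))))
    utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stageLog(log, "done", "%d outputs in %s", nrow(manifest), outDir)
    invisible(manifest)
}
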