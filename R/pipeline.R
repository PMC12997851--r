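#' @include AllClasses.R AllGenerics.R
NULL

.configError <- function(...) {
    stop(structure(class = c("bsinc_config_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        if (inherits(e, "bsinc_config_error") ||
            inherits(e, "bsinc_stage_error")) stop(e)
        stop(structure(class = c("bsinc_stage_error", "error", "condition"),
                       list(message = sprintf("[stage %s] %s", name,
                                              conditionMessage(e)),
                            call = NULL)))
    })
}

.defaultThresholds <- list(lod = 0.10, loq_cv = 0.10, min_quality = 7,
                           min_length = 200)

#' Run the full detection + quantitation pipeline from one config
#'
#' Executes filter -> (optional) subsample -> coverage -> BEF -> calibrate
#' -> quantify -> aggregate -> report from a single YAML/JSON config (or an
#' equivalent R list), writing `model.json`, `quant.tsv`, `rank_<rank>.tsv`,
#' `coverage.tsv`, `accounting.tsv`, `composition.tsv` and `run_log.txt`
#' into the output directory. Reruns with the same config and seed produce
#' byte-identical tables.
#'
#' Config fields: `reference_manifest`, `spikein_truth`, `barcodes` (list of
#' records with `barcode`, `material`, `replicate_group`, `fastq`,
#' `alignments` (PAF or SAM), `input_dna_ng`, optional `volume_ul`),
#' optional `thresholds` (`lod`, `loq_cv`, `min_quality`, `min_length`),
#' `kappa`, `seed`, optional `subsample_target_bases`, `rank`,
#' `output_dir`.
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @param outputDir Overrides the config's `output_dir`.
#' @return Invisibly, a result bundle: `db`, `truth`, `libraries`,
#'   `coverage`, `befs`, `model`, `quant`, `rankTable`, `composition`,
#'   `accounting`, `paths`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) {
        if (!file.exists(config)) .configError("config not found: ", config)
        config <- yaml::read_yaml(config)
    }
    for (f in c("reference_manifest", "spikein_truth", "barcodes"))
        if (is.null(config[[f]])) .configError("config missing field: ", f)
    thr <- utils::modifyList(.defaultThresholds,
                             as.list(config$thresholds %||% list()))
    if (thr$lod < 0 || thr$lod > 1 || thr$loq_cv < 0)
        .configError("thresholds out of range")
    # detection/quantitation thresholds for reporting may be stricter than
    # the calibration filters (e.g. a survey run with lod = 1.0 still needs
    # a calibration to report against)
    calLod <- thr$calibration_lod %||% thr$lod
    calLoq <- thr$calibration_loq_cv %||% thr$loq_cv
    kappa <- config$kappa %||% 1e7
    seed <- config$seed %||% 42
    rank <- config$rank %||% "genus"
    outdir <- outputDir %||% config$output_dir %||% "bsinc_out"
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (b in config$barcodes)
        for (f in c("fastq", "alignments"))
            if (!is.null(b[[f]]) && !file.exists(b[[f]]))
                .configError("file not found for barcode ", b$barcode,
                             ": ", b[[f]])

    log <- c(sprintf("bsinc %s | R %s", as.character(
                 utils::packageVersion("bsinc")), getRversion()),
             sprintf("seed=%s kappa=%g lod=%g loq_cv=%g min_quality=%g min_length=%g",
                     seed, kappa, thr$lod, thr$loq_cv, thr$min_quality,
                     thr$min_length))

    db <- .stage("reference_db",
                 loadReferenceManifest(config$reference_manifest,
                                       keepSequences = FALSE))
    truth <- .stage("reference_db",
                    loadSpikeInTruth(config$spikein_truth, db))
    log <- c(log, sprintf("reference_db: %d genomes (%d spike-in)",
                          length(genomeIds(db)), length(spikeInIds(db))))

    libs <- list(); cov <- list(); vol <- NULL
    for (i in seq_along(config$barcodes)) {
        b <- config$barcodes[[i]]
        lib <- .stage("read_processing", {
            l <- readFastqLibrary(b$fastq, b$barcode,
                                  material = b$material,
                                  replicateGroup = b$replicate_group %||%
                                      b$material,
                                  inputDnaNg = b$input_dna_ng,
                                  keepSequences = FALSE)
            l <- filterReads(l, thr$min_quality, thr$min_length)
            if (!is.null(config$subsample_target_bases))
                l <- subsampleToBases(l, config$subsample_target_bases,
                                      .deriveSeed(seed, i))
            l
        })
        cov[[b$barcode]] <- .stage("alignment_summary", {
            aln <- parseAlignments(b$alignments, db, b$barcode)
            aln <- aln[aln$read_id %in% readInfo(lib)$read_id, ,
                       drop = FALSE]
            summarizeCoverage(aln, db, b$barcode)
        })
        libs[[b$barcode]] <- lib
        if (is.null(vol) && b$material == "sample" &&
            !is.null(b$volume_ul)) vol <- b$volume_ul
        log <- c(log, sprintf("barcode %s (%s): %d reads, %.0f bases after filtering",
                              b$barcode, b$material, nReads(lib),
                              totalBases(lib)))
    }
    coverage <- do.call(rbind, cov); rownames(coverage) <- NULL
    befs <- .stage("bsinc_quant", do.call(rbind, lapply(libs, function(l)
        barcodeEffectFactor(totalBases(l), l@inputDnaNg, kappa,
                            l@barcode))))
    rownames(befs) <- NULL

    isSpike <- vapply(libs, function(l) l@material == "spike_in",
                      logical(1))
    spikeBC <- names(libs)[isSpike]
    sampleBC <- names(libs)[!isSpike]
    if (length(spikeBC) < 1L) .configError("no spike_in barcodes in config")
    if (length(sampleBC) < 1L) .configError("no sample barcodes in config")

    model <- tryCatch(
        fitCalibration(truth,
                       observedCopyNumber(
                           coverage[coverage$barcode %in% spikeBC, ,
                                    drop = FALSE], befs),
                       lod = calLod, loqCv = calLoq, kappa = kappa),
        error = function(e)
            stop(structure(class = c("bsinc_calibration_error", "error",
                                     "condition"),
                           list(message = conditionMessage(e),
                                call = NULL))))
    log <- c(log, sprintf("calibration: slope=%.4f intercept=%.4f R2=%s n=%d",
                          model@slope, model@intercept,
                          ifelse(is.na(model@rSquared), "NA",
                                 sprintf("%.4f", model@rSquared)),
                          model@nPoints))

    quant <- .stage("bsinc_quant", {
        q <- quantifySample(coverage[coverage$barcode %in% sampleBC, ,
                                     drop = FALSE],
                            befs, model, lod = thr$lod, loqCv = thr$loq_cv,
                            volumeUl = vol)
        sampleIds <- genomeIds(db)[genomeRoles(db) == "sample_reference"]
        q[q$genome_id %in% sampleIds, , drop = FALSE]
    })
    tax <- taxonomyTable(db)
    quant <- cbind(quant,
                   taxonomy = .formatTaxonomy(
                       tax[match(quant$genome_id, tax$genome_id), ]))
    rankTable <- .stage("bsinc_quant", aggregateRank(quant, db, rank))
    log <- c(log, sprintf("quantified %d/%d sample genomes (rank %s: %d labels)",
                          sum(quant$quantifiable), nrow(quant), rank,
                          nrow(rankTable)))

    composition <- .stage("metrics", {
        est <- stats::setNames(quant$estimated_copies, quant$genome_id)
        est <- est[quant$quantifiable]
        if (length(est)) {
            rel <- relativeAbundance(est)
            data.frame(genome_id = names(rel), estimated_copies = est,
                       rel_abundance = as.numeric(rel),
                       simpson_dominance = simpsonDominance(rel),
                       stringsAsFactors = FALSE, row.names = NULL)
        } else data.frame(genome_id = character(), estimated_copies = numeric(),
                          rel_abundance = numeric(),
                          simpson_dominance = numeric())
    })

    accounting <- libraryAccounting(libs)
    paths <- list(model = file.path(outdir, "model.json"),
                  quant = file.path(outdir, "quant.tsv"),
                  rank = file.path(outdir, sprintf("rank_%s.tsv", rank)),
                  coverage = file.path(outdir, "coverage.tsv"),
                  accounting = file.path(outdir, "accounting.tsv"),
                  composition = file.path(outdir, "composition.tsv"),
                  log = file.path(outdir, "run_log.txt"))
    writeCalibrationModel(model, paths$model)
    .writeTsv(quant, paths$quant)
    .writeTsv(rankTable, paths$rank)
    .writeTsv(coverage, paths$coverage)
    .writeTsv(accounting, paths$accounting)
    .writeTsv(composition, paths$composition)
    writeLines(log, paths$log)
    invisible(list(db = db, truth = truth, libraries = libs,
                   coverage = coverage, befs = befs, model = model,
                   quant = quant, rankTable = rankTable,
                   composition = composition, accounting = accounting,
                   paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
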