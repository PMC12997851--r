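#' @include AllClasses.R AllGenerics.R
NULL

#' Barcode effect factor (BEF)
#'
#' Ratio of a barcode's observed sequencing output (bp) to its theoretical
#' output implied by the input DNA mass, `observedBases / (kappa *
#' inputDnaNg)`. BEF corrects the batch effect of variable barcode ligation
#' efficiency so one calibration model can serve all barcodes. The yield
#' constant `kappa` (bp per ng) is a run-level configuration value; final
#' calibrated estimates are invariant to it (the log shift is absorbed by
#' the calibration intercept).
#'
#' @param observedBases Observed sequenced bases for the barcode (bp, > 0).
#' @param inputDnaNg Input DNA mass (ng, > 0).
#' @param kappa Theoretical yield constant (bp/ng, > 0; default 1e7).
#' @param barcode Optional barcode label(s).
#' @return data.frame: `barcode`, `observed_bases`, `input_dna_ng`, `kappa`,
#'   `bef`. Vectorized over barcodes.
#' @export
barcodeEffectFactor <- function(observedBases, inputDnaNg, kappa = 1e7,
                                barcode = NA_character_) {
    if (any(!is.finite(observedBases) | observedBases <= 0))
        stop("observedBases must be > 0", call. = FALSE)
    if (any(!is.finite(inputDnaNg) | inputDnaNg <= 0))
        stop("inputDnaNg must be > 0", call. = FALSE)
    .assertScalarNumber(kappa, "kappa", positive = TRUE)
    data.frame(barcode = barcode,
               observed_bases = as.numeric(observedBases),
               input_dna_ng = as.numeric(inputDnaNg),
               kappa = kappa,
               bef = as.numeric(observedBases) / (kappa * as.numeric(inputDnaNg)),
               stringsAsFactors = FALSE)
}

#' Observed genome copy number
#'
#' BEF-normalized mapped bases divided by covered bases, per genome and
#' barcode: `(mapped_bases / bef) / covered_bases`. Dividing by covered
#' bases (not genome length) makes the statistic usable with draft genomes.
#' Genomes with zero covered bases get `NA` copies with reason
#' `"no coverage"` — absence of evidence, never zero copies.
#'
#' @param coverage Coverage summary rows from [summarizeCoverage()].
#' @param bef One-row BEF table from [barcodeEffectFactor()] (or a list of
#'   rows covering all barcodes present).
#' @return `coverage` with added columns `bef`, `copies_observed`,
#'   `copy_reason`.
#' @export
observedCopyNumber <- function(coverage, bef) {
    if (!all(c("genome_id", "barcode", "mapped_bases", "covered_bases") %in%
             names(coverage)))
        stop("coverage must come from summarizeCoverage()", call. = FALSE)
    m <- match(coverage$barcode, bef$barcode)
    if (anyNA(m))
        stop("barcode mismatch between coverage and BEF table: ",
             paste(unique(coverage$barcode[is.na(m)]), collapse = ", "),
             call. = FALSE)
    coverage$bef <- bef$bef[m]
    ok <- coverage$covered_bases > 0
    coverage$copies_observed <- ifelse(
        ok, (coverage$mapped_bases / coverage$bef) / coverage$covered_bases,
        NA_real_)
    coverage$copy_reason <- ifelse(ok, "ok", "no coverage")
    coverage
}

#' Dynamic limit of detection on coverage fraction
#'
#' A genome is detected when its coverage fraction is strictly greater than
#' the threshold (default 10% of the genome covered by at least one read),
#' which guards against false positives from reads mapping only to conserved
#' regions.
#'
#' @param coverageFraction Numeric vector in `[0, 1]`.
#' @param threshold LOD threshold (default 0.10).
#' @return Logical vector: detected.
#' @export
applyLod <- function(coverageFraction, threshold = 0.10) {
    if (any(coverageFraction < 0 | coverageFraction > 1, na.rm = TRUE))
        stop("coverage fraction must be in [0, 1]", call. = FALSE)
    !is.na(coverageFraction) & coverageFraction > threshold
}

#' Replicate coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) over the mean, across
#' replicate barcodes. Returns `NA` with fewer than 2 defined values or a
#' zero mean.
#'
#' @param values Numeric vector of observed copy numbers across replicates
#'   (`NA`s dropped).
#' @return CV as a fraction, or `NA`.
#' @export
replicateCv <- function(values) {
    v <- values[is.finite(values)]
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    stats::sd(v) / m
}

.retainSpikeGenomes <- function(truth, observed, lod, loqCv) {
    sp <- split(observed, observed$genome_id)
    keep <- vapply(truth$genome_id, function(g) {
        o <- sp[[g]]
        if (is.null(o) || !nrow(o)) return(FALSE)
        if (!all(applyLod(o$coverage_fraction, lod))) return(FALSE)
        if (any(!is.finite(o$copies_observed))) return(FALSE)
        cv <- replicateCv(o$copies_observed)
        !is.na(cv) && cv <= loqCv
    }, logical(1))
    truth$genome_id[keep]
}

#' Fit the spike-in calibration model
#'
#' Ordinary least squares of `y = log10(theoretical copies)` on
#' `x = log10(observed copies)` over spike-in genomes that pass the dynamic
#' LOD in every replicate barcode and whose replicate CV is at most the LOQ
#' threshold. By default each genome contributes one point at its
#' replicate-mean observed copy number (`aggregate = "mean"`); with
#' `aggregate = "pooled"` every barcode contributes its own point.
#'
#' @param truth Spike-in truth table ([loadSpikeInTruth()]).
#' @param observed Observed copy numbers ([observedCopyNumber()]) for the
#'   replicate spike-in barcodes.
#' @param lod Coverage-fraction detection threshold (default 0.10).
#' @param loqCv Replicate-CV quantitation threshold (default 0.10).
#' @param aggregate `"mean"` or `"pooled"` (see Details).
#' @param kappa Yield constant recorded in the model (bookkeeping only).
#' @return A [CalibrationModel-class]. R-squared is `NA` with fewer than 3
#'   points; fewer than 2 retained genomes is a hard error
#'   ("calibration underdetermined").
#' @export
fitCalibration <- function(truth, observed, lod = 0.10, loqCv = 0.10,
                           aggregate = c("mean", "pooled"), kappa = NA_real_) {
    aggregate <- match.arg(aggregate)
    retained <- .retainSpikeGenomes(truth, observed, lod, loqCv)
    if (length(retained) < 2L)
        stop("calibration underdetermined: fewer than 2 spike-in genomes ",
             "pass the LOD/LOQ filters", call. = FALSE)
    obs <- observed[observed$genome_id %in% retained, , drop = FALSE]
    theo <- stats::setNames(truth$theoretical_copies, truth$genome_id)
    if (aggregate == "mean") {
        xbar <- vapply(split(obs$copies_observed, obs$genome_id), mean,
                       numeric(1))
        x <- log10(xbar[retained])
        y <- log10(theo[retained])
    } else {
        x <- log10(obs$copies_observed)
        y <- log10(theo[obs$genome_id])
    }
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    r2 <- if (length(x) >= 3L)
        1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    else NA_real_
    new("CalibrationModel", slope = unname(cf[2L]),
        intercept = unname(cf[1L]), rSquared = r2,
        nPoints = length(x), retained = retained,
        filters = list(lod = lod, loq_cv = loqCv), kappa = kappa,
        method = if (aggregate == "mean") "ols_mean" else "ols_pooled")
}

#' Apply a calibration model to observed copy numbers
#'
#' `10^(intercept + slope * log10(observed))`. Non-positive or missing
#' observed copies yield `NA` (no evidence, not zero). A zero-slope model is
#' degenerate (constant output) and raises a warning.
#'
#' @param model A [CalibrationModel-class].
#' @param copiesObserved Numeric vector of observed copy numbers.
#' @return Estimated absolute genome copy numbers.
#' @export
estimateCopies <- function(model, copiesObserved) {
    if (model@slope == 0)
        warning("zero-slope calibration model: all estimates are constant")
    ifelse(is.finite(copiesObserved) & copiesObserved > 0,
           10^(model@intercept + model@slope * log10(copiesObserved)),
           NA_real_)
}

#' Quantify sample genomes across replicate barcodes
#'
#' Per genome: detection by dynamic LOD in each replicate (by default a
#' genome must pass in all replicates; `detection = "any"` relaxes this),
#' replicate CV of observed copies, quantifiability (CV at or below the LOQ
#' threshold), and — for detected, quantifiable genomes — the calibrated
#' estimate from the replicate-mean observed copy number. Undetected or
#' unquantifiable genomes are reported with flags, never dropped.
#'
#' @param coverage Coverage summaries over the replicate sample barcodes
#'   (rows from [summarizeCoverage()], all barcodes stacked).
#' @param befs BEF table covering those barcodes ([barcodeEffectFactor()]).
#' @param model A fitted [CalibrationModel-class].
#' @param lod,loqCv Thresholds (defaults as recorded in the model).
#' @param detection `"all"` (conservative default) or `"any"`.
#' @param volumeUl Optional DNA-extract volume (µL) represented by one
#'   barcode library; adds `copies_per_ul`.
#' @return data.frame: `genome_id`, `n_replicates`, `n_detected`,
#'   `detected`, `mean_observed`, `cv`, `quantifiable`, `estimated_copies`,
#'   optionally `copies_per_ul`.
#' @export
quantifySample <- function(coverage, befs, model,
                           lod = model@filters$lod,
                           loqCv = model@filters$loq_cv,
                           detection = c("all", "any"), volumeUl = NULL) {
    detection <- match.arg(detection)
    obs <- observedCopyNumber(coverage, befs)
    sp <- split(obs, obs$genome_id)
    rows <- lapply(names(sp), function(g) {
        o <- sp[[g]]
        det_rep <- applyLod(o$coverage_fraction, lod)
        detected <- if (detection == "all") all(det_rep) else any(det_rep)
        cv <- replicateCv(o$copies_observed)
        vals <- o$copies_observed[is.finite(o$copies_observed)]
        meanobs <- if (length(vals)) mean(vals) else NA_real_
        quant <- isTRUE(detected) && !is.na(cv) && cv <= loqCv
        est <- if (quant) estimateCopies(model, meanobs) else NA_real_
        data.frame(genome_id = g, n_replicates = nrow(o),
                   n_detected = sum(det_rep), detected = detected,
                   mean_observed = meanobs, cv = cv, quantifiable = quant,
                   estimated_copies = est, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$genome_id), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(volumeUl))
        out$copies_per_ul <- copiesPerUl(out$estimated_copies, volumeUl)
    out
}

#' Convert library copies to copies per microliter of extract
#'
#' @param estimatedCopies Copies per barcode library.
#' @param volumeUl Extract volume loaded per library (µL, > 0).
#' @return Copies/µL DNA extract.
#' @export
copiesPerUl <- function(estimatedCopies, volumeUl) {
    .assertScalarNumber(volumeUl, "volumeUl", positive = TRUE)
    estimatedCopies / volumeUl
}

#' Aggregate genome-level estimates to a taxonomic rank
#'
#' Sums estimated copies of quantifiable genomes sharing a rank label
#' (e.g., species abundances aggregated to genus-level estimates). Taxa
#' whose genomes all lack estimates are absent from the quantified totals
#' but present in the coverage report.
#'
#' @param quant Output of [quantifySample()].
#' @param db A [ReferenceDB-class] supplying taxonomy.
#' @param rank One of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return data.frame: rank label, `estimated_copies` (NA when no member
#'   genome is quantifiable), `n_genomes`, `n_quantified`.
#' @export
aggregateRank <- function(quant, db, rank = "genus") {
    if (!rank %in% .TAX_RANKS)
        stop("unknown rank '", rank, "'; use one of ",
             paste(.TAX_RANKS, collapse = ", "), call. = FALSE)
    tax <- taxonomyTable(db)
    lab <- tax[[rank]][match(quant$genome_id, tax$genome_id)]
    if (anyNA(lab))
        stop("genome(s) missing from the reference database: ",
             paste(quant$genome_id[is.na(lab)], collapse = ", "),
             call. = FALSE)
    sp <- split(seq_len(nrow(quant)), lab)
    out <- do.call(rbind, lapply(names(sp), function(tx) {
        i <- sp[[tx]]
        q <- quant$quantifiable[i]
        data.frame(rank_label = tx,
                   estimated_copies = if (any(q))
                       sum(quant$estimated_copies[i][q]) else NA_real_,
                   n_genomes = length(i), n_quantified = sum(q),
                   stringsAsFactors = FALSE)
    }))
    names(out)[1L] <- rank
    rownames(out) <- NULL
    out
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A [CalibrationModel-class].
#' @param path JSON path.
#' @return `writeCalibrationModel`: invisibly, `path`;
#'   `readCalibrationModel`: the restored model.
#' @export
writeCalibrationModel <- function(model, path) {
    jsonlite::write_json(list(
        slope = model@slope, intercept = model@intercept,
        r_squared = model@rSquared, n_points = model@nPoints,
        retained_genomes = model@retained,
        lod = model@filters$lod, loq_cv = model@filters$loq_cv,
        kappa = model@kappa, method = model@method),
        path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    invisible(path)
}

#' @rdname writeCalibrationModel
#' @export
readCalibrationModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("CalibrationModel", slope = j$slope, intercept = j$intercept,
        rSquared = if (is.null(j$r_squared)) NA_real_ else j$r_squared,
        nPoints = as.integer(j$n_points),
        retained = as.character(j$retained_genomes),
        filters = list(lod = j$lod, loq_cv = j$loq_cv),
        kappa = if (is.null(j$kappa)) NA_real_ else j$kappa,
        method = j$method)
}

#' Calibrate and quantify a simulated or in-memory experiment
#'
#' In-memory mirror of [runPipeline()] for result bundles produced by
#' [simulateExperiment()] / [expectedExperiment()] (or any list with
#' `coverage`, `befs`, `truth`, `sampleTruth`, `db`): recomputes BEFs at
#' `kappa`, fits the spike-in calibration on the spike-in barcodes, and
#' quantifies the sample barcodes.
#'
#' @param sim Experiment bundle.
#' @param lod,loqCv Filter thresholds.
#' @param aggregate Calibration aggregation (see [fitCalibration()]).
#' @param kappa Yield constant; BEFs are recomputed from the bundle's
#'   observed bases and input DNA at this value.
#' @param useBef With `FALSE`, barcode effect factors are forced to 1
#'   (normalization off) — for quantifying the effect of BEF itself.
#' @param detection Replicate detection rule for [quantifySample()].
#' @return List: `model` ([CalibrationModel-class]), `quant` (sample
#'   genomes only), `befs`.
#' @export
calibrateAndQuantify <- function(sim, lod = 0.10, loqCv = 0.10,
                                 aggregate = "mean", kappa = 1e7,
                                 useBef = TRUE, detection = "all") {
    befs <- barcodeEffectFactor(sim$befs$observed_bases,
                                sim$befs$input_dna_ng, kappa,
                                sim$befs$barcode)
    if (!useBef) befs$bef <- 1
    roles <- genomeRoles(sim$db)
    spikeBC <- unique(sim$coverage$barcode[
        sim$coverage$barcode %in% sim$run$barcodes$barcode[
            sim$run$barcodes$material == "spike_in"]])
    sampleBC <- setdiff(unique(sim$coverage$barcode), spikeBC)
    spikeObs <- observedCopyNumber(
        sim$coverage[sim$coverage$barcode %in% spikeBC &
                     sim$coverage$genome_id %in% sim$truth$genome_id, ,
                     drop = FALSE], befs)
    model <- fitCalibration(sim$truth, spikeObs, lod = lod, loqCv = loqCv,
                            aggregate = aggregate, kappa = kappa)
    quant <- quantifySample(
        sim$coverage[sim$coverage$barcode %in% sampleBC &
                     sim$coverage$genome_id %in%
                         names(roles)[roles == "sample_reference"], ,
                     drop = FALSE],
        befs, model, lod = lod, loqCv = loqCv, detection = detection)
    list(model = model, quant = quant, befs = befs)
}
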