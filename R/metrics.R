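#' @include AllClasses.R AllGenerics.R
NULL

#' Relative abundance of a copy-number vector
#'
#' @param copies Named nonnegative numeric vector (taxon -> copies), at
#'   least one positive entry.
#' @return Named numeric vector summing to 1.
#' @export
relativeAbundance <- function(copies) {
    if (any(!is.finite(copies) | copies < 0))
        stop("copies must be finite and nonnegative", call. = FALSE)
    tot <- sum(copies)
    if (tot == 0) stop("all-zero composition", call. = FALSE)
    copies / tot
}

#' Percent deviation of estimates from theoretical values
#'
#' Per taxon, `100 * (estimated - theoretical) / theoretical`; the summary
#' statistic is the median of the absolute percent deviations (deviation
#' magnitudes). Taxa with zero theoretical value get `NA` deviations and
#' are excluded from the median.
#'
#' @param estimated,theoretical Named numeric vectors sharing taxon names
#'   (relative abundances or absolute copies — use the same scale for both).
#' @return List: `deviation_pct` (named per-taxon signed deviations),
#'   `median_deviation_pct` (median absolute deviation, percent).
#' @export
deviationPct <- function(estimated, theoretical) {
    taxa <- names(theoretical)
    if (is.null(taxa) || is.null(names(estimated)))
        stop("estimated and theoretical must be named", call. = FALSE)
    missing <- setdiff(taxa, names(estimated))
    if (length(missing))
        stop("estimate missing for taxa: ", paste(missing, collapse = ", "),
             call. = FALSE)
    est <- estimated[taxa]
    dev <- ifelse(theoretical == 0, NA_real_,
                  100 * (est - theoretical) / theoretical)
    names(dev) <- taxa
    list(deviation_pct = dev,
         median_deviation_pct = stats::median(abs(dev), na.rm = TRUE))
}

#' Simpson index of a composition
#'
#' The dominance form `sum(p_i^2)` (1 for a single-taxon community, `1/S`
#' for a uniform community over `S` taxa) is the default, matching how the
#' index is quoted for mock-community DNA standards (log-distributed
#' standard ~0.9, even gut standard ~0.11); `variant = "complement"` gives
#' the Gini-Simpson diversity `1 - sum(p^2)`.
#'
#' @param p Relative-abundance vector (renormalized if needed) or a copies
#'   vector.
#' @param variant `"dominance"` (default) or `"complement"`.
#' @return Numeric scalar.
#' @export
simpsonDominance <- function(p, variant = c("dominance", "complement")) {
    variant <- match.arg(variant)
    p <- relativeAbundance(p)
    d <- sum(p^2)
    if (variant == "dominance") d else 1 - d
}

#' Single-taxon spike-in calibration
#'
#' The conventional single spike-in strategy: a lone correction factor from
#' one taxon, i.e. a log10-space line with slope fixed at 1 and intercept
#' `log10(theoretical) - log10(observed)`. R-squared is undefined. The
#' taxon must pass the LOD in every replicate.
#'
#' @param theoreticalCopies Theoretical copies of the single spike-in taxon.
#' @param copiesObserved Observed copy number(s) of that taxon across
#'   replicate barcodes (the replicate mean is used).
#' @param coverageFraction Coverage fraction(s) across the same replicates.
#' @param lod Detection threshold (default 0.10).
#' @param genomeId Label recorded in the model.
#' @return A [CalibrationModel-class] with `method = "single_taxon"`.
#' @export
singleSpikeInCalibration <- function(theoreticalCopies, copiesObserved,
                                     coverageFraction, lod = 0.10,
                                     genomeId = "single_spikein") {
    .assertScalarNumber(theoreticalCopies, "theoreticalCopies",
                        positive = TRUE)
    if (!all(applyLod(coverageFraction, lod)))
        stop("single spike-in taxon below LOD (coverage fraction <= ",
             lod, ")", call. = FALSE)
    obs <- mean(copiesObserved[is.finite(copiesObserved)])
    if (!is.finite(obs) || obs <= 0)
        stop("single spike-in taxon has no defined observed copy number",
             call. = FALSE)
    new("CalibrationModel", slope = 1,
        intercept = log10(theoreticalCopies) - log10(obs),
        rSquared = NA_real_, nPoints = 1L, retained = genomeId,
        filters = list(lod = lod, loq_cv = NA_real_), kappa = NA_real_,
        method = "single_taxon")
}

#' Sequencing-effort titration of the calibration
#'
#' For each target sequencing effort (ascending bases): subsample every
#' spike-in library to the target, recompute BEFs from the subsampled
#' output, summarize coverage from the retained reads' alignments, refit
#' the calibration, and score the deviation of the spike-ins' estimated
#' composition from the theoretical composition. Emits a tidy long table
#' for convergence plots.
#'
#' @param libs List of replicate spike-in [BarcodeLibrary-class] objects.
#' @param alignments Alignment table covering those barcodes
#'   ([parseAlignments()] output, stacked).
#' @param db A [ReferenceDB-class].
#' @param truth Spike-in truth table.
#' @param targets Ascending numeric vector of target bases per barcode.
#' @param seed Master seed (per-target, per-barcode streams are derived).
#' @param kappa Yield constant for the BEFs.
#' @param lod,loqCv Calibration filter thresholds.
#' @return Long data.frame: `target_bases`, `metric`
#'   (`slope`/`intercept`/`r_squared`/`n_points`/`median_deviation_pct`),
#'   `value`, `seed`.
#' @export
effortTitration <- function(libs, alignments, db, truth, targets, seed = 42,
                            kappa = 1e7, lod = 0.10, loqCv = 0.10) {
    if (is.unsorted(targets, strictly = FALSE))
        stop("targets must be ascending", call. = FALSE)
    theo_rel <- stats::setNames(truth$theoretical_rel_abundance,
                                truth$genome_id)
    out <- lapply(seq_along(targets), function(ti) {
        tgt <- targets[ti]
        subs <- lapply(seq_along(libs), function(i)
            subsampleToBases(libs[[i]], tgt, .deriveSeed(seed, ti * 131 + i)))
        cov <- do.call(rbind, lapply(subs, function(l) {
            keep <- alignments$read_id %in% readInfo(l)$read_id
            summarizeCoverage(alignments[keep, , drop = FALSE], db,
                              l@barcode)
        }))
        befs <- do.call(rbind, lapply(subs, function(l)
            barcodeEffectFactor(totalBases(l), l@inputDnaNg, kappa,
                                l@barcode)))
        obs <- observedCopyNumber(cov, befs)
        obs <- obs[obs$genome_id %in% truth$genome_id, , drop = FALSE]
        vals <- tryCatch({
            model <- fitCalibration(truth, obs, lod, loqCv, kappa = kappa)
            meanobs <- vapply(split(obs$copies_observed, obs$genome_id),
                              function(v) mean(v[is.finite(v)]), numeric(1))
            est <- estimateCopies(model, meanobs[model@retained])
            names(est) <- model@retained
            md <- deviationPct(
                relativeAbundance(est),
                relativeAbundance(theo_rel[model@retained]))$median_deviation_pct
            c(slope = model@slope, intercept = model@intercept,
              r_squared = model@rSquared, n_points = model@nPoints,
              median_deviation_pct = md)
        }, error = function(e)
            c(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
              n_points = NA_real_, median_deviation_pct = NA_real_))
        data.frame(target_bases = tgt, metric = names(vals),
                   value = unname(vals), seed = seed,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Compare multi-taxon vs single-taxon spike-in calibration
#'
#' Quantifies one simulated (or real, in-memory) experiment twice: once with
#' the full multi-taxon spike-in regression and once with an intercept-only
#' correction derived from a single spike-in taxon
#' ([singleSpikeInCalibration()]), and reports the median absolute percent
#' deviation of the sample genomes' absolute copy estimates from truth under
#' each strategy. Deviations are computed on absolute copies because an
#' intercept-only correction leaves relative abundances untouched — only the
#' absolute scale can distinguish the two strategies.
#'
#' @param sim Experiment bundle from [simulateExperiment()] (needs
#'   `sampleTruth`).
#' @param singleGenomeId Spike-in genome to use as the lone calibrant.
#' @param lod,loqCv Filter thresholds.
#' @param kappa Yield constant.
#' @return List: `median_deviation_pct` (named: `multi`, `single`),
#'   `deviations` (per-genome signed percent deviations for each strategy).
#' @export
compareSpikeInStrategies <- function(sim, singleGenomeId, lod = 0.10,
                                     loqCv = 0.10, kappa = 1e7) {
    res <- calibrateAndQuantify(sim, lod = lod, loqCv = loqCv,
                                kappa = kappa)
    spikeBC <- sim$run$barcodes$barcode[
        sim$run$barcodes$material == "spike_in"]
    spikeObs <- observedCopyNumber(
        sim$coverage[sim$coverage$barcode %in% spikeBC &
                     sim$coverage$genome_id == singleGenomeId, ,
                     drop = FALSE], res$befs)
    theoSingle <- sim$truth$theoretical_copies[
        sim$truth$genome_id == singleGenomeId]
    mSingle <- singleSpikeInCalibration(theoSingle,
                                        spikeObs$copies_observed,
                                        spikeObs$coverage_fraction,
                                        lod = lod,
                                        genomeId = singleGenomeId)
    q <- res$quant
    ok <- is.finite(q$mean_observed) & q$mean_observed > 0
    q <- q[ok, , drop = FALSE]
    truthCopies <- stats::setNames(sim$sampleTruth$theoretical_copies,
                                   sim$sampleTruth$genome_id)[q$genome_id]
    estMulti <- stats::setNames(estimateCopies(res$model, q$mean_observed),
                                q$genome_id)
    estSingle <- stats::setNames(estimateCopies(mSingle, q$mean_observed),
                                 q$genome_id)
    dMulti <- deviationPct(estMulti, truthCopies)
    dSingle <- deviationPct(estSingle, truthCopies)
    list(median_deviation_pct = c(multi = dMulti$median_deviation_pct,
                                  single = dSingle$median_deviation_pct),
         deviations = data.frame(genome_id = q$genome_id,
                                 multi_pct = unname(dMulti$deviation_pct),
                                 single_pct = unname(dSingle$deviation_pct),
                                 stringsAsFactors = FALSE))
}
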