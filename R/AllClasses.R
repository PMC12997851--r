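#' @import methods
NULL

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Reference genome database
#'
#' Holds one record per reference genome (complete assemblies or MAGs) with
#' its total length, seven-rank taxonomy, and role (`spike_in` or
#' `sample_reference`), plus the contig-to-genome map used to lift
#' contig-level alignment coordinates onto concatenated genome coordinates.
#' Multi-contig genomes are first class: a genome's length is the sum of its
#' contig lengths and all coverage statistics are genome-level aggregates.
#'
#' @slot genomes data.frame with columns `genome_id`, `length`, `role`,
#'   and the seven taxonomic ranks `domain` ... `species`.
#' @slot contigs data.frame with columns `contig_id`, `genome_id`,
#'   `length`, `offset` (0-based start of the contig on the concatenated
#'   genome coordinate system).
#' @slot sequences Optional [Biostrings::DNAStringSet] of contig sequences
#'   (named by contig id), or `NULL` when sequences were not retained.
#'
#' @seealso [loadReferenceManifest()], [genomeLengths()], [taxonomyTable()]
#' @export
setClass("ReferenceDB",
    representation(genomes = "data.frame", contigs = "data.frame",
                   sequences = "ANY"),
    prototype(sequences = NULL))

setValidity("ReferenceDB", function(object) {
    g <- object@genomes
    ct <- object@contigs
    msgs <- character()
    need <- c("genome_id", "length", "role", .TAX_RANKS)
    if (!all(need %in% names(g)))
        msgs <- c(msgs, paste("genomes table must have columns:",
                              paste(setdiff(need, names(g)), collapse = ", ")))
    else {
        if (anyDuplicated(g$genome_id))
            msgs <- c(msgs, "duplicate genome_id in database")
        if (nrow(g) && any(g$length <= 0))
            msgs <- c(msgs, "genome lengths must be > 0")
        if (nrow(g) && !all(g$role %in% c("spike_in", "sample_reference")))
            msgs <- c(msgs, "role must be 'spike_in' or 'sample_reference'")
    }
    needc <- c("contig_id", "genome_id", "length", "offset")
    if (!all(needc %in% names(ct)))
        msgs <- c(msgs, "contigs table must have columns contig_id, genome_id, length, offset")
    else if (nrow(ct) && !all(ct$genome_id %in% g$genome_id))
        msgs <- c(msgs, "contig mapped to unknown genome_id")
    if (length(msgs)) msgs else TRUE
})

#' One barcoded read library
#'
#' Per-barcode container for long reads: read-level metadata (id, length,
#' mean Phred quality) plus, optionally, the sequences and qualities
#' themselves. The library also carries the run metadata the barcode effect
#' factor needs (input DNA mass in ng) and the experimental role of the
#' barcode (spike-in standard or sample).
#'
#' @slot barcode Character scalar barcode label.
#' @slot material `"spike_in"` or `"sample"`.
#' @slot replicateGroup Character scalar naming the replicate set this
#'   barcode belongs to.
#' @slot inputDnaNg Input DNA mass for this barcode library (ng), > 0.
#' @slot reads data.frame with columns `read_id`, `length`, `mean_quality`.
#' @slot sequences Optional [Biostrings::QualityScaledDNAStringSet] (or
#'   `NULL`), parallel to `reads` and named by read id.
#' @slot stats List of per-stage accounting (kept/dropped reads and bases).
#'
#' @seealso [readFastqLibrary()], [filterReads()], [subsampleToBases()]
#' @export
setClass("BarcodeLibrary",
    representation(barcode = "character", material = "character",
                   replicateGroup = "character", inputDnaNg = "numeric",
                   reads = "data.frame", sequences = "ANY", stats = "list"),
    prototype(material = "sample", replicateGroup = NA_character_,
              inputDnaNg = 1, sequences = NULL, stats = list()))

setValidity("BarcodeLibrary", function(object) {
    msgs <- character()
    if (length(object@barcode) != 1L || is.na(object@barcode))
        msgs <- c(msgs, "barcode must be a single string")
    if (!object@material %in% c("spike_in", "sample"))
        msgs <- c(msgs, "material must be 'spike_in' or 'sample'")
    if (length(object@inputDnaNg) != 1L || is.na(object@inputDnaNg) ||
        object@inputDnaNg <= 0)
        msgs <- c(msgs, "inputDnaNg must be a single positive number")
    r <- object@reads
    if (!all(c("read_id", "length", "mean_quality") %in% names(r)))
        msgs <- c(msgs, "reads table needs read_id, length, mean_quality")
    else {
        if (nrow(r) && any(r$length < 0)) msgs <- c(msgs, "read length < 0")
        if (nrow(r) && any(r$mean_quality < 0, na.rm = TRUE))
            msgs <- c(msgs, "mean_quality < 0")
    }
    if (!is.null(object@sequences) &&
        length(object@sequences) != nrow(object@reads))
        msgs <- c(msgs, "sequences must be NULL or parallel to reads")
    if (length(msgs)) msgs else TRUE
})

#' Spike-in calibration model
#'
#' Ordinary least-squares fit of log10(theoretical genome copies) on
#' log10(observed genome copies) over the spike-in genomes retained after
#' dynamic LOD (genome coverage fraction) and LOQ (replicate CV) filtering.
#' Applying the model to a sample genome's observed copy number yields its
#' calibrated absolute copy number.
#'
#' @slot slope Regression slope (log10/log10).
#' @slot intercept Regression intercept (log10 copies).
#' @slot rSquared Coefficient of determination; `NA` when fewer than 3
#'   points (or for the fixed-slope single spike-in variant).
#' @slot nPoints Number of fitted points.
#' @slot retained Character vector of genome ids retained by the filters.
#' @slot filters List recording `lod`, `loq_cv` thresholds applied.
#' @slot kappa Theoretical sequencing yield constant (bp per ng) in force
#'   when the observed copy numbers were computed.
#' @slot method Fitting method: `"ols_mean"` (replicate-averaged),
#'   `"ols_pooled"` (per-barcode points), or `"single_taxon"` (slope fixed
#'   at 1).
#'
#' @seealso [fitCalibration()], [estimateCopies()],
#'   [singleSpikeInCalibration()]
#' @export
setClass("CalibrationModel",
    representation(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", nPoints = "integer",
                   retained = "character", filters = "list",
                   kappa = "numeric", method = "character"),
    prototype(rSquared = NA_real_, kappa = NA_real_, method = "ols_mean"))

setValidity("CalibrationModel", function(object) {
    msgs <- character()
    if (length(object@slope) != 1L || !is.finite(object@slope))
        msgs <- c(msgs, "slope must be a single finite number")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        msgs <- c(msgs, "intercept must be a single finite number")
    if (object@nPoints < 1L)
        msgs <- c(msgs, "nPoints must be >= 1")
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
        msgs <- c(msgs, "rSquared must be in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "ReferenceDB", function(object) {
    cat(sprintf("ReferenceDB with %d genome(s), %d contig(s)\n",
                nrow(object@genomes), nrow(object@contigs)))
    if (nrow(object@genomes)) {
        tab <- table(object@genomes$role)
        cat("  roles:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
        cat("  total length:", sum(object@genomes$length), "bp\n")
    }
    if (!is.null(object@sequences)) cat("  sequences: retained\n")
})

setMethod("show", "BarcodeLibrary", function(object) {
    cat(sprintf("BarcodeLibrary '%s' (%s, group %s)\n", object@barcode,
                object@material, object@replicateGroup))
    cat(sprintf("  %d read(s), %.0f bases, input DNA %.3g ng\n",
                nrow(object@reads), sum(as.numeric(object@reads$length)),
                object@inputDnaNg))
})

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf("CalibrationModel (%s): log10(theoretical) = %.4f + %.4f * log10(observed)\n",
                object@method, object@intercept, object@slope))
    cat(sprintf("  n = %d, R^2 = %s; LOD %.3g, LOQ CV %.3g\n",
                object@nPoints,
                ifelse(is.na(object@rSquared), "NA",
                       sprintf("%.4f", object@rSquared)),
                object@filters$lod, object@filters$loq_cv))
})
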