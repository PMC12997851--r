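#' @include AllClasses.R
NULL

#' Accessors for bsinc S4 objects
#'
#' Small accessor family for [ReferenceDB-class], [BarcodeLibrary-class] and
#' [CalibrationModel-class] objects; prefer these over direct slot access.
#'
#' @param x A bsinc S4 object.
#' @return `genomeIds`, `retainedGenomes`: character vector.
#'   `genomeLengths`: named numeric vector of genome lengths (bp).
#'   `genomeRoles`: named character vector. `taxonomyTable`, `contigMap`,
#'   `readInfo`: data.frame. `spikeInIds`: character vector of spike-in
#'   genome ids. `nReads`, `nPoints`: integer. `totalBases`: numeric (bp).
#'   `modelSlope`, `modelIntercept`, `rSquared`: numeric scalars.
#'   `filterStats`: list of per-stage read/base accounting.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))
#' @rdname accessors
#' @export
setGeneric("genomeRoles", function(x) standardGeneric("genomeRoles"))
#' @rdname accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))
#' @rdname accessors
#' @export
setGeneric("contigMap", function(x) standardGeneric("contigMap"))
#' @rdname accessors
#' @export
setGeneric("spikeInIds", function(x) standardGeneric("spikeInIds"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))
#' @rdname accessors
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))
#' @rdname accessors
#' @export
setGeneric("readInfo", function(x) standardGeneric("readInfo"))
#' @rdname accessors
#' @export
setGeneric("filterStats", function(x) standardGeneric("filterStats"))
#' @rdname accessors
#' @export
setGeneric("modelSlope", function(x) standardGeneric("modelSlope"))
#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("retainedGenomes", function(x) standardGeneric("retainedGenomes"))

#' @rdname accessors
#' @export
setMethod("genomeIds", "ReferenceDB", function(x) x@genomes$genome_id)
#' @rdname accessors
#' @export
setMethod("genomeLengths", "ReferenceDB", function(x)
    stats::setNames(as.numeric(x@genomes$length), x@genomes$genome_id))
#' @rdname accessors
#' @export
setMethod("genomeRoles", "ReferenceDB", function(x)
    stats::setNames(x@genomes$role, x@genomes$genome_id))
#' @rdname accessors
#' @export
setMethod("taxonomyTable", "ReferenceDB", function(x)
    x@genomes[, c("genome_id", .TAX_RANKS)])
#' @rdname accessors
#' @export
setMethod("contigMap", "ReferenceDB", function(x) x@contigs)
#' @rdname accessors
#' @export
setMethod("spikeInIds", "ReferenceDB", function(x)
    x@genomes$genome_id[x@genomes$role == "spike_in"])

#' @rdname accessors
#' @export
setMethod("nReads", "BarcodeLibrary", function(x) nrow(x@reads))
#' @rdname accessors
#' @export
setMethod("totalBases", "BarcodeLibrary", function(x)
    sum(as.numeric(x@reads$length)))
#' @rdname accessors
#' @export
setMethod("readInfo", "BarcodeLibrary", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("filterStats", "BarcodeLibrary", function(x) x@stats)

#' @rdname accessors
#' @export
setMethod("modelSlope", "CalibrationModel", function(x) x@slope)
#' @rdname accessors
#' @export
setMethod("modelIntercept", "CalibrationModel", function(x) x@intercept)
#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationModel", function(x) x@rSquared)
#' @rdname accessors
#' @export
setMethod("nPoints", "CalibrationModel", function(x) x@nPoints)
#' @rdname accessors
#' @export
setMethod("retainedGenomes", "CalibrationModel", function(x) x@retained)
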