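#' @include AllClasses.R AllGenerics.R
NULL

#' Mean read quality on the Phred scale
#'
#' Long-read mean quality is the Phred transform of the mean per-base error
#' probability, `-10 * log10(mean(10^(-q/10)))` — the basecaller convention —
#' not the arithmetic mean of the per-base Q values.
#'
#' @param perBasePhred Integer (or numeric) vector of per-base Phred scores.
#' @return Phred-scaled mean quality (numeric scalar).
#' @examples
#' meanReadQuality(c(10, 20))  # 12.596..., not 15
#' @export
meanReadQuality <- function(perBasePhred) {
    if (length(perBasePhred) == 0L)
        stop("empty quality vector", call. = FALSE)
    -10 * log10(mean(10^(-perBasePhred / 10)))
}

#' Construct a BarcodeLibrary
#'
#' @param barcode Barcode label.
#' @param reads data.frame with `read_id`, `length`, `mean_quality`.
#' @param material `"spike_in"` or `"sample"`.
#' @param replicateGroup Replicate-set label (defaults to `material`).
#' @param inputDnaNg Input DNA mass for the barcode library (ng).
#' @param sequences Optional [Biostrings::QualityScaledDNAStringSet].
#' @return A [BarcodeLibrary-class].
#' @export
barcodeLibrary <- function(barcode, reads, material = "sample",
                           replicateGroup = material, inputDnaNg = 1,
                           sequences = NULL) {
    if (nrow(reads) && !is.null(sequences) &&
        !identical(names(sequences), reads$read_id))
        sequences <- sequences[reads$read_id]
    new("BarcodeLibrary", barcode = as.character(barcode),
        material = material, replicateGroup = as.character(replicateGroup),
        inputDnaNg = inputDnaNg, reads = reads, sequences = sequences,
        stats = list())
}

#' Read a demultiplexed FASTQ file into a BarcodeLibrary
#'
#' Reads a per-barcode FASTQ (gzip-transparent), computing each read's
#' length and mean Phred quality ([meanReadQuality()]).
#'
#' @inheritParams barcodeLibrary
#' @param path FASTQ file.
#' @param keepSequences Retain sequences/qualities (default `TRUE`); with
#'   `FALSE` only read metadata is kept, which is all the quantitation
#'   pipeline needs.
#' @return A [BarcodeLibrary-class].
#' @export
readFastqLibrary <- function(path, barcode, material = "sample",
                             replicateGroup = material, inputDnaNg = 1,
                             keepSequences = TRUE) {
    # Biostrings warns about dropping the mcols it itself attaches while
    # reading FASTQ; that metadata is never used here
    seqs <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {
            if (grepl("metadata columns.*dropped", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    qint <- as(Biostrings::quality(seqs), "IntegerList")
    meanq <- vapply(qint, function(q)
        if (length(q)) meanReadQuality(q) else 0, numeric(1))
    reads <- data.frame(read_id = names(seqs),
                        length = Biostrings::width(seqs),
                        mean_quality = meanq, stringsAsFactors = FALSE)
    barcodeLibrary(barcode, reads, material, replicateGroup, inputDnaNg,
                   sequences = if (keepSequences) seqs else NULL)
}

#' Write a BarcodeLibrary to FASTQ
#'
#' @param lib A [BarcodeLibrary-class] holding sequences.
#' @param path Output FASTQ path (`.gz` for compressed output).
#' @return Invisibly, `path`.
#' @export
writeFastqLibrary <- function(lib, path) {
    if (is.null(lib@sequences))
        stop("library holds no sequences", call. = FALSE)
    # emitted record-by-record: the stock FASTQ serializer is limited to
    # ~20 kb records, well short of real long-read lengths
    dna <- as.character(as(lib@sequences, "DNAStringSet"))
    qual <- as.character(Biostrings::quality(lib@sequences))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", names(dna), "\n", unname(dna), "\n+\n",
                      unname(qual)), con)
    invisible(path)
}

.subsetLibrary <- function(lib, idx, stage, statsExtra = list()) {
    kept <- lib@reads[idx, , drop = FALSE]
    rownames(kept) <- NULL
    st <- lib@stats
    st[[stage]] <- c(list(
        reads_in = nrow(lib@reads),
        reads_out = nrow(kept),
        bases_in = sum(as.numeric(lib@reads$length)),
        bases_out = sum(as.numeric(kept$length))), statsExtra)
    new("BarcodeLibrary", barcode = lib@barcode, material = lib@material,
        replicateGroup = lib@replicateGroup, inputDnaNg = lib@inputDnaNg,
        reads = kept,
        sequences = if (is.null(lib@sequences)) NULL else lib@sequences[idx],
        stats = st)
}

#' Quality/length filter a read library
#'
#' Removes reads with mean quality strictly below `minQuality` or length
#' strictly below `minLength` (defaults Q 7 and 200 bp, the real-time
#' long-read filters); boundary values are kept. Kept/dropped read and base
#' counts are recorded in [filterStats()] under `"filter"`.
#'
#' @param lib A [BarcodeLibrary-class].
#' @param minQuality Minimum mean Phred quality retained (default 7).
#' @param minLength Minimum read length retained (default 200 bp).
#' @return The filtered [BarcodeLibrary-class]. Idempotent.
#' @export
filterReads <- function(lib, minQuality = 7, minLength = 200) {
    keep <- lib@reads$mean_quality >= minQuality &
        lib@reads$length >= minLength
    keep[is.na(keep)] <- FALSE
    .subsetLibrary(lib, which(keep), "filter",
                   list(min_quality = minQuality, min_length = minLength))
}

#' Randomly subsample a library to a target number of bases
#'
#' Reads are shuffled by a seeded RNG and taken in order until the
#' cumulative base count reaches `targetBases`; the read that crosses the
#' target is included (so the subsample holds between `targetBases` and
#' `targetBases + max read length - 1` bases). If the library holds at most
#' `targetBases` bases it is returned unchanged. Deterministic for a given
#' seed; the session RNG state is left untouched.
#'
#' @param lib A [BarcodeLibrary-class].
#' @param targetBases Target cumulative bases (> 0).
#' @param seed Integer seed (default 42).
#' @return The subsampled [BarcodeLibrary-class].
#' @export
subsampleToBases <- function(lib, targetBases, seed = 42) {
    .assertScalarNumber(targetBases, "targetBases", positive = TRUE)
    tot <- totalBases(lib)
    if (tot <= targetBases) return(lib)
    perm <- .withSeed(seed, sample.int(nrow(lib@reads)))
    cum <- cumsum(as.numeric(lib@reads$length[perm]))
    k <- which(cum >= targetBases)[1L]
    idx <- sort(perm[seq_len(k)])
    .subsetLibrary(lib, idx, "subsample",
                   list(target_bases = targetBases, seed = seed))
}

#' Per-stage read/base accounting for a set of libraries
#'
#' @param libs List of [BarcodeLibrary-class] objects.
#' @return Long data.frame: barcode, stage, reads_in, reads_out, bases_in,
#'   bases_out.
#' @export
libraryAccounting <- function(libs) {
    do.call(rbind, lapply(libs, function(l) {
        if (!length(l@stats)) return(NULL)
        do.call(rbind, lapply(names(l@stats), function(stage) {
            s <- l@stats[[stage]]
            data.frame(barcode = l@barcode, stage = stage,
                       reads_in = s$reads_in, reads_out = s$reads_out,
                       bases_in = s$bases_in, bases_out = s$bases_out,
                       stringsAsFactors = FALSE)
        }))
    }))
}
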