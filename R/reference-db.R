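#' @include AllClasses.R AllGenerics.R
NULL

#' Parse a taxonomy string into the seven canonical ranks
#'
#' Accepts GTDB-style strings (`d__Bacteria;p__...;s__Genus species`) or
#' plain semicolon-separated rank lists. Missing or empty ranks are allowed
#' and returned as `""`; rank prefixes (`d__`, `p__`, ...) are stripped.
#'
#' @param x Character vector of taxonomy strings.
#' @return data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`, one row per input string.
#' @examples
#' parseTaxonomy("d__Bacteria;p__Bacillota;c__Bacilli;o__Lactobacillales;f__Listeriaceae;g__Listeria;s__Listeria monocytogenes")
#' @export
parseTaxonomy <- function(x) {
    if (length(x) == 0L) {
        out <- as.data.frame(stats::setNames(
            rep(list(character(0)), length(.TAX_RANKS)), .TAX_RANKS))
        return(out)
    }
    parts <- strsplit(as.character(x), ";", fixed = TRUE)
    parts[lengths(parts) == 0L] <- list("")
    out <- do.call(rbind, lapply(parts, function(p) {
        p <- trimws(p)
        p <- sub("^[dpcofgs]__", "", p)
        length(p) <- length(.TAX_RANKS)
        p[is.na(p)] <- ""
        p
    }))
    out <- as.data.frame(out, stringsAsFactors = FALSE)
    names(out) <- .TAX_RANKS
    out
}

.formatTaxonomy <- function(taxdf) {
    pre <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
    apply(taxdf[, .TAX_RANKS, drop = FALSE], 1L, function(r)
        paste0(pre, r, collapse = ";"))
}

# Build a ReferenceDB from parallel vectors; shared by the loader and the
# simulator.
.makeReferenceDB <- function(genome_id, contig_id, contig_genome,
                             contig_length, taxonomy, role,
                             sequences = NULL) {
    taxdf <- parseTaxonomy(taxonomy)
    ord <- order(match(contig_genome, genome_id))
    contig_id <- contig_id[ord]
    contig_genome <- contig_genome[ord]
    contig_length <- contig_length[ord]
    offset <- unlist(lapply(split(contig_length, factor(contig_genome,
                                                        levels = genome_id)),
                            function(l) cumsum(c(0, l))[seq_along(l)]),
                     use.names = FALSE)
    glen <- vapply(split(contig_length, factor(contig_genome,
                                               levels = genome_id)),
                   sum, numeric(1))
    genomes <- data.frame(genome_id = genome_id,
                          length = as.numeric(glen[genome_id]),
                          role = role, taxdf,
                          stringsAsFactors = FALSE, row.names = NULL)
    contigs <- data.frame(contig_id = contig_id, genome_id = contig_genome,
                          length = as.numeric(contig_length),
                          offset = as.numeric(offset),
                          stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(sequences) && length(sequences))
        sequences <- sequences[contigs$contig_id]
    new("ReferenceDB", genomes = genomes, contigs = contigs,
        sequences = sequences)
}

#' Load a reference genome database from a manifest
#'
#' The manifest is a TSV with columns `genome_id`, `fasta_path` (relative to
#' the manifest's directory or absolute), `contig_ids` (comma-separated list
#' in concatenation order, or `"*"` for all contigs of the FASTA in file
#' order), `taxonomy` (semicolon seven-rank string), and `role`
#' (`spike_in` or `sample_reference`). A genome's length is the sum of its
#' contig lengths, so draft assemblies (MAGs) are handled the same way as
#' complete genomes.
#'
#' @param manifestPath Path to the manifest TSV.
#' @param keepSequences Retain contig sequences in the returned object
#'   (needed by [writeReferenceManifest()] and read simulation from real
#'   genomes). Default `TRUE`.
#' @return A [ReferenceDB-class] object.
#' @details Duplicate genome ids and FASTA contigs not claimed by any
#'   manifest row are hard errors (the latter names the offending contig),
#'   so silent truncation of a database cannot happen. An empty manifest
#'   yields an empty database with a warning.
#' @seealso [writeReferenceManifest()], [loadSpikeInTruth()]
#' @export
loadReferenceManifest <- function(manifestPath, keepSequences = TRUE) {
    if (!file.exists(manifestPath))
        stop("manifest not found: ", manifestPath, call. = FALSE)
    man <- .readTsv(manifestPath)
    need <- c("genome_id", "fasta_path", "contig_ids", "taxonomy", "role")
    if (!all(need %in% names(man)))
        stop("manifest must have columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (nrow(man) == 0L) {
        warning("empty manifest: returning an empty ReferenceDB")
        return(.makeReferenceDB(character(), character(), character(),
                                numeric(), character(), character(),
                                if (keepSequences) Biostrings::DNAStringSet()))
    }
    if (anyDuplicated(man$genome_id))
        stop("duplicate genome_id in manifest: ",
             paste(unique(man$genome_id[duplicated(man$genome_id)]),
                   collapse = ", "), call. = FALSE)
    base <- dirname(normalizePath(manifestPath))
    fpaths <- ifelse(grepl("^(/|[A-Za-z]:)", man$fasta_path),
                     man$fasta_path, file.path(base, man$fasta_path))
    seqs_by_file <- lapply(unique(fpaths), function(fp) {
        if (!file.exists(fp)) stop("FASTA not found: ", fp, call. = FALSE)
        s <- Biostrings::readDNAStringSet(fp)
        names(s) <- sub("\\s.*$", "", names(s))
        s
    })
    names(seqs_by_file) <- unique(fpaths)

    contig_id <- character(); contig_genome <- character()
    contig_length <- numeric(); allseq <- NULL
    claimed <- stats::setNames(vector("list", length(seqs_by_file)),
                               names(seqs_by_file))
    for (i in seq_len(nrow(man))) {
        s <- seqs_by_file[[fpaths[i]]]
        ids <- trimws(strsplit(man$contig_ids[i], ",", fixed = TRUE)[[1]])
        if (length(ids) == 1L && ids == "*") ids <- names(s)
        missing <- setdiff(ids, names(s))
        if (length(missing))
            stop("contig(s) listed for genome '", man$genome_id[i],
                 "' not present in FASTA: ", paste(missing, collapse = ", "),
                 call. = FALSE)
        claimed[[fpaths[i]]] <- c(claimed[[fpaths[i]]], ids)
        contig_id <- c(contig_id, ids)
        contig_genome <- c(contig_genome, rep(man$genome_id[i], length(ids)))
        contig_length <- c(contig_length, Biostrings::width(s[ids]))
        if (keepSequences)
            allseq <- if (is.null(allseq)) s[ids] else c(allseq, s[ids])
    }
    for (fp in names(seqs_by_file)) {
        orphan <- setdiff(names(seqs_by_file[[fp]]), claimed[[fp]])
        if (length(orphan))
            stop("contig(s) present in FASTA '", fp,
                 "' but absent from manifest: ",
                 paste(orphan, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(contig_id))
        stop("contig id claimed by more than one genome: ",
             paste(unique(contig_id[duplicated(contig_id)]), collapse = ", "),
             call. = FALSE)
    .makeReferenceDB(man$genome_id, contig_id, contig_genome, contig_length,
                     man$taxonomy, man$role, allseq)
}

#' Write a ReferenceDB back to FASTA + manifest
#'
#' Writes `genomes.fasta` and `manifest.tsv` under `dir`; reloading the
#' manifest with [loadReferenceManifest()] reproduces the database
#' (round-trip identity). Requires sequences to have been retained.
#'
#' @param db A [ReferenceDB-class] with sequences.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeReferenceManifest <- function(db, dir) {
    if (is.null(db@sequences))
        stop("database has no sequences to write; reload with keepSequences = TRUE",
             call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genomes.fasta")
    Biostrings::writeXStringSet(db@sequences, fa)
    ct <- db@contigs
    cid <- vapply(split(ct$contig_id,
                        factor(ct$genome_id, levels = db@genomes$genome_id)),
                  paste, character(1), collapse = ",")
    man <- data.frame(genome_id = db@genomes$genome_id,
                      fasta_path = "genomes.fasta",
                      contig_ids = cid[db@genomes$genome_id],
                      taxonomy = .formatTaxonomy(db@genomes),
                      role = db@genomes$role,
                      stringsAsFactors = FALSE)
    path <- file.path(dir, "manifest.tsv")
    .writeTsv(man, path)
    invisible(path)
}

#' Load a spike-in truth table
#'
#' Reads the theoretical genome copy number loaded per barcode library for
#' each spike-in genome, and derives theoretical relative abundances
#' (copies over the standard's total).
#'
#' @param path TSV with columns `genome_id`, `theoretical_copies`, or a
#'   data.frame with those columns.
#' @param db Optional [ReferenceDB-class]; when given, every truth genome
#'   must exist in the database (hard error otherwise).
#' @return data.frame with columns `genome_id`, `theoretical_copies`,
#'   `theoretical_rel_abundance` (summing to 1).
#' @export
loadSpikeInTruth <- function(path, db = NULL) {
    truth <- if (is.data.frame(path)) path else .readTsv(path)
    if (!all(c("genome_id", "theoretical_copies") %in% names(truth)))
        stop("truth table needs columns genome_id, theoretical_copies",
             call. = FALSE)
    if (nrow(truth) == 0L) stop("empty spike-in truth table", call. = FALSE)
    if (any(!is.finite(truth$theoretical_copies) |
            truth$theoretical_copies <= 0))
        stop("theoretical_copies must all be > 0", call. = FALSE)
    if (anyDuplicated(truth$genome_id))
        stop("duplicate genome_id in truth table", call. = FALSE)
    if (!is.null(db)) {
        unknown <- setdiff(truth$genome_id, genomeIds(db))
        if (length(unknown))
            stop("truth genome(s) not in reference database: ",
                 paste(unknown, collapse = ", "), call. = FALSE)
    }
    truth$theoretical_rel_abundance <-
        truth$theoretical_copies / sum(truth$theoretical_copies)
    truth[, c("genome_id", "theoretical_copies",
              "theoretical_rel_abundance")]
}
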