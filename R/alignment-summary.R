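#' @include AllClasses.R AllGenerics.R
NULL

.PAF_CORE <- c("query_name", "query_length", "query_start", "query_end",
               "strand", "target_name", "target_length", "target_start",
               "target_end", "n_matches", "alignment_length", "mapq")

#' Read a PAF alignment file
#'
#' Parses the 12 core PAF columns plus the `tp:A:` alignment-type tag
#' (P = primary, S = secondary, I = inversion) when present.
#'
#' @param path PAF file (minimap2 dialect; gzip-transparent).
#' @return data.frame with the core columns and `tp` (`NA` when untagged).
#' @export
readPaf <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        out <- as.data.frame(stats::setNames(
            rep(list(character(0)), length(.PAF_CORE)), .PAF_CORE))
        out$tp <- character(0)
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
        stop("malformed PAF line ", which(nf < 12L)[1L],
             ": fewer than 12 fields", call. = FALSE)
    core <- t(vapply(fields, function(f) f[1:12], character(12)))
    out <- data.frame(core, stringsAsFactors = FALSE)
    names(out) <- .PAF_CORE
    numcols <- c("query_length", "query_start", "query_end", "target_length",
                 "target_start", "target_end", "n_matches",
                 "alignment_length", "mapq")
    for (cc in numcols) out[[cc]] <- suppressWarnings(as.numeric(out[[cc]]))
    bad <- which(!stats::complete.cases(out[numcols]))
    if (length(bad))
        stop("malformed PAF line ", bad[1L], ": non-numeric coordinate field",
             call. = FALSE)
    out$tp <- vapply(fields, function(f) {
        tp <- grep("^tp:A:", f[-(1:12)], value = TRUE)
        if (length(tp)) sub("^tp:A:", "", tp[1L]) else NA_character_
    }, character(1))
    out
}

.samToAlignmentTable <- function(path, countSupplementary = FALSE) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    flag <- Rsamtools::scanBamFlag(
        isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = if (countSupplementary) NA else FALSE,
        isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "qname")
    gal <- GenomicAlignments::readGAlignments(bam, param = param)
    data.frame(read_id = S4Vectors::mcols(gal)$qname,
               contig = as.character(GenomicAlignments::seqnames(gal)),
               start = GenomicAlignments::start(gal) - 1,  # to 0-based
               end = as.numeric(GenomicAlignments::end(gal)),
               is_primary = TRUE, stringsAsFactors = FALSE)
}

#' Convert read-to-genome alignments into genome-coordinate records
#'
#' Consumes a PAF file/table or a SAM file, keeps primary alignments only
#' (PAF `tp:A:S` secondaries and SAM 0x100/0x800 records are dropped;
#' untagged PAF lines count as primary), and lifts contig coordinates onto
#' each genome's concatenated coordinate system using the database's contig
#' offsets. Coordinates are 0-based half-open throughout (PAF-native; SAM
#' converted on parse).
#'
#' @param x PAF path, SAM path (extension `.sam`), or a data.frame from
#'   [readPaf()].
#' @param db A [ReferenceDB-class] resolving every target contig.
#' @param barcode Barcode label attached to the records.
#' @param countSupplementary Keep SAM supplementary (0x800) alignments
#'   (default `FALSE`; PAF has no supplementary notion).
#' @return data.frame: `read_id`, `genome_id`, `target_start`, `target_end`
#'   (genome coordinates), `is_primary`, `barcode`.
#' @export
parseAlignments <- function(x, db, barcode, countSupplementary = FALSE) {
    if (is.character(x) && length(x) == 1L &&
        grepl("\\.sam$", x, ignore.case = TRUE)) {
        aln <- .samToAlignmentTable(x, countSupplementary)
    } else {
        paf <- if (is.data.frame(x)) x else readPaf(x)
        keep <- is.na(paf$tp) | paf$tp == "P"
        aln <- data.frame(read_id = paf$query_name[keep],
                          contig = paf$target_name[keep],
                          start = paf$target_start[keep],
                          end = paf$target_end[keep],
                          is_primary = TRUE, stringsAsFactors = FALSE)
    }
    ct <- contigMap(db)
    m <- match(aln$contig, ct$contig_id)
    if (anyNA(m)) {
        unknown <- unique(aln$contig[is.na(m)])
        stop("alignment to contig(s) absent from the reference database: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- which(aln$start < 0 | aln$end <= aln$start |
                 aln$end > ct$length[m])
    if (length(bad))
        stop("alignment interval outside contig bounds at record ", bad[1L],
             call. = FALSE)
    out <- data.frame(read_id = aln$read_id,
                      genome_id = ct$genome_id[m],
                      target_start = aln$start + ct$offset[m],
                      target_end = aln$end + ct$offset[m],
                      is_primary = aln$is_primary,
                      barcode = barcode, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Genome-wide coverage summary for one barcode
#'
#' For every genome in the database (zero rows included for genomes without
#' alignments): mapped bases (sum of primary alignment target spans),
#' covered bases (size of the interval union, computed by interval merging),
#' coverage fraction (covered / genome length — the detection statistic),
#' and depth (mapped / genome length). Input order of alignments is
#' irrelevant.
#'
#' @param alignments data.frame from [parseAlignments()] (or the simulator's
#'   truth alignments); only rows with `is_primary` count.
#' @param db A [ReferenceDB-class].
#' @param barcode Barcode label for the summaries; when `alignments` carries
#'   a `barcode` column, rows are restricted to this barcode.
#' @return data.frame: `genome_id`, `barcode`, `mapped_bases`,
#'   `covered_bases`, `genome_length`, `coverage_fraction`, `depth`.
#' @export
summarizeCoverage <- function(alignments, db, barcode) {
    glen <- genomeLengths(db)
    if (!is.null(alignments$barcode))
        alignments <- alignments[alignments$barcode == barcode, , drop = FALSE]
    if (!is.null(alignments$is_primary))
        alignments <- alignments[alignments$is_primary, , drop = FALSE]
    mapped <- covered <- stats::setNames(numeric(length(glen)), names(glen))
    if (nrow(alignments)) {
        unknown <- setdiff(unique(alignments$genome_id), names(glen))
        if (length(unknown))
            stop("alignments reference unknown genome(s): ",
                 paste(unknown, collapse = ", "), call. = FALSE)
        sp <- split(seq_len(nrow(alignments)), alignments$genome_id)
        for (g in names(sp)) {
            s <- alignments$target_start[sp[[g]]]
            e <- alignments$target_end[sp[[g]]]
            mapped[g] <- sum(e - s)
            # 0-based half-open -> 1-based closed for IRanges
            covered[g] <- sum(IRanges::width(IRanges::reduce(
                IRanges::IRanges(start = s + 1, end = e))))
        }
    }
    data.frame(genome_id = names(glen), barcode = barcode,
               mapped_bases = as.numeric(mapped),
               covered_bases = as.numeric(covered),
               genome_length = as.numeric(glen),
               coverage_fraction = as.numeric(covered / glen),
               depth = as.numeric(mapped / glen),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a truth/alignment table as PAF
#'
#' Emits one primary full-span PAF record per alignment row (used by the
#' simulator's truth output).
#'
#' @param alignments data.frame with `read_id`, `genome_id` (single-contig
#'   target naming), `target_start`, `target_end`, optional `strand`.
#' @param db [ReferenceDB-class] supplying target lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePaf <- function(alignments, db, path) {
    glen <- genomeLengths(db)
    span <- alignments$target_end - alignments$target_start
    strand <- if (is.null(alignments$strand)) "+" else alignments$strand
    lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:P",
                     alignments$read_id, as.integer(span), 0L,
                     as.integer(span), strand, alignments$genome_id,
                     as.integer(glen[alignments$genome_id]),
                     as.integer(alignments$target_start),
                     as.integer(alignments$target_end),
                     as.integer(span), as.integer(span), 60L)
    writeLines(lines, path)
    invisible(path)
}
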