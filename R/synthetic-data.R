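#' @include AllClasses.R AllGenerics.R
NULL

# Approximate mass of one base pair of dsDNA in ng (650 g/mol / Avogadro).
.NG_PER_BP <- 1.08e-12

#' Specify a mock community
#'
#' A community is a table of taxa with genome lengths and theoretical genome
#' copy numbers per barcode library. Helpers build the two canonical shapes:
#' a log-distributed standard (abundances spanning several decades, one
#' dominant taxon) and an even standard.
#'
#' @param genomeId Character vector of genome ids.
#' @param genomeLength Genome lengths (bp, >= 1).
#' @param copies Theoretical genome copies per library (> 0).
#' @param gc Per-genome GC content in (0, 1) (default 0.5).
#' @param taxonomy Optional semicolon taxonomy strings; autogenerated
#'   (one genus per genome) when omitted.
#' @return data.frame with columns `genome_id`, `length`, `copies`, `gc`,
#'   `taxonomy`.
#' @export
communitySpec <- function(genomeId, genomeLength, copies, gc = 0.5,
                          taxonomy = NULL) {
    if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
    if (any(genomeLength < 1)) stop("genome lengths must be >= 1",
                                    call. = FALSE)
    if (any(gc <= 0 | gc >= 1)) stop("gc must be in (0, 1)", call. = FALSE)
    if (is.null(taxonomy))
        taxonomy <- sprintf(
            "d__Bacteria;p__p_%s;c__c_%s;o__o_%s;f__f_%s;g__g_%s;s__s_%s",
            genomeId, genomeId, genomeId, genomeId, genomeId, genomeId)
    data.frame(genome_id = as.character(genomeId),
               length = as.numeric(genomeLength),
               copies = as.numeric(copies),
               gc = rep_len(as.numeric(gc), length(genomeId)),
               taxonomy = taxonomy, stringsAsFactors = FALSE)
}

#' @rdname communitySpec
#' @param nTaxa Number of taxa.
#' @param decades Abundance span in log10 decades (>= 3 for a
#'   log-distributed standard).
#' @param topCopies Copies of the most abundant taxon.
#' @param prefix Genome-id prefix.
#' @export
logDistributedCommunity <- function(nTaxa = 8, decades = 4,
                                    topCopies = 1e6,
                                    genomeLength = 1e5, prefix = "logsp") {
    if (decades < 3)
        stop("a log-distributed community must span >= 3 decades",
             call. = FALSE)
    copies <- topCopies * 10^(-seq(0, decades, length.out = nTaxa))
    communitySpec(sprintf("%s%02d", prefix, seq_len(nTaxa)),
                  rep_len(genomeLength, nTaxa), copies)
}

#' @rdname communitySpec
#' @export
evenCommunity <- function(nTaxa = 10, topCopies = 1e5, genomeLength = 1e5,
                          prefix = "evensp") {
    communitySpec(sprintf("%s%02d", prefix, seq_len(nTaxa)),
                  rep_len(genomeLength, nTaxa), rep(topCopies, nTaxa))
}

#' Total DNA mass of a community (ng)
#'
#' `sum(copies * length) * 1.08e-12` — the mass one barcode library of this
#' community would contribute, used as the default `input_dna_ng`.
#'
#' @param community A [communitySpec()] table.
#' @return Mass in ng.
#' @export
communityMassNg <- function(community) {
    sum(community$copies * community$length) * .NG_PER_BP
}

#' Specify a simulated sequencing run
#'
#' Captures the per-barcode design (material, replicate group, input DNA,
#' ligation-efficiency/throughput multiplier) and the read model: lognormal
#' read lengths (defaults echo a long-read run with N50 around 3.8 kb), an
#' optional uniform-substitution error rate (affects emitted sequences
#' only), and optional per-taxon multiplicative extraction bias.
#'
#' @param barcodes data.frame with columns `barcode`, `material`
#'   (`spike_in`/`sample`), `replicate_group`, `input_dna_ng` (NA = derive
#'   from the community's mass), `throughput` (> 0 multiplier).
#' @param readLengthMeanLog,readLengthSdLog Lognormal read-length
#'   parameters (natural-log scale).
#' @param errorRate Per-base substitution probability for emitted sequences
#'   (0 = error-free).
#' @param extractionBias Named per-genome multiplicative factors (> 0)
#'   applied to sampling weights; unnamed genomes get 1.
#' @param qualityMean,qualitySd Per-read mean-quality model (Phred).
#' @return List of class `bsinc_run`.
#' @export
runSpec <- function(barcodes,
                    readLengthMeanLog = log(3800), readLengthSdLog = 0.6,
                    errorRate = 0, extractionBias = NULL,
                    qualityMean = 12, qualitySd = 2) {
    need <- c("barcode", "material", "replicate_group", "input_dna_ng",
              "throughput")
    if (!all(need %in% names(barcodes)))
        stop("barcodes needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (any(barcodes$throughput <= 0))
        stop("throughput multipliers must be > 0", call. = FALSE)
    if (!is.null(extractionBias) && any(extractionBias <= 0))
        stop("extraction bias factors must be > 0", call. = FALSE)
    structure(list(barcodes = barcodes,
                   readLengthMeanLog = readLengthMeanLog,
                   readLengthSdLog = readLengthSdLog,
                   errorRate = errorRate, extractionBias = extractionBias,
                   qualityMean = qualityMean, qualitySd = qualitySd),
              class = "bsinc_run")
}

#' Convenience run design: replicate spike-in and sample barcodes
#'
#' @param nSpike,nSample Replicate counts (>= 2 recommended).
#' @param spikeThroughput,sampleThroughput Per-barcode throughput
#'   multipliers (recycled).
#' @param ... Passed to [runSpec()].
#' @return A `bsinc_run`.
#' @export
standardRunDesign <- function(nSpike = 3, nSample = 3,
                              spikeThroughput = 1, sampleThroughput = 1,
                              ...) {
    barcodes <- data.frame(
        barcode = c(sprintf("BC%02d", seq_len(nSpike)),
                    sprintf("BC%02d", nSpike + seq_len(nSample))),
        material = c(rep("spike_in", nSpike), rep("sample", nSample)),
        replicate_group = c(rep("spike", nSpike), rep("sample", nSample)),
        input_dna_ng = NA_real_,
        throughput = c(rep_len(spikeThroughput, nSpike),
                       rep_len(sampleThroughput, nSample)),
        stringsAsFactors = FALSE)
    runSpec(barcodes, ...)
}

#' Simulate reference genomes for one or more communities
#'
#' Draws i.i.d. nucleotide sequences at each genome's GC content
#' (deterministic per seed) and assembles a [ReferenceDB-class]; optionally
#' writes FASTA + manifest.
#'
#' @param community A [communitySpec()] table, or a named list of them.
#' @param seed Integer seed.
#' @param role Role per community (`spike_in`/`sample_reference`), recycled
#'   over the list.
#' @param dir Optional output directory for FASTA + manifest.
#' @param emitSequences Generate sequences (default `TRUE`); with `FALSE`
#'   the database carries lengths/taxonomy only, which suffices for
#'   truth-alignment workflows.
#' @return A [ReferenceDB-class].
#' @export
simulateGenomes <- function(community, seed = 42, role = "sample_reference",
                            dir = NULL, emitSequences = TRUE) {
    comms <- if (is.data.frame(community)) list(community) else community
    role <- rep_len(role, length(comms))
    comm <- do.call(rbind, comms)
    rolev <- rep(role, vapply(comms, nrow, integer(1)))
    if (anyDuplicated(comm$genome_id))
        stop("duplicate genome_id across communities", call. = FALSE)
    seqs <- NULL
    if (emitSequences) {
        seqs <- .withSeed(seed, {
            s <- lapply(seq_len(nrow(comm)), function(i) {
                gc <- comm$gc[i]
                paste(sample(c("A", "C", "G", "T"), comm$length[i],
                             replace = TRUE,
                             prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                      (1 - gc) / 2)),
                      collapse = "")
            })
            Biostrings::DNAStringSet(stats::setNames(unlist(s),
                                                     comm$genome_id))
        })
    }
    db <- .makeReferenceDB(comm$genome_id, comm$genome_id, comm$genome_id,
                           comm$length, comm$taxonomy, rolev, seqs)
    if (!is.null(dir)) writeReferenceManifest(db, dir)
    db
}

# Sampling weights: theoretical copies x genome length x extraction bias.
.communityWeights <- function(community, extractionBias = NULL) {
    w <- community$copies * community$length
    if (!is.null(extractionBias)) {
        b <- extractionBias[community$genome_id]
        b[is.na(b)] <- 1
        w <- w * b
    }
    stats::setNames(w, community$genome_id)
}

#' Simulate one barcode's read library with truth alignments
#'
#' Reads are drawn from the community with probability proportional to
#' `copies * length * bias`; each read starts uniformly on its source
#' genome with a lognormal length truncated to the genome, and its true
#' source interval is emitted as a primary full-span alignment record. The
#' library totals approximately `targetBases * throughput` bases (the read
#' crossing the target is included), emulating ligation-efficiency
#' differences between barcodes. Byte-deterministic per seed.
#'
#' @param community A [communitySpec()] table.
#' @param run A [runSpec()] object.
#' @param barcode Barcode label (must exist in the run design).
#' @param targetBases Nominal per-barcode sequencing effort (bp).
#' @param seed Integer seed.
#' @param db Optional [ReferenceDB-class] with sequences; when supplied,
#'   read sequences are extracted (reverse-complemented on minus-strand
#'   reads, substitution errors applied at the run's `errorRate`) and
#'   attached to the library.
#' @return List: `library` ([BarcodeLibrary-class]), `alignments`
#'   (truth alignment table as from [parseAlignments()], plus `strand`).
#' @export
simulateBarcodeReads <- function(community, run, barcode, targetBases,
                                 seed = 42, db = NULL) {
    bc <- run$barcodes[run$barcodes$barcode == barcode, , drop = FALSE]
    if (nrow(bc) != 1L)
        stop("barcode '", barcode, "' not in run design", call. = FALSE)
    tb <- targetBases * bc$throughput
    w <- .communityWeights(community, run$extractionBias)
    G <- stats::setNames(community$length, community$genome_id)
    .withSeed(seed, {
        meanlen <- exp(run$readLengthMeanLog + run$readLengthSdLog^2 / 2)
        lens <- numeric(0)
        while (sum(lens) < tb) {
            nmore <- max(16L, ceiling((tb - sum(lens)) / meanlen * 1.15))
            lens <- c(lens, pmax(1, round(stats::rlnorm(
                nmore, run$readLengthMeanLog, run$readLengthSdLog))))
        }
        k <- which(cumsum(lens) >= tb)[1L]
        lens <- lens[seq_len(k)]
        gi <- sample.int(length(w), k, replace = TRUE, prob = w)
        gid <- names(w)[gi]
        lens <- pmin(lens, G[gid])
        start <- floor(stats::runif(k) * (G[gid] - lens + 1))
        strand <- ifelse(stats::runif(k) < 0.5, "+", "-")
        meanq <- pmax(0, stats::rnorm(k, run$qualityMean, run$qualitySd))
        read_id <- sprintf("%s_r%07d", barcode, seq_len(k))
        reads <- data.frame(read_id = read_id, length = as.numeric(lens),
                            mean_quality = meanq, stringsAsFactors = FALSE)
        aln <- data.frame(read_id = read_id, genome_id = gid,
                          target_start = as.numeric(start),
                          target_end = as.numeric(start + lens),
                          is_primary = TRUE, barcode = barcode,
                          strand = strand, stringsAsFactors = FALSE,
                          row.names = NULL)
        seqs <- NULL
        if (!is.null(db) && !is.null(db@sequences)) {
            raw <- Biostrings::DNAStringSet(db@sequences[gid],
                                            start = start + 1,
                                            width = lens)
            neg <- strand == "-"
            if (any(neg))
                raw[neg] <- Biostrings::reverseComplement(raw[neg])
            if (run$errorRate > 0) {
                chars <- strsplit(as.character(raw), "")
                mut <- lapply(chars, function(x) {
                    hit <- stats::runif(length(x)) < run$errorRate
                    if (any(hit))
                        x[hit] <- sample(c("A", "C", "G", "T"), sum(hit),
                                         replace = TRUE)
                    paste(x, collapse = "")
                })
                raw <- Biostrings::DNAStringSet(unlist(mut))
            }
            names(raw) <- read_id
            qchar <- vapply(seq_len(k), function(i)
                paste(rep(rawToChar(as.raw(33L + round(meanq[i]))),
                          lens[i]), collapse = ""), character(1))
            seqs <- Biostrings::QualityScaledDNAStringSet(
                raw, Biostrings::PhredQuality(qchar))
        }
        ng <- bc$input_dna_ng
        if (is.na(ng)) ng <- communityMassNg(community)
        list(library = barcodeLibrary(barcode, reads,
                                      material = bc$material,
                                      replicateGroup = bc$replicate_group,
                                      inputDnaNg = ng, sequences = seqs),
             alignments = aln)
    })
}

#' Simulate a complete multiplexed experiment
#'
#' Runs [simulateBarcodeReads()] for every barcode in the design (spike-in
#' barcodes draw from the spike-in community, sample barcodes from the
#' sample community), applies the real-time read filter, restricts truth
#' alignments to the retained reads, and summarizes coverage and BEFs —
#' everything the calibration and quantitation steps consume.
#'
#' @param spike,sample [communitySpec()] tables for the spike-in standard
#'   and the sample community.
#' @param run A [runSpec()] design containing both materials.
#' @param targetBases Nominal per-barcode effort (bp).
#' @param seed Master seed (per-barcode streams derived).
#' @param kappa Yield constant for the BEFs (bp/ng).
#' @param minQuality,minLength Read filter thresholds.
#' @param emitSequences Generate genome and read sequences (slower; only
#'   needed for FASTQ-level tests).
#' @return List: `db`, `truth` (spike-in truth table), `sampleTruth`,
#'   `libraries` (named list), `alignments` (stacked truth alignments of
#'   retained reads), `coverage`, `befs`, `run`, `seed`.
#' @export
simulateExperiment <- function(spike, sample, run = standardRunDesign(),
                               targetBases = 2e7, seed = 42, kappa = 1e7,
                               minQuality = 7, minLength = 200,
                               emitSequences = FALSE) {
    db <- simulateGenomes(list(spike, sample), seed = .deriveSeed(seed, 1),
                          role = c("spike_in", "sample_reference"),
                          emitSequences = emitSequences)
    libs <- list(); alns <- list()
    for (i in seq_len(nrow(run$barcodes))) {
        b <- run$barcodes$barcode[i]
        comm <- if (run$barcodes$material[i] == "spike_in") spike else sample
        sim <- simulateBarcodeReads(comm, run, b, targetBases,
                                    seed = .deriveSeed(seed, 100 + i),
                                    db = if (emitSequences) db else NULL)
        lib <- filterReads(sim$library, minQuality, minLength)
        keep <- sim$alignments$read_id %in% readInfo(lib)$read_id
        libs[[b]] <- lib
        alns[[b]] <- sim$alignments[keep, , drop = FALSE]
    }
    alignments <- do.call(rbind, alns)
    rownames(alignments) <- NULL
    coverage <- do.call(rbind, lapply(names(libs), function(b)
        summarizeCoverage(alignments, db, b)))
    befs <- do.call(rbind, lapply(libs, function(l)
        barcodeEffectFactor(totalBases(l), l@inputDnaNg, kappa, l@barcode)))
    rownames(befs) <- NULL
    truth <- loadSpikeInTruth(data.frame(genome_id = spike$genome_id,
                                         theoretical_copies = spike$copies))
    sampleTruth <- loadSpikeInTruth(data.frame(
        genome_id = sample$genome_id, theoretical_copies = sample$copies))
    list(db = db, truth = truth, sampleTruth = sampleTruth,
         libraries = libs, alignments = alignments, coverage = coverage,
         befs = befs, run = run, seed = seed, kappa = kappa)
}

#' Deterministic expected-coverage experiment
#'
#' The noise-free face of the generator: instead of sampling reads it
#' computes each genome's expected per-barcode coverage analytically. With
#' per-barcode effort `T` and sampling weight share `w_g/W`, the expected
#' depth is `lambda_g = T * (w_g/W) / L_g`; mapped bases are `lambda * L`
#' exactly and covered bases follow the Lander-Waterman expectation
#' `L * (1 - exp(-lambda))`. Per-barcode observed bases (for the BEF) are
#' the summed mapped bases. `coverageFractionOverride` pins named genomes
#' to a chosen coverage fraction (depth `-log(1 - f)`), emulating targeted
#' withholding or extension of sequencing effort for that genome.
#'
#' @inheritParams simulateExperiment
#' @param coverageFractionOverride Named numeric vector (genome ->
#'   coverage fraction in (0, 1)) applied to sample barcodes.
#' @return Same shape as [simulateExperiment()] minus `libraries` and
#'   `alignments`.
#' @export
expectedExperiment <- function(spike, sample, run = standardRunDesign(),
                               targetBases = 2e7, kappa = 1e7,
                               coverageFractionOverride = NULL) {
    db <- simulateGenomes(list(spike, sample), role = c("spike_in",
                                                        "sample_reference"),
                          emitSequences = FALSE)
    cov <- list(); befrows <- list()
    for (i in seq_len(nrow(run$barcodes))) {
        b <- run$barcodes$barcode[i]
        isSpike <- run$barcodes$material[i] == "spike_in"
        comm <- if (isSpike) spike else sample
        tb <- targetBases * run$barcodes$throughput[i]
        w <- .communityWeights(comm, run$extractionBias)
        lambda <- tb * (w / sum(w)) / comm$length
        names(lambda) <- comm$genome_id
        if (!isSpike && !is.null(coverageFractionOverride)) {
            ov <- coverageFractionOverride[names(coverageFractionOverride)
                                           %in% names(lambda)]
            lambda[names(ov)] <- -log(1 - ov)
        }
        mapped <- lambda * comm$length
        covered <- comm$length * (1 - exp(-lambda))
        cc <- data.frame(genome_id = comm$genome_id, barcode = b,
                         mapped_bases = as.numeric(mapped),
                         covered_bases = as.numeric(covered),
                         genome_length = comm$length,
                         coverage_fraction = as.numeric(covered / comm$length),
                         depth = as.numeric(lambda),
                         stringsAsFactors = FALSE)
        # zero rows for the other community's genomes
        other <- setdiff(genomeIds(db), comm$genome_id)
        zz <- data.frame(genome_id = other, barcode = b, mapped_bases = 0,
                         covered_bases = 0,
                         genome_length = genomeLengths(db)[other],
                         coverage_fraction = 0, depth = 0,
                         stringsAsFactors = FALSE)
        cov[[b]] <- rbind(cc, zz)
        ng <- run$barcodes$input_dna_ng[i]
        if (is.na(ng)) ng <- communityMassNg(comm)
        befrows[[b]] <- barcodeEffectFactor(sum(mapped), ng, kappa, b)
    }
    coverage <- do.call(rbind, cov); rownames(coverage) <- NULL
    befs <- do.call(rbind, befrows); rownames(befs) <- NULL
    truth <- loadSpikeInTruth(data.frame(genome_id = spike$genome_id,
                                         theoretical_copies = spike$copies))
    sampleTruth <- loadSpikeInTruth(data.frame(
        genome_id = sample$genome_id, theoretical_copies = sample$copies))
    list(db = db, truth = truth, sampleTruth = sampleTruth,
         coverage = coverage, befs = befs, run = run, kappa = kappa)
}

#' Write machine-readable truth tables for a simulated run
#'
#' Emits `spikein_truth.tsv` (theoretical copies and relative abundances),
#' `sample_truth.tsv`, `run_design.tsv`, and `extraction_bias.tsv` under
#' `dir`.
#'
#' @param spike,sample [communitySpec()] tables.
#' @param run A [runSpec()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
writeTruthTables <- function(spike, sample, run, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("spike", "sample")) {
        comm <- if (nm == "spike") spike else sample
        tt <- data.frame(genome_id = comm$genome_id,
                         theoretical_copies = comm$copies,
                         theoretical_rel_abundance =
                             comm$copies / sum(comm$copies))
        .writeTsv(tt, file.path(dir, paste0(
            if (nm == "spike") "spikein" else "sample", "_truth.tsv")))
    }
    .writeTsv(run$barcodes, file.path(dir, "run_design.tsv"))
    bias <- run$extractionBias
    if (is.null(bias))
        bias <- stats::setNames(rep(1, nrow(spike) + nrow(sample)),
                                c(spike$genome_id, sample$genome_id))
    .writeTsv(data.frame(genome_id = names(bias), bias_factor = bias,
                         row.names = NULL),
              file.path(dir, "extraction_bias.tsv"))
    invisible(dir)
}
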