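# Shared fixture builders and independent oracles.

# Per-base boolean-array oracle for covered bases: independent of the
# interval-merge implementation.
coverageOracleBp <- function(genomeLength, starts, ends) {
    hit <- logical(genomeLength)
    for (i in seq_along(starts))
        if (ends[i] > starts[i])
            hit[(starts[i] + 1):ends[i]] <- TRUE  # 0-based half-open
    sum(hit)
}

# Closed-form OLS oracle (normal equations), independent of lm().
olsOracle <- function(x, y) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    yhat <- intercept + slope * x
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    list(slope = slope, intercept = intercept, r2 = r2)
}

# Write a FASTA file from a named character vector of sequences.
writeFastaFixture <- function(seqs, path) {
    con <- file(path, "w")
    for (nm in names(seqs)) {
        writeLines(paste0(">", nm), con)
        writeLines(seqs[[nm]], con)
    }
    close(con)
    path
}

# Two-genome fixture database: g1 single contig (1000 bp), g2 two contigs
# (1200 + 800 bp). Returns the manifest path.
tinyManifestFixture <- function(dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(11)
    mkseq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
    writeFastaFixture(c(c1 = mkseq(1000), c2a = mkseq(1200),
                        c2b = mkseq(800)),
                      file.path(dir, "ref.fasta"))
    man <- data.frame(
        genome_id = c("g1", "g2"),
        fasta_path = "ref.fasta",
        contig_ids = c("c1", "c2a,c2b"),
        taxonomy = c("d__Bacteria;p__P1;c__C1;o__O1;f__F1;g__GenusA;s__GenusA sp1",
                     "d__Bacteria;p__P1;c__C1;o__O1;f__F1;g__GenusA;s__GenusA sp2"),
        role = c("spike_in", "sample_reference"),
        stringsAsFactors = FALSE)
    path <- file.path(dir, "manifest.tsv")
    write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# A BarcodeLibrary of n reads with given lengths/qualities.
libFixture <- function(lengths, qualities = 12, barcode = "BC01", ...) {
    n <- length(lengths)
    barcodeLibrary(barcode,
                   data.frame(read_id = sprintf("%s_r%03d", barcode,
                                                seq_len(n)),
                              length = lengths,
                              mean_quality = rep_len(qualities, n),
                              stringsAsFactors = FALSE), ...)
}

# A PAF line with optional tag field.
pafLine <- function(q, qlen, tname, tlen, tstart, tend, tag = "tp:A:P") {
    paste(q, qlen, 0, qlen, "+", tname, tlen, tstart, tend,
          tend - tstart, tend - tstart, 60, tag, sep = "\t")
}

# Small but fully resolvable simulated experiment: spike-in genomes over
# ~2.5 decades, even sample community, per-barcode throughput multipliers.
smallExperiment <- function(seed = 1, targetBases = 2e7,
                            spikeThroughput = c(0.5, 1, 2),
                            sampleThroughput = c(2, 1, 0.5),
                            extractionBias = NULL, ...) {
    spike <- communitySpec(sprintf("sp%02d", 1:6), rep(5e4, 6),
                           1e5 * 10^-seq(0, 2.5, length.out = 6))
    samp <- evenCommunity(nTaxa = 5, topCopies = 2e4, genomeLength = 5e4)
    run <- standardRunDesign(spikeThroughput = spikeThroughput,
                             sampleThroughput = sampleThroughput,
                             extractionBias = extractionBias)
    sim <- simulateExperiment(spike, samp, run, targetBases, seed = seed,
                              ...)
    sim$spikeCommunity <- spike
    sim$sampleCommunity <- samp
    sim
}

# Study conditions for the single- vs multi-taxon spike-in comparison: a
# log-distributed spike-in whose rarest member ("rare") sits just above the
# detection limit (expected depth ~0.3x at the default effort) while the
# sample community is even and abundant; mild per-taxon lognormal
# extraction bias (sd 0.05 in log10).
.mismatchedSpikeSim <- function(seed, targetBases = 4e7) {
    spike <- communitySpec(
        c(sprintf("spk%02d", 1:5), "rare"),
        c(rep(1e5, 5), 1e6),
        c(5e5, 1.5e5, 5e4, 1.5e4, 5e3, 544))
    samp <- evenCommunity(nTaxa = 8, topCopies = 2e4, genomeLength = 1e5)
    set.seed(seed)
    bias <- 10^rnorm(nrow(spike) + nrow(samp), 0, 0.05)
    names(bias) <- c(spike$genome_id, samp$genome_id)
    run <- standardRunDesign(extractionBias = bias)
    sim <- simulateExperiment(spike, samp, run, targetBases, seed = seed)
    sim$spikeCommunity <- spike
    sim$sampleCommunity <- samp
    sim
}

.multiVsSingleDeviation <- function(sim) {
    cmp <- compareSpikeInStrategies(sim, "rare")
    cmp$median_deviation_pct
}
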