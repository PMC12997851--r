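dbFixture <- function() {
    man <- tinyManifestFixture(
        withr::local_tempdir(.local_envir = parent.frame()))
    loadReferenceManifest(man, keepSequences = FALSE)
}

test_that("PAF parsing keeps primaries and lifts contig coordinates", {
    db <- dbFixture()
    paf <- c(pafLine("r1", 100, "c1", 1000, 10, 110),           # primary
             pafLine("r2", 100, "c1", 1000, 300, 400, "tp:A:S"),# secondary
             pafLine("r3", 150, "c2b", 800, 0, 150),            # offset 1200
             pafLine("r4", 80, "c2a", 1200, 100, 180, "NM:i:3"))# untagged
    path <- withr::local_tempfile(lines = paf, fileext = ".paf")
    aln <- parseAlignments(path, db, "BC01")
    expect_equal(aln$read_id, c("r1", "r3", "r4"))
    expect_equal(aln$genome_id, c("g1", "g2", "g2"))
    expect_equal(aln$target_start, c(10, 1200, 100))
    expect_equal(aln$target_end, c(110, 1350, 180))
    expect_true(all(aln$barcode == "BC01"))

    bad <- withr::local_tempfile(lines = c(paf[1], "r9\t100\tbroken"),
                                 fileext = ".paf")
    expect_error(readPaf(bad), "line 2")
    unknown <- withr::local_tempfile(
        lines = pafLine("r1", 50, "cX", 500, 0, 50), fileext = ".paf")
    expect_error(parseAlignments(unknown, db, "BC01"), "cX")
})

test_that("SAM parsing honors flags and CIGAR reference spans", {
    db <- dbFixture()
    samRec <- function(qname, flag, rname, pos, cigar)
        paste(qname, flag, rname, pos, 60, cigar, "*", 0, 0, "*", "*",
              sep = "\t")
    sam <- c("@HD\tVN:1.6\tSO:unknown",
             "@SQ\tSN:c1\tLN:1000", "@SQ\tSN:c2a\tLN:1200",
             "@SQ\tSN:c2b\tLN:800",
             samRec("r1", 0, "c1", 11, "100M"),        # [10,110)
             samRec("r2", 256, "c1", 301, "100M"),     # secondary: dropped
             samRec("r3", 2048, "c1", 501, "50M"),     # supplementary
             samRec("r4", 16, "c2b", 1, "50M10D40M"),  # span 100, offset 1200
             samRec("r5", 0, "c2a", 21, "10S80M5S"))   # clips don't count
    path <- withr::local_tempfile(lines = sam, fileext = ".sam")
    aln <- parseAlignments(path, db, "BC02")
    expect_setequal(aln$read_id, c("r1", "r4", "r5"))
    expect_equal(aln[aln$read_id == "r1", c("target_start", "target_end")],
                 data.frame(target_start = 10, target_end = 110,
                            row.names = 1L))
    r4 <- aln[aln$read_id == "r4", ]
    expect_equal(r4$genome_id, "g2")
    expect_equal(r4$target_end - r4$target_start, 100)  # deletions included
    expect_equal(r4$target_start, 1200)
    r5 <- aln[aln$read_id == "r5", ]
    expect_equal(r5$target_end - r5$target_start, 80)   # soft clips excluded
    # supplementary records included on request
    alnSupp <- parseAlignments(path, db, "BC02", countSupplementary = TRUE)
    expect_setequal(alnSupp$read_id, c("r1", "r3", "r4", "r5"))
})

test_that("coverage summaries compute mapped/covered bases and include zero rows", {
    db <- dbFixture()
    mk <- function(...) {
        m <- rbind(...)
        data.frame(read_id = sprintf("r%d", seq_len(nrow(m))),
                   genome_id = m[, 1], target_start = as.numeric(m[, 2]),
                   target_end = as.numeric(m[, 3]), is_primary = TRUE,
                   barcode = "BC01", stringsAsFactors = FALSE)
    }
    cov <- summarizeCoverage(mk(c("g1", 0, 100)), db, "BC01")
    g1 <- cov[cov$genome_id == "g1", ]
    expect_equal(g1$mapped_bases, 100)
    expect_equal(g1$covered_bases, 100)
    expect_equal(g1$coverage_fraction, 0.10)
    expect_equal(g1$depth, 0.10)
    # zero row for the unaligned genome
    expect_equal(cov[cov$genome_id == "g2", ]$mapped_bases, 0)
    expect_equal(cov[cov$genome_id == "g2", ]$coverage_fraction, 0)

    cov2 <- summarizeCoverage(mk(c("g1", 0, 100), c("g1", 50, 150)),
                              db, "BC01")
    g1 <- cov2[cov2$genome_id == "g1", ]
    expect_equal(g1$mapped_bases, 200)
    expect_equal(g1$covered_bases, 150)

    covEmpty <- summarizeCoverage(mk(c("g1", 0, 100))[0, ], db, "BC01")
    expect_equal(covEmpty$mapped_bases, c(0, 0))
})

test_that("interval-union covered bases equal the per-base boolean oracle", {
    set.seed(33)
    db1 <- simulateGenomes(communitySpec("gg", 10000, 1),
                           emitSequences = FALSE)
    for (i in 1:30) {
        n <- sample(1:120, 1)
        start <- sample(0:9999, n, replace = TRUE)
        len <- sample(1:600, n, replace = TRUE)
        end <- pmin(start + len, 10000)
        ok <- end > start
        aln <- data.frame(read_id = sprintf("r%d", seq_len(sum(ok))),
                          genome_id = "gg", target_start = start[ok],
                          target_end = end[ok], is_primary = TRUE,
                          barcode = "b", stringsAsFactors = FALSE)
        cov <- summarizeCoverage(aln, db1, "b")
        expect_equal(cov$covered_bases,
                     coverageOracleBp(10000, start[ok], end[ok]))
        expect_equal(cov$mapped_bases, sum(end[ok] - start[ok]))
        # permutation invariance
        perm <- aln[sample(nrow(aln)), ]
        expect_equal(summarizeCoverage(perm, db1, "b"), cov)
    }
})

test_that("adding alignments never decreases coverage statistics", {
    set.seed(44)
    db1 <- simulateGenomes(communitySpec("gg", 10000, 1),
                           emitSequences = FALSE)
    start <- sample(0:9500, 80, replace = TRUE)
    end <- start + sample(50:500, 80, replace = TRUE)
    end <- pmin(end, 10000)
    aln <- data.frame(read_id = sprintf("r%d", 1:80), genome_id = "gg",
                      target_start = start, target_end = end,
                      is_primary = TRUE, barcode = "b",
                      stringsAsFactors = FALSE)
    prev <- c(0, 0, 0)
    for (k in c(5, 20, 40, 80)) {
        cov <- summarizeCoverage(aln[1:k, ], db1, "b")
        cur <- c(cov$mapped_bases, cov$covered_bases,
                 cov$coverage_fraction)
        expect_true(all(cur >= prev))
        prev <- cur
    }
})

test_that("truth-alignment PAF round-trips through the parser", {
    sim <- smallExperiment(seed = 6, targetBases = 2e6)
    db <- sim$db
    b <- names(sim$libraries)[1]
    aln <- sim$alignments[sim$alignments$barcode == b, ]
    path <- file.path(withr::local_tempdir(), "truth.paf")
    writePaf(aln, db, path)
    back <- parseAlignments(path, db, b)
    expect_equal(nrow(back), nrow(aln))
    expect_equal(back$target_start, aln$target_start)
    expect_equal(back$target_end, aln$target_end)
    expect_equal(summarizeCoverage(back, db, b),
                 summarizeCoverage(aln, db, b))
})
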