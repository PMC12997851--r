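obsFixture <- function(genomes, barcodes, copies, covFrac = 0.5) {
    # one row per genome x barcode with prescribed observed copies
    grid <- expand.grid(genome_id = genomes, barcode = barcodes,
                        stringsAsFactors = FALSE)
    grid$coverage_fraction <- covFrac
    grid$copies_observed <- as.numeric(copies)
    grid
}

test_that("barcode effect factor is observed over theoretical output", {
    expect_equal(barcodeEffectFactor(1e7 * 50, 50, 1e7)$bef, 1.0)
    expect_equal(barcodeEffectFactor(2e9, 100, 1e7)$bef, 2.0)
    expect_error(barcodeEffectFactor(1e9, 0, 1e7), "> 0")
    expect_error(barcodeEffectFactor(0, 10, 1e7), "> 0")
    befs <- barcodeEffectFactor(c(1e9, 2e9), c(100, 100), 1e7,
                                c("BC01", "BC02"))
    expect_equal(befs$bef, c(1, 2))
})

test_that("observed copy number divides BEF-normalized mapped by covered bases", {
    cov <- data.frame(genome_id = c("g1", "g1", "g2"),
                      barcode = c("BC01", "BC02", "BC01"),
                      mapped_bases = c(1000, 1000, 500),
                      covered_bases = c(100, 100, 0),
                      genome_length = 1000,
                      coverage_fraction = c(0.1, 0.1, 0),
                      depth = c(1, 1, 0.5), stringsAsFactors = FALSE)
    befs <- barcodeEffectFactor(c(1e9, 2e9), c(100, 100), 1e7,
                                c("BC01", "BC02"))
    befs$bef <- c(1, 2)
    obs <- observedCopyNumber(cov, befs)
    expect_equal(obs$copies_observed[1], 10)
    expect_equal(obs$copies_observed[2], 5)   # halved by BEF 2
    expect_true(is.na(obs$copies_observed[3]))
    expect_equal(obs$copy_reason[3], "no coverage")
    expect_error(observedCopyNumber(cov,
                                    befs[befs$barcode == "BC01", ]),
                 "barcode mismatch")
})

test_that("LOD detection is strictly greater-than the coverage threshold", {
    expect_true(applyLod(0.11))
    expect_false(applyLod(0.10))
    expect_false(applyLod(0.0))
    expect_equal(applyLod(c(0.05, 0.2, NA)), c(FALSE, TRUE, FALSE))
    expect_error(applyLod(1.2), "\\[0, 1\\]")
})

test_that("replicate CV uses the n-1 standard deviation over the mean", {
    expect_equal(replicateCv(c(10, 10, 10)), 0)
    expect_equal(replicateCv(c(8, 10, 12)), 0.2)
    expect_true(is.na(replicateCv(5)))
    expect_true(is.na(replicateCv(c(3, NA))))
    expect_equal(replicateCv(c(8, NA, 12)), sd(c(8, 12)) / 10)
})

test_that("calibration recovers identity and constant-factor relations", {
    theo <- 10^(2:6)
    truth <- loadSpikeInTruth(data.frame(
        genome_id = paste0("s", 1:5), theoretical_copies = theo))
    obsId <- obsFixture(paste0("s", 1:5), c("b1", "b2", "b3"),
                        rep(theo, 3))
    m <- fitCalibration(truth, obsId)
    expect_equal(modelSlope(m), 1, tolerance = 1e-12)
    expect_equal(modelIntercept(m), 0, tolerance = 1e-12)
    expect_equal(rSquared(m), 1, tolerance = 1e-12)
    expect_equal(nPoints(m), 5L)
    expect_setequal(retainedGenomes(m), paste0("s", 1:5))

    # observed = theoretical x 10 shifts only the intercept
    m10 <- fitCalibration(truth, obsFixture(paste0("s", 1:5),
                                            c("b1", "b2", "b3"),
                                            rep(theo * 10, 3)))
    expect_equal(modelSlope(m10), 1, tolerance = 1e-12)
    expect_equal(modelIntercept(m10), -1, tolerance = 1e-12)
})

test_that("calibration matches independent least-squares oracles", {
    # exactly two retained genomes: closed-form two-point line
    truth2 <- loadSpikeInTruth(data.frame(genome_id = c("a", "b"),
                                          theoretical_copies = c(100, 9000)))
    obs2 <- obsFixture(c("a", "b"), c("b1", "b2"), c(50, 4000, 51, 4100))
    m2 <- fitCalibration(truth2, obs2)
    x <- log10(c(mean(c(50, 51)), mean(c(4000, 4100))))
    y <- log10(c(100, 9000))
    expect_equal(modelSlope(m2), diff(y) / diff(x), tolerance = 1e-12)
    expect_equal(modelIntercept(m2), y[1] - diff(y) / diff(x) * x[1],
                 tolerance = 1e-12)
    expect_true(is.na(rSquared(m2)))

    # noisy 8-genome fit agrees with the normal-equation oracle
    set.seed(17)
    theo <- 10^seq(2, 6, length.out = 8)
    noisy <- theo * 10^rnorm(8, 0, 0.05)
    truth8 <- loadSpikeInTruth(data.frame(genome_id = paste0("g", 1:8),
                                          theoretical_copies = theo))
    obs8 <- obsFixture(paste0("g", 1:8), c("b1", "b2"), rep(noisy, 2))
    m8 <- fitCalibration(truth8, obs8)
    ora <- olsOracle(log10(noisy), log10(theo))
    expect_equal(modelSlope(m8), ora$slope, tolerance = 1e-10)
    expect_equal(modelIntercept(m8), ora$intercept, tolerance = 1e-10)
    expect_equal(rSquared(m8), ora$r2, tolerance = 1e-10)
    expect_equal(modelSlope(m8), 1, tolerance = 0.1)
})

test_that("LOD/LOQ filtering retains a subset and underdetermined fits error", {
    theo <- 10^(2:6)
    truth <- loadSpikeInTruth(data.frame(genome_id = paste0("s", 1:5),
                                         theoretical_copies = theo))
    obs <- obsFixture(paste0("s", 1:5), c("b1", "b2", "b3"), rep(theo, 3))
    # s1 fails LOD in one replicate; s2 fails LOQ (high CV)
    obs$coverage_fraction[obs$genome_id == "s1" & obs$barcode == "b2"] <- 0.05
    obs$copies_observed[obs$genome_id == "s2"] <-
        c(0.5, 1, 2) * theo[2]
    m <- fitCalibration(truth, obs)
    expect_setequal(retainedGenomes(m), c("s3", "s4", "s5"))
    expect_true(all(retainedGenomes(m) %in% truth$genome_id))
    obsBad <- obs
    obsBad$coverage_fraction <- 0.01
    expect_error(fitCalibration(truth, obsBad), "underdetermined")
})

test_that("estimate application inverts the log-log model", {
    ident <- fitCalibration(
        loadSpikeInTruth(data.frame(genome_id = c("a", "b"),
                                    theoretical_copies = c(10, 1000))),
        obsFixture(c("a", "b"), c("b1", "b2"), c(10, 1000, 10, 1000)))
    expect_equal(estimateCopies(ident, 250), 250, tolerance = 1e-9)
    shift <- new("CalibrationModel", slope = 1, intercept = 0.3,
                 rSquared = NA_real_, nPoints = 2L, retained = "x",
                 filters = list(lod = 0.1, loq_cv = 0.1))
    expect_equal(estimateCopies(shift, 1000), 10^3.3)
    expect_equal(estimateCopies(shift, 1000), 1995.26, tolerance = 1e-4)
    expect_true(is.na(estimateCopies(shift, 0)))
    expect_true(is.na(estimateCopies(shift, NA)))
    degen <- new("CalibrationModel", slope = 0, intercept = 2,
                 rSquared = NA_real_, nPoints = 2L, retained = "x",
                 filters = list(lod = 0.1, loq_cv = 0.1))
    expect_warning(est <- estimateCopies(degen, c(10, 1e6)), "zero-slope")
    expect_equal(est, c(100, 100))
})

test_that("copies per microliter scales by extract volume", {
    expect_equal(copiesPerUl(1000, 2), 500)
    expect_equal(copiesPerUl(0, 2), 0)
    expect_error(copiesPerUl(100, 0), "> 0")
})

test_that("sample quantitation flags undetected and unquantifiable genomes", {
    theo <- c(1e3, 1e5)
    truth <- loadSpikeInTruth(data.frame(genome_id = c("a", "b"),
                                         theoretical_copies = theo))
    model <- fitCalibration(truth, obsFixture(c("a", "b"),
                                              c("b1", "b2"),
                                              rep(theo, 2)))
    cov <- expand.grid(genome_id = c("gLow", "gOk", "gNoisy"),
                       barcode = c("s1", "s2", "s3"),
                       stringsAsFactors = FALSE)
    cov$genome_length <- 1000
    cov$coverage_fraction <- ifelse(cov$genome_id == "gLow", 0.05, 0.9)
    cov$covered_bases <- cov$coverage_fraction * 1000
    base <- c(gLow = 50, gOk = 200, gNoisy = 200)[cov$genome_id]
    fac <- ifelse(cov$genome_id == "gNoisy",
                  c(0.5, 1, 2)[match(cov$barcode, c("s1", "s2", "s3"))], 1)
    cov$mapped_bases <- base * fac * cov$covered_bases
    cov$depth <- cov$mapped_bases / cov$genome_length
    befs <- barcodeEffectFactor(rep(1e9, 3), rep(100, 3), 1e7,
                                c("s1", "s2", "s3"))
    befs$bef <- 1
    q <- quantifySample(cov, befs, model, volumeUl = 2)
    q <- q[order(q$genome_id), ]
    expect_equal(q$genome_id, c("gLow", "gNoisy", "gOk"))
    expect_equal(q$detected, c(FALSE, TRUE, TRUE))
    expect_equal(q$quantifiable, c(FALSE, FALSE, TRUE))
    expect_true(is.na(q$estimated_copies[q$genome_id == "gLow"]))
    expect_true(is.na(q$estimated_copies[q$genome_id == "gNoisy"]))
    ok <- q[q$genome_id == "gOk", ]
    expect_equal(ok$cv, 0)
    expect_equal(ok$estimated_copies, 200, tolerance = 1e-9)
    expect_equal(ok$copies_per_ul, 100, tolerance = 1e-9)
    # any-replicate detection relaxes the rule
    covAny <- cov
    covAny$coverage_fraction[covAny$genome_id == "gLow" &
                             covAny$barcode == "s1"] <- 0.5
    qAny <- quantifySample(covAny, befs, model, detection = "any")
    expect_true(qAny$detected[qAny$genome_id == "gLow"])
})

test_that("rank aggregation sums quantifiable species into genus totals", {
    comm <- communitySpec(c("sp1", "sp2", "sp3"), rep(1000, 3), c(1, 1, 1),
                          taxonomy = c(
        "d__B;p__P;c__C;o__O;f__F;g__GenusX;s__sp one",
        "d__B;p__P;c__C;o__O;f__F;g__GenusX;s__sp two",
        "d__B;p__P;c__C;o__O;f__F;g__GenusY;s__sp three"))
    db <- simulateGenomes(comm, emitSequences = FALSE)
    quant <- data.frame(genome_id = c("sp1", "sp2", "sp3"),
                        quantifiable = c(TRUE, TRUE, FALSE),
                        estimated_copies = c(100, 50, NA),
                        stringsAsFactors = FALSE)
    agg <- aggregateRank(quant, db, "genus")
    expect_equal(agg$estimated_copies[agg$genus == "GenusX"], 150)
    expect_true(is.na(agg$estimated_copies[agg$genus == "GenusY"]))
    expect_equal(agg$n_quantified[agg$genus == "GenusY"], 0)
    expect_equal(agg$n_genomes[agg$genus == "GenusX"], 2)
    expect_error(aggregateRank(quant, db, "strain"), "unknown rank")
})

test_that("calibration model JSON round-trips", {
    m <- new("CalibrationModel", slope = 0.97, intercept = 0.31,
             rSquared = 0.995, nPoints = 7L,
             retained = c("a", "b", "c"),
             filters = list(lod = 0.1, loq_cv = 0.1), kappa = 1e7,
             method = "ols_mean")
    path <- withr::local_tempfile(fileext = ".json")
    writeCalibrationModel(m, path)
    m2 <- readCalibrationModel(path)
    expect_equal(modelSlope(m2), 0.97)
    expect_equal(modelIntercept(m2), 0.31)
    expect_equal(rSquared(m2), 0.995)
    expect_equal(retainedGenomes(m2), c("a", "b", "c"))
    expect_equal(m2@filters$lod, 0.1)
})

test_that("final estimates are invariant to the kappa yield constant", {
    sim <- smallExperiment(seed = 11, targetBases = 1e7)
    a <- calibrateAndQuantify(sim, kappa = 1e7)
    b <- calibrateAndQuantify(sim, kappa = 1e10)
    ea <- a$quant$estimated_copies
    eb <- b$quant$estimated_copies
    ok <- is.finite(ea) & is.finite(eb)
    expect_true(any(ok))
    expect_lt(max(abs(eb[ok] - ea[ok]) / ea[ok]), 1e-9)
    # the BEFs and observed copies themselves do change
    expect_false(isTRUE(all.equal(a$befs$bef, b$befs$bef)))
})

test_that("noise-free expected-coverage runs recover theoretical copies exactly", {
    spike <- communitySpec(sprintf("sp%d", 1:6), rep(1e5, 6),
                           1e5 * 10^seq(0, 2, length.out = 6))
    samp <- communitySpec(sprintf("sa%d", 1:4), rep(1e5, 4),
                          c(2e5, 8e5, 3e6, 6e6))
    run <- standardRunDesign(spikeThroughput = c(0.5, 1, 2),
                             sampleThroughput = c(1.5, 1, 0.7))
    sim <- expectedExperiment(spike, samp, run, targetBases = 5e9)
    res <- calibrateAndQuantify(sim, kappa = 1e7)
    q <- res$quant
    expect_true(all(q$detected))
    relerr <- abs(q$estimated_copies - samp$copies[match(q$genome_id,
                                                         samp$genome_id)]) /
        samp$copies[match(q$genome_id, samp$genome_id)]
    expect_lt(max(relerr), 1e-6)
})

test_that("BEF normalization reduces estimation error under unequal throughput", {
    errs <- vapply(1:5, function(seed) {
        set.seed(seed)
        tp <- sample(c(0.5, 1, 2), 6, replace = TRUE)
        sim <- smallExperiment(seed = seed, targetBases = 8e6,
                               spikeThroughput = tp[1:3],
                               sampleThroughput = tp[4:6])
        truthCopies <- sim$sampleCommunity$copies
        names(truthCopies) <- sim$sampleCommunity$genome_id
        # LOQ relaxed in BOTH arms: without BEF the replicate CV explodes
        # and the LOQ filter would simply empty the calibration, so the
        # error comparison is made on unfiltered estimates
        err <- function(useBef) {
            q <- calibrateAndQuantify(sim, useBef = useBef,
                                      loqCv = Inf)$quant
            ok <- q$quantifiable
            mean(abs(log10(q$estimated_copies[ok]) -
                     log10(truthCopies[q$genome_id[ok]])))
        }
        c(bef = err(TRUE), nobef = err(FALSE))
    }, numeric(2))
    expect_lt(mean(errs["bef", ]), mean(errs["nobef", ]))
})
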