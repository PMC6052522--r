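test_that("metagene windows count 5' ends relative to the anchors", {
    tm <- transcriptModel("t1", "g1", "c", "+", IRanges::IRanges(1L, 500L),
                          cdsStartT = 101L, cdsEndT = 400L)
    ts <- transcriptSet(list(tm))
    # read 5' end 12 nt upstream of the start codon
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = 89L))
    w <- metageneWindow(idx, ts, "g1", 28L, "start")
    expect_equal(unname(windowCounts(w)["-12"]), 1)
    expect_equal(sum(w@counts), 1)
    # stop anchor sits on the first base of the last sense codon (398)
    idxStop <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = 386L))
    ws <- metageneWindow(idxStop, ts, "g1", 28L, "stop")
    expect_equal(unname(windowCounts(ws)["-12"]), 1)
    # a leader shorter than 30 nt simply leaves positions uncovered
    shortLeader <- transcriptModel("t2", "g2", "c", "+",
                                   IRanges::IRanges(1001L, 1500L),
                                   cdsStartT = 11L, cdsEndT = 310L)
    ts2 <- transcriptSet(list(shortLeader))
    w2 <- metageneWindow(idx, ts2, "g2", 28L, "start")
    expect_equal(sum(w2@counts), 0)
    # windows are additive over disjoint gene sets
    ts3 <- transcriptSet(list(tm, shortLeader))
    idx3 <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = c(89L, 999L)))
    wu <- metageneWindow(idx3, ts3, c("g1", "g2"), 28L, "start")
    wa <- metageneWindow(idx3, ts3, "g1", 28L, "start")
    wb <- metageneWindow(idx3, ts3, "g2", 28L, "start")
    expect_equal(wu@counts, wa@counts + wb@counts)
})

test_that("change point finds the maximal segment-mean shift", {
    step <- c(rep(0, 18), rep(10, 23))   # step up at window position -12
    expect_equal(changePoint(step)$dstar, -12L)
    spike <- numeric(41); spike[19L] <- 100  # single spike at -12
    expect_equal(changePoint(spike)$dstar, -12L)
    expect_equal(changePoint(spike)$dstar, changePointOracle(spike))
    ramp <- seq_len(41)
    expect_equal(changePoint(ramp)$dstar, changePointOracle(ramp))
    expect_error(changePoint(numeric(41)), "no change point")
    # ties resolve to the most 5' boundary
    twoSteps <- c(rep(0, 10), rep(4, 10), rep(4, 10), rep(8, 11))
    expect_equal(changePoint(twoSteps)$dstar, changePointOracle(twoSteps))
})

test_that("change point matches the exhaustive boundary oracle", {
    set.seed(13)
    for (i in 1:150) {
        x <- stats::rpois(41L, 3)
        if (all(x == 0)) x[sample.int(41L, 1L)] <- 1L
        expect_identical(changePoint(x)$dstar, changePointOracle(x))
    }
})

test_that("shifting the signal shifts the change point equivariantly", {
    base <- numeric(41); base[16:41] <- 5  # edge at -15
    d0 <- changePoint(base)$dstar
    for (s in c(1L, 3L, 6L)) {
        shifted <- c(numeric(s), base)[1:41]
        expect_equal(changePoint(shifted)$dstar, d0 + s)
    }
})

test_that("offsets derive from change points with sign checks", {
    expect_equal(offsetFromChangepoint(-12L, "start"), 12L)
    expect_equal(offsetFromChangepoint(0L, "start"), 0L)
    expect_equal(offsetFromChangepoint(-12L, "stop"), 12L)
    expect_warning(off <- offsetFromChangepoint(3L, "start"),
                   "implausible")
    expect_equal(off, -3L)
})

test_that("calibration recovers the simulated offsets on every anchor", {
    lib <- standardLib()
    truth <- lib$scn@trueOffsets
    lens <- as.integer(names(truth))
    for (pol in c("auto", "start", "stop")) {
        ot <- calibrateOffsets(lib$idx, lib$ts, lib$genes, lens,
                               anchorPolicy = pol)
        tab <- offsetTable(ot)
        expect_equal(stats::setNames(tab$offset, tab$length),
                     stats::setNames(as.integer(truth), names(truth)),
                     info = pol)
        expect_false(any(tab$userOverridden))
    }
    # start- and stop-anchored calibration agree: the effective P-site
    # position is the same whichever end anchors it
    s1 <- offsetTable(calibrateOffsets(lib$idx, lib$ts, lib$genes, lens,
                                       anchorPolicy = "start"))
    s2 <- offsetTable(calibrateOffsets(lib$idx, lib$ts, lib$genes, lens,
                                       anchorPolicy = "stop"))
    expect_equal(s1$offset, s2$offset)
})

test_that("uniform 5' offsets across lengths are recovered uniformly", {
    scn <- simScenario(seed = 21L, readsPerLength = 1500L,
                       noiseReads = 0L, noiseLengths = integer(),
                       trueOffsets = c("27" = 12L, "28" = 12L,
                                       "29" = 12L))
    lib <- cachedSim("uniform12", scn)
    ot <- offsetTable(calibrateOffsets(lib$idx, lib$ts, lib$genes,
                                       27:29))
    expect_equal(ot$offset, rep(12L, 3L))
})

test_that("auto anchoring falls back to the stop codon when leaders are empty", {
    tm <- transcriptModel("t1", "g1", "c", "+", IRanges::IRanges(1L, 500L),
                          cdsStartT = 101L, cdsEndT = 400L)
    ts <- transcriptSet(list(tm))
    # no reads anywhere near the start codon; a clear terminating peak
    # 12 nt upstream of the last codon (genomic 386) over flat elongation
    pos <- c(rep(386L, 50L), seq(201L, 350L, by = 3L))
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = pos))
    ot <- offsetTable(calibrateOffsets(idx, ts, "g1", 28L,
                                       anchorPolicy = "auto"))
    expect_equal(ot$anchorUsed, "stop")
    expect_equal(ot$offset, 12L)
    # with no signal on either anchor the offset is absent, with warning
    idxFar <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = 200L))
    expect_warning(otNA <- offsetTable(
        calibrateOffsets(idxFar, ts, "g1", 28L, anchorPolicy = "auto")),
        "offset undefined")
    expect_true(is.na(otNA$offset))
})

test_that("manual overrides are recorded and replace calibrated values", {
    lib <- standardLib()
    ot <- calibrateOffsets(lib$idx, lib$ts, lib$genes, c(27L, 28L, 29L))
    ot2 <- setOffset(ot, 28L, 13L)
    tab <- offsetTable(ot2)
    expect_equal(tab$offset[tab$length == 28L], 13L)
    expect_true(tab$userOverridden[tab$length == 28L])
    expect_equal(tab$anchorUsed[tab$length == 28L], "manual")
    expect_false(any(tab$userOverridden[tab$length != 28L]))
})

test_that("frame fractions concentrate on frame 0 at the correct offset", {
    tm <- transcriptModel("t1", "g1", "c", "+", IRanges::IRanges(1L, 500L),
                          cdsStartT = 101L, cdsEndT = 400L)
    ts <- transcriptSet(list(tm))
    # all 5' ends on the first codon position, no offset
    idx0 <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+",
        pos = seq(101L, 200L, by = 3L)))
    f0 <- frameFractions(idx0, ts, "g1", 28L)
    expect_equal(as.numeric(f0), c(1, 0, 0))
    # even split over the three frames
    idxE <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = 101:160))
    fE <- frameFractions(idxE, ts, "g1", 28L)
    expect_equal(as.numeric(fE), rep(1 / 3, 3L))
    # no CDS reads: flagged zero fractions
    idxN <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = 10L))
    fN <- frameFractions(idxN, ts, "g1", 28L)
    expect_equal(as.numeric(fN), c(0, 0, 0))
    expect_true(attr(fN, "noReads"))
    # simulated library at the calibrated offset: frame 0 near the
    # phase concentration (binomial tolerance)
    lib <- standardLib()
    fS <- frameFractions(lib$idx, lib$ts, lib$genes, 28L, offset = 12L)
    expect_equal(unname(fS["frame0"]), lib$scn@phase, tolerance = 0.04)
})

test_that("offset recovery is exact across offsets 10-14 at phase 0.7", {
    offs <- stats::setNames(10:14, 26:30)
    for (seed in 1:2) {
        scn <- simScenario(seed = seed, periodicLengths = 26:30,
                           trueOffsets = offs, readsPerLength = 4000L,
                           phase = 0.7, noiseReads = 0L,
                           noiseLengths = integer())
        lib <- cachedSim(sprintf("recov%d", seed), scn)
        for (pol in c("start", "stop")) {
            tab <- offsetTable(calibrateOffsets(lib$idx, lib$ts,
                                                lib$genes, 26:30,
                                                anchorPolicy = pol))
            expect_equal(tab$offset, unname(offs),
                         info = sprintf("seed %d %s", seed, pol))
        }
    }
})
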