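toyOffsets <- function(...) {
    pairs <- list(...)
    tab <- data.frame(length = as.integer(names(pairs)),
                      offset = as.integer(unlist(pairs)),
                      anchorUsed = "start", changepoint = NA_integer_,
                      userOverridden = FALSE)
    new("OffsetTable", table = tab)
}

test_that("P-site tracks shift 5' ends towards 3' on both strands", {
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "chr1", strand = c("+", "-"),
        pos = c(1000L, 1027L), count = c(3L, 2L)))
    tr <- psiteTrack(idx, toyOffsets("28" = 12L), toyTs())
    df <- trackData(tr)
    expect_equal(df$pos[df$strand == "+"], 1012L)
    expect_equal(df$pos[df$strand == "-"], 1015L)   # 3' is leftward on -
    expect_equal(sum(df$value), 5)
})

test_that("merged tracks equal the position-wise sum of per-length tracks", {
    idx <- fivePrimeEndIndex(data.frame(
        length = rep(c(27L, 28L), each = 3L), chrom = "chr1",
        strand = "+", pos = c(10L, 10L, 40L, 11L, 40L, 70L)))
    off <- toyOffsets("27" = 11L, "28" = 12L)
    merged <- trackData(psiteTrack(idx, off, toyTs()))
    per <- psiteTrack(idx, off, toyTs(), perLength = TRUE)
    expect_setequal(names(per), c("27", "28"))
    acc <- do.call(rbind, lapply(per, trackData))
    agg <- rowsum(acc$value, paste(acc$seq, acc$strand, acc$pos))
    key <- paste(merged$seq, merged$strand, merged$pos)
    expect_equal(unname(agg[key, 1L]), merged$value)
    expect_equal(sum(merged$value), idx@totalAfterMask)
    # lengths without offsets are excluded with a warning
    expect_warning(psiteTrack(idx, toyOffsets("27" = 11L), toyTs()),
                   "without calibrated offsets")
})

test_that("transcriptomic tracks map through representative transcripts", {
    tm <- modelPlus()
    ts <- transcriptSet(list(tm))
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "chrT", strand = "+",
        pos = c(38L, 88L, 150L)))  # last one shifts into the intron
    tr <- psiteTrack(idx, toyOffsets("28" = 12L), ts,
                     space = "transcriptomic")
    df <- trackData(tr)
    expect_equal(df$seq, c("tP", "tP"))
    expect_equal(df$pos, c(50L, 100L))
    expect_equal(tr@droppedReads, 1L)
    # conservation: placed + dropped = counted
    expect_equal(sum(df$value) + tr@droppedReads, idx@totalAfterMask)
})

test_that("wiggle output round-trips through an independent reader", {
    set.seed(99)
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = sample(c("chr1", "chr2"), 40L, TRUE),
        strand = sample(c("+", "-"), 40L, TRUE),
        pos = sample.int(5000L, 40L, TRUE)))
    tr <- psiteTrack(idx, toyOffsets("28" = 12L), toyTs())
    base <- file.path(tempdir(), "wigtest")
    files <- writeWiggle(tr, base)
    expect_equal(basename(files),
                 c("wigtest.fwd.wig", "wigtest.rev.wig"))
    df <- trackData(tr)
    total <- 0
    for (i in 1:2) {
        strand <- c("+", "-")[i]
        got <- rtracklayer::import(files[i], format = "wig")
        want <- df[df$strand == strand, , drop = FALSE]
        want <- want[order(want$seq, want$pos), ]
        expect_equal(as.character(GenomicRanges::seqnames(got)),
                     want$seq)
        expect_equal(GenomicRanges::start(got), want$pos)
        expect_equal(got$score, want$value)
        total <- total + sum(got$score)
    }
    # conservation through export: wiggle values sum to exported reads
    expect_equal(total, sum(df$value))
    # empty track: header-comment-only files
    emptyTr <- new("CoverageTrack", space = "transcriptomic",
                   data = data.frame(seq = character(),
                                     strand = character(),
                                     pos = integer(), value = integer()),
                   droppedReads = 0L)
    f <- writeWiggle(emptyTr, file.path(tempdir(), "empty.wig"))
    expect_equal(length(readLines(f)), 1L)
    expect_match(readLines(f), "^#")
})

test_that("region statistics partition counted reads into regions", {
    tm <- modelPlus()       # exons 1..100, 201..300; CDS tpos 51..150
    ts <- transcriptSet(list(tm, modelNoncoding()))
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "chrT", strand = "+",
        pos = c(10L, 60L, 220L, 280L, 150L, 600L, 1100L)))
    st <- regionStats(idx, ts)
    row <- regionCounts(st)[regionCounts(st)$length == "all", ]
    expect_equal(row$five_prime_leader, 1)   # pos 10
    expect_equal(row$cds, 2)                 # 60 (tpos 60), 220 (tpos 120)
    expect_equal(row$three_prime_trailer, 1) # 280 -> tpos 180
    expect_equal(row$intron, 1)              # 150
    expect_equal(row$intergenic, 1)          # 600
    expect_equal(row$noncoding_transcript, 1) # 1100 on tN
    expect_equal(sum(row[, -1L]), idx@totalAfterMask)
    # offset shifting moves reads between categories as recomputed
    st2 <- regionStats(idx, ts, offsets = toyOffsets("28" = 45L))
    row2 <- regionCounts(st2)[regionCounts(st2)$length == "all", ]
    expect_equal(sum(row2[, -1L]), idx@totalAfterMask)
    expect_equal(row2$five_prime_leader, 0)  # pos 10 -> 55 (tpos 55, cds)
})

test_that("RPKM follows its definition and is scale invariant", {
    # 10 reads on a 1000-nt CDS in a 1,000,000-read library -> RPKM 10
    tm <- transcriptModel("t1", "gX", "c", "+",
                          IRanges::IRanges(1L, 1200L),
                          cdsStartT = 101L, cdsEndT = 1100L)
    filler <- transcriptModel("t2", "gF", "c", "+",
                              IRanges::IRanges(5001L, 6200L),
                              cdsStartT = 101L, cdsEndT = 1100L)
    ts <- transcriptSet(list(tm, filler))
    idx <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+",
        pos = c(rep(200L, 1L), 5200L),
        count = c(10L, 999990L)))
    tab <- rpkmTable(idx, ts)
    expect_equal(tab$rpkm[tab$gene_id == "gX"], 10)
    expect_equal(tab$count[tab$gene_id == "gX"], 10)
    expect_equal(tab$length_kb[tab$gene_id == "gX"], 1)
    # uniform scaling leaves RPKM unchanged (library size scales too)
    idx2 <- fivePrimeEndIndex(transform(endCounts(idx),
                                        count = count * 2L))
    expect_equal(rpkmTable(idx2, ts)$rpkm, tab$rpkm)
    # a gene with zero reads reports RPKM 0
    idx3 <- fivePrimeEndIndex(data.frame(
        length = 28L, chrom = "c", strand = "+", pos = 200L))
    tab3 <- rpkmTable(idx3, ts)
    expect_equal(tab3$rpkm[tab3$gene_id == "gF"], 0)
    expect_error(rpkmTable(idx3, ts, lengths = 30L), "no counted reads")
})

test_that("translational efficiency is the ratio of RPKM tables", {
    ribo <- data.frame(gene_id = c("a", "b", "c"), count = 1,
                       length_kb = 1, rpkm = c(10, 0, 7))
    rna <- data.frame(gene_id = c("a", "b", "c", "d"), count = 1,
                      length_kb = 1, rpkm = c(5, 4, 0, 9))
    te <- translationalEfficiency(ribo, rna)
    expect_equal(te$te[te$gene_id == "a"], 2)
    expect_equal(te$te[te$gene_id == "b"], 0)
    expect_true(is.na(te$te[te$gene_id == "c"]))
    expect_false(te$te_defined[te$gene_id == "c"])
    expect_false("d" %in% te$gene_id)
    expect_error(translationalEfficiency(
        ribo, data.frame(gene_id = "z", count = 1, length_kb = 1,
                         rpkm = 1)), "no genes shared")
})

test_that("simulated 2x footprint density doubles relative efficiency", {
    w <- rep(1, 12); w[5L] <- 2   # gene 5 translated twice as heavily
    scn <- simScenario(seed = 31L, nGenes = 12L, readsPerLength = 1200L,
                       noiseReads = 0L, noiseLengths = integer(),
                       geneWeights = w, rnaWeights = rep(1, 12),
                       rnaReads = 12000L)
    lib <- cachedSim("te2x", scn, rna = TRUE)
    rnaIdx <- buildEndIndex(lib$rnaBam, lib$ts)
    ribo <- rpkmTable(lib$idx, lib$ts, lengths = 27:29,
                      offsets = toyOffsets("27" = 11L, "28" = 12L,
                                           "29" = 13L))
    rna <- rpkmTable(rnaIdx, lib$ts, mode = "rna")
    te <- translationalEfficiency(ribo, rna)
    # TE carries a per-gene exon-kb / CDS-kb factor (footprint density is
    # per CDS, RNA density per transcript); normalize it out before
    # comparing across genes
    kbFactor <- vapply(te$gene_id, function(g) {
        tm <- getTranscript(lib$ts, representativeTranscripts(lib$ts)[[g]])
        (txLength(tm) / 1000) / (cdsLength(tm) / 1000)
    }, 0)
    adj <- te$te / kbFactor
    ratio <- adj[te$gene_id == "g005"] /
        stats::median(adj[te$gene_id != "g005"])
    expect_equal(unname(ratio), 2, tolerance = 0.1)
})
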