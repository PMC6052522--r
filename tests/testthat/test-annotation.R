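test_that("GTF parsing converts coordinates and stitches CDS across exons", {
    gtf <- writeToyGtf(tempfile(fileext = ".gtf"))
    ts <- readAnnotation(gtf)
    expect_equal(transcriptIds(ts), "t1")
    tm <- getTranscript(ts, "t1")
    expect_equal(IRanges::start(tm@exons), c(1L, 201L))
    expect_equal(IRanges::end(tm@exons), c(100L, 300L))
    expect_equal(txLength(tm), 200L)
    # CDS genomic 51..100 + 201..250 -> transcript 51..150
    expect_equal(tm@cdsStartT, 51L)
    expect_equal(tm@cdsEndT, 150L)
    # independent per-base enumeration: count exonic bases 5' of the CDS
    exonic <- c(1:100, 201:300)
    expect_equal(which(exonic == 51L), 51L)
    expect_equal(which(exonic == 250L), 150L)
})

test_that("BED12 and GTF representations parse to the same model", {
    gtf <- readAnnotation(writeToyGtf(tempfile(fileext = ".gtf")))
    bed <- readAnnotation(writeToyBed12(tempfile(fileext = ".bed")))
    a <- getTranscript(gtf, "t1"); b <- getTranscript(bed, "t1")
    expect_equal(IRanges::start(a@exons), IRanges::start(b@exons))
    expect_equal(IRanges::end(a@exons), IRanges::end(b@exons))
    expect_equal(a@cdsStartT, b@cdsStartT)
    expect_equal(a@cdsEndT, b@cdsEndT)
    expect_equal(a@strand, b@strand)
})

test_that("malformed annotations fail with the offending line number", {
    bad <- tempfile(fileext = ".gtf")
    writeLines(c("chr1\ttest\texon\t1\t100\t.\t+\t.\ttranscript_id \"t\";",
                 "chr1\ttest\texon"), bad)
    expect_error(readAnnotation(bad), "line 2")
    noid <- tempfile(fileext = ".gtf")
    writeLines("chr1\ttest\texon\t1\t100\t.\t+\t.\tfoo \"bar\";", noid)
    expect_error(readAnnotation(noid), "transcript_id")
    expect_error(readAnnotation(tempfile(fileext = ".gtf")), "not found")
})

test_that("genome/transcript mapping is mutually inverse on both strands", {
    for (tm in list(modelPlus(), modelMinus())) {
        tl <- txLength(tm)
        tpos <- seq_len(tl)
        gpos <- transcriptToGenome(tpos, tm)
        expect_equal(genomeToTranscript(gpos, tm), tpos)
        # every exonic genomic position round-trips
        exonic <- c(1:100, 201:300)
        expect_equal(transcriptToGenome(genomeToTranscript(exonic, tm), tm),
                     exonic)
    }
    # worked examples: 100 exonic bases precede genomic 250 on plus
    expect_equal(genomeToTranscript(250L, modelPlus()), 150L)
    expect_equal(transcriptToGenome(150L, modelPlus()), 250L)
    # minus strand: genomic right end is transcript position 1
    tmM <- modelMinus()
    expect_equal(genomeToTranscript(300L, tmM), 1L)
    expect_equal(transcriptToGenome(1L, tmM), 300L)
    # intronic and flanking positions are unmapped
    expect_true(is.na(genomeToTranscript(150L, modelPlus())))
    expect_true(is.na(genomeToTranscript(301L, modelPlus())))
    expect_error(transcriptToGenome(201L, modelPlus()), "out of range")
})

test_that("coordinate round-trip holds for random multi-exon models", {
    set.seed(42)
    for (i in 1:25) {
        tm <- randomModel(sprintf("r%02d", i),
                          if (i %% 2L) "+" else "-")
        tpos <- seq_len(txLength(tm))
        expect_identical(genomeToTranscript(transcriptToGenome(tpos, tm),
                                            tm), tpos)
    }
})

test_that("leader/CDS/trailer partition every coding transcript position", {
    tm <- modelPlus()
    reg <- classifyRegion(seq_len(txLength(tm)), tm)
    expect_equal(sum(reg == "five_prime_leader"), tm@cdsStartT - 1L)
    expect_equal(sum(reg == "cds"), cdsLength(tm))
    expect_equal(sum(reg == "three_prime_trailer"),
                 txLength(tm) - tm@cdsEndT)
    # half-open-equivalent boundaries: first CDS base is cds, the base
    # after the last CDS base is trailer
    expect_equal(classifyRegion(tm@cdsStartT, tm), "cds")
    expect_equal(classifyRegion(tm@cdsEndT, tm), "cds")
    expect_equal(classifyRegion(tm@cdsEndT + 1L, tm),
                 "three_prime_trailer")
    expect_equal(classifyRegion(5L, modelNoncoding()), "noncoding")
    expect_error(classifyRegion(0L, tm), "out of range")
})

test_that("mask reading merges intervals and tolerates empty files", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed)
    m <- readMask(bed)
    expect_equal(length(maskRanges(m)), 1L)
    expect_equal(IRanges::start(maskRanges(m)), 11L)  # 0-based 10 -> 1-based 11
    expect_equal(IRanges::end(maskRanges(m)), 30L)
    empty <- tempfile(fileext = ".bed")
    writeLines(character(), empty)
    expect_equal(length(maskRanges(readMask(empty))), 0L)
    gtfMask <- tempfile(fileext = ".gtf")
    attr1 <- 'gene_id "rrna1";'
    writeLines(c(paste("chr1", "x", "gene", "5", "50", ".", "+", ".",
                       attr1, sep = "\t"),
                 paste("chr2", "x", "gene", "7", "70", ".", "-", ".",
                       attr1, sep = "\t")), gtfMask)
    m2 <- readMask(gtfMask)
    expect_equal(length(maskRanges(m2)), 2L)
    expect_setequal(as.character(GenomicRanges::seqnames(maskRanges(m2))),
                    c("chr1", "chr2"))
})

test_that("representative transcript is the longest CDS, ties lexicographic", {
    short <- transcriptModel("txB", "g1", "c", "+",
                             IRanges::IRanges(1L, 300L),
                             cdsStartT = 1L, cdsEndT = 90L)
    long <- transcriptModel("txA", "g1", "c", "+",
                            IRanges::IRanges(1L, 300L),
                            cdsStartT = 1L, cdsEndT = 150L)
    ts <- transcriptSet(list(short, long))
    expect_equal(unname(representativeTranscripts(ts)["g1"]), "txA")
    tie1 <- transcriptModel("txZ", "g2", "c", "+",
                            IRanges::IRanges(1L, 300L),
                            cdsStartT = 1L, cdsEndT = 90L)
    tie2 <- transcriptModel("txY", "g2", "c", "+",
                            IRanges::IRanges(1L, 300L),
                            cdsStartT = 11L, cdsEndT = 100L)
    ts2 <- transcriptSet(list(tie1, tie2))
    expect_equal(unname(representativeTranscripts(ts2)["g2"]), "txY")
})
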