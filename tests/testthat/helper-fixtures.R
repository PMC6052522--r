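# --- hand-built coordinate fixtures -----------------------------------------

# two-exon plus-strand transcript: exons [1,100] and [201,300] (1-based,
# closed), CDS covering transcript positions 51..150
modelPlus <- function() {
    transcriptModel("tP", "gP", "chrT", "+",
                    IRanges::IRanges(c(1L, 201L), c(100L, 300L)),
                    cdsStartT = 51L, cdsEndT = 150L)
}

# two-exon minus-strand transcript over the same genomic intervals;
# transcript position 1 is genomic 300
modelMinus <- function() {
    transcriptModel("tM", "gM", "chrT", "-",
                    IRanges::IRanges(c(1L, 201L), c(100L, 300L)),
                    cdsStartT = 51L, cdsEndT = 150L)
}

# single-exon noncoding transcript
modelNoncoding <- function() {
    transcriptModel("tN", "gN", "chrT", "+",
                    IRanges::IRanges(1001L, 1300L), biotype = "lincRNA")
}

toyTs <- function() transcriptSet(list(modelPlus(), modelMinus(),
                                       modelNoncoding()))

# random multi-exon transcript model for property loops
randomModel <- function(id, strand) {
    nEx <- sample(1:4, 1L)
    widths <- sample(20:80, nEx, replace = TRUE)
    gaps <- sample(10:50, nEx, replace = TRUE)
    starts <- 100L + cumsum(c(0L, (widths + gaps)[-nEx]))
    ex <- IRanges::IRanges(starts, width = widths)
    tl <- sum(widths)
    cs <- sample(seq_len(tl %/% 2), 1L)
    ce <- cs + sample(seq_len(tl - cs), 1L) - 1L
    transcriptModel(id, paste0("g", id), "chrR", strand, ex,
                    cdsStartT = cs, cdsEndT = ce)
}

# --- independent oracles -----------------------------------------------------

# O(N^2) direct periodogram: amplitudes of sum_j c[j] e^{-2 pi i j k / N}
periodogramOracle <- function(x) {
    N <- length(x)
    j <- 0:(N - 1L)
    ks <- seq_len(N %/% 2L)
    amps <- vapply(ks, function(k)
        Mod(sum(x * exp(-2i * pi * j * k / N))), 0)
    k <- which.max(amps)
    list(period = N / k, k = k, amps = amps)
}

# exhaustive segment-mean boundary search
changePointOracle <- function(x, positions = NULL) {
    n <- length(x)
    if (is.null(positions))
        positions <- if (n == 41L) -30:10 else seq_len(n)
    best <- -Inf; bi <- 1L
    for (b in seq_len(n - 1L)) {
        d <- mean(x[(b + 1L):n]) - mean(x[seq_len(b)])
        if (d > best) { best <- d; bi <- b }
    }
    positions[bi + 1L]
}

# --- shared simulated library (built once per test run) ----------------------

.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, scn, rna = FALSE) {
    if (is.null(.simCache[[key]])) {
        dir <- file.path(tempdir(), paste0("ribocal_sim_", key))
        sim <- simulateAnnotation(scn, dir)
        bam <- file.path(dir, "footprints.bam")
        simulateFootprints(scn, sim, bam)
        rnaBam <- NULL
        if (rna) {
            rnaBam <- file.path(dir, "rnaseq.bam")
            simulateRnaSeq(scn, sim, rnaBam)
        }
        ts <- readAnnotation(sim$gtf)
        idx <- buildEndIndex(bam, ts)
        genes <- selectTopGenes(idx, ts, 0.1)
        .simCache[[key]] <- list(scn = scn, sim = sim, bam = bam,
                                 rnaBam = rnaBam, ts = ts, idx = idx,
                                 genes = genes, dir = dir)
    }
    .simCache[[key]]
}

# reduced-size instance of the reference scenario for unit tests
standardLib <- function() {
    cachedSim("std", simScenario(seed = 1L, readsPerLength = 1500L,
                                 noiseReads = 400L))
}

# --- GTF / BED12 fixture of the same two-exon transcript ---------------------

writeToyGtf <- function(path) {
    attr1 <- 'transcript_id "t1"; gene_id "g1"; gene_biotype "protein_coding";'
    writeLines(c(
        paste("chr1", "test", "exon", "1", "100", ".", "+", ".", attr1,
              sep = "\t"),
        paste("chr1", "test", "exon", "201", "300", ".", "+", ".", attr1,
              sep = "\t"),
        paste("chr1", "test", "CDS", "51", "100", ".", "+", "0", attr1,
              sep = "\t"),
        paste("chr1", "test", "CDS", "201", "250", ".", "+", "2", attr1,
              sep = "\t")), path)
    path
}

writeToyBed12 <- function(path) {
    writeLines(paste("chr1", "0", "300", "t1", "0", "+", "50", "250",
                     "0", "2", "100,100", "0,200", sep = "\t"), path)
    path
}

# --- tiny BAM builder for ingest tests ---------------------------------------

# records: data.frame(name, flag, chrom, pos, cigar, seqlen)
writeTinyBam <- function(records, seqlengths, prefix) {
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                        as.integer(seqlengths)))
    qlen <- function(cig) {
        ops <- regmatches(cig, gregexpr("[0-9]+[MIS]", cig))[[1L]]
        sum(as.integer(sub("[MIS]", "", ops)))
    }
    body <- vapply(seq_len(nrow(records)), function(i) {
        r <- records[i, ]
        L <- qlen(r$cigar)
        tag <- if (!is.null(records$nh)) sprintf("\tNH:i:%d", r$nh) else ""
        paste0(paste(r$name, r$flag, r$chrom, r$pos, 255L, r$cigar, "*",
                     0L, 0L, strrep("A", L), strrep("I", L), sep = "\t"),
               tag)
    }, "")
    sam <- paste0(prefix, ".sam")
    writeLines(c(header, body), sam)
    on.exit(unlink(sam))
    Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                     indexDestination = TRUE)
}
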