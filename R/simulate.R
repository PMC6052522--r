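#' Create a simulation scenario
#'
#' Defaults describe the reference validation library: 30 coding genes
#' with Zipf-distributed expression, three periodic footprint lengths
#' (27, 28, 29 nt) at 5000 reads each with true 5'-to-P-site offsets
#' 11, 12, 13 nt and 90% of 5' ends on frame 0, plus three non-periodic
#' noise lengths (20-22 nt) placed uniformly over transcripts. First and
#' last CDS codons carry a 40x sampling weight, reproducing the distinct
#' initiation/termination metagene peaks of CHX-treated libraries that
#' anchor change-point calibration on either end.
#'
#' @param nGenes,leaderLen,trailerLen,cdsCodonsRange genome layout.
#' @param periodicLengths,trueOffsets,readsPerLength,phase footprint model.
#' @param noiseLengths,noiseReads non-periodic background lengths.
#' @param startPeak,stopPeak first/last codon weight multipliers.
#' @param geneWeights,rnaWeights per-gene expression weights (default
#'   Zipf `1/rank`; `rnaWeights` defaults to `geneWeights`).
#' @param rnaReads matched RNA-seq library size.
#' @param seed integer seed; every generated file is a deterministic
#'   function of the scenario.
#' @return a [SimScenario-class].
#' @export
simScenario <- function(nGenes = 30L, leaderLen = 60L, trailerLen = 60L,
                        cdsCodonsRange = c(100L, 200L),
                        periodicLengths = c(27L, 28L, 29L),
                        trueOffsets = c("27" = 11L, "28" = 12L,
                                        "29" = 13L),
                        readsPerLength = 5000L, phase = 0.9,
                        noiseLengths = 20:22, noiseReads = 1000L,
                        startPeak = 40, stopPeak = 40,
                        geneWeights = NULL, rnaWeights = NULL,
                        rnaReads = 30000L, seed = 1L) {
    if (is.null(geneWeights)) geneWeights <- 1 / seq_len(nGenes)
    if (is.null(rnaWeights)) rnaWeights <- geneWeights
    new("SimScenario", nGenes = as.integer(nGenes),
        leaderLen = as.integer(leaderLen),
        trailerLen = as.integer(trailerLen),
        cdsCodonsRange = as.integer(cdsCodonsRange),
        periodicLengths = as.integer(periodicLengths),
        trueOffsets = stats::setNames(as.integer(trueOffsets),
                                      names(trueOffsets)),
        readsPerLength = as.integer(readsPerLength),
        phase = as.numeric(phase), noiseLengths = as.integer(noiseLengths),
        noiseReads = as.integer(noiseReads),
        startPeak = as.numeric(startPeak), stopPeak = as.numeric(stopPeak),
        geneWeights = as.numeric(geneWeights),
        rnaWeights = as.numeric(rnaWeights),
        rnaReads = as.integer(rnaReads), seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
    cat(sprintf(paste0("SimScenario: %d genes, periodic lengths %s ",
                       "(offsets %s, phase %.2f, %d reads/length), ",
                       "noise lengths %s, seed %d\n"),
                object@nGenes,
                paste(object@periodicLengths, collapse = ","),
                paste(object@trueOffsets, collapse = ","), object@phase,
                object@readsPerLength,
                paste(object@noiseLengths, collapse = ","), object@seed))
})

SIM_INTRON_LEN <- 150L
SIM_GENE_GAP <- 500L
SIM_RNA_READ_LEN <- 50L

#' Generate a toy annotation
#'
#' Lays out the scenario's genes deterministically on two chromosomes
#' (alternating strands; every third gene carries one intron inside its
#' CDS), writes a GTF parseable by [readAnnotation()] and returns the
#' in-memory [TranscriptSet-class] together with the chromosome lengths
#' needed for BAM headers. The toy genome has no nucleotide sequence:
#' alignment records only need the sequence names and lengths emitted
#' here.
#'
#' @param scn a [SimScenario-class].
#' @param dir output directory for `annotation.gtf`.
#' @return list with elements `ts`, `gtf` (path) and `seqlengths`
#'   (named integer).
#' @export
simulateAnnotation <- function(scn, dir) {
    methods::validObject(scn)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    nc <- withSeed(scn@seed, {
        sample(seq(scn@cdsCodonsRange[1L], scn@cdsCodonsRange[2L]),
               scn@nGenes, replace = TRUE)
    })
    cursors <- c(chrS1 = 1001L, chrS2 = 1001L)
    half <- ceiling(scn@nGenes / 2)
    models <- vector("list", scn@nGenes)
    for (i in seq_len(scn@nGenes)) {
        chrom <- if (i <= half) "chrS1" else "chrS2"
        strand <- if (i %% 2L == 1L) "+" else "-"
        cdsLen <- 3L * nc[i]
        T <- scn@leaderLen + cdsLen + scn@trailerLen
        g <- cursors[[chrom]]
        multi <- i %% 3L == 0L
        if (multi) {
            b <- scn@leaderLen + 90L      # transcript-space exon boundary
            w1 <- b; w2 <- T - b
            widths <- if (strand == "+") c(w1, w2) else c(w2, w1)
            exons <- IRanges::IRanges(
                start = c(g, g + widths[1L] + SIM_INTRON_LEN),
                width = widths)
        } else {
            exons <- IRanges::IRanges(g, width = T)
        }
        models[[i]] <- transcriptModel(
            sprintf("tx%03d", i), sprintf("g%03d", i), chrom, strand,
            exons, cdsStartT = scn@leaderLen + 1L,
            cdsEndT = scn@leaderLen + cdsLen, biotype = "protein_coding")
        cursors[[chrom]] <- max(IRanges::end(exons)) + SIM_GENE_GAP
    }
    ts <- transcriptSet(models)
    rows <- combineGRanges(lapply(models, function(tm) {
        ex <- GRanges(tm@chrom, tm@exons, strand = tm@strand)
        cds <- cdsGenomicRanges(tm)
        mcols(ex)$type <- "exon"
        mcols(ex)$phase <- NA_integer_
        mcols(cds)$type <- "CDS"
        # phase of each CDS block in transcript orientation
        ord <- if (tm@strand == "+") seq_along(cds) else rev(seq_along(cds))
        cum <- c(0L, cumsum(GenomicRanges::width(cds)[ord]))[seq_along(cds)]
        ph <- (3L - cum %% 3L) %% 3L
        mcols(cds)$phase <- ph[order(ord)]
        gr <- c(ex, cds)
        mcols(gr)$source <- "ribocal_sim"
        mcols(gr)$transcript_id <- tm@transcriptId
        mcols(gr)$gene_id <- tm@geneId
        mcols(gr)$gene_biotype <- tm@biotype
        gr
    }))
    gtf <- file.path(dir, "annotation.gtf")
    rtracklayer::export(rows, gtf, format = "gtf")
    sq <- as.character(GenomicRanges::seqnames(rows))
    ends <- GenomicRanges::end(rows)
    chroms <- sort(unique(sq))
    seqlengths <- vapply(chroms, function(ch) max(ends[sq == ch]) + 1000L,
                         0L)
    list(ts = ts, gtf = gtf, seqlengths = seqlengths)
}

# write simulated reads (gene index, transcript 5' end, length) as a
# coordinate-sorted, indexed BAM
writeSimBam <- function(reads, sim, bamPath) {
    models <- sim$ts@transcripts
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sim$seqlengths),
                        as.integer(sim$seqlengths)))
    body <- character(0)
    if (nrow(reads) > 0L) {
        reads$id <- seq_len(nrow(reads))
        parts <- lapply(split(reads, reads$gene), function(sub) {
            tm <- models[[as.integer(sub$gene[1L])]]
            tend <- sub$tpos5 + sub$L - 1L
            gp1 <- transcriptToGenome(sub$tpos5, tm)
            gp2 <- transcriptToGenome(tend, tm)
            left <- pmin(gp1, gp2); right <- pmax(gp1, gp2)
            span <- right - left + 1L
            cigar <- sprintf("%dM", sub$L)
            spliced <- span > sub$L
            if (any(spliced)) {
                ex <- tm@exons
                iStart <- IRanges::end(ex)[1L] + 1L
                iEnd <- IRanges::start(ex)[2L] - 1L
                iLen <- iEnd - iStart + 1L
                w1 <- iStart - left[spliced]
                w2 <- right[spliced] - iEnd
                cigar[spliced] <- sprintf("%dM%dN%dM", w1, iLen, w2)
            }
            flag <- if (tm@strand == "+") 0L else 16L
            data.frame(id = sub$id, chrom = tm@chrom, pos = left,
                       flag = flag, cigar = cigar, L = sub$L,
                       stringsAsFactors = FALSE)
        })
        aln <- do.call(rbind, parts)
        aln <- aln[order(aln$id), , drop = FALSE]
        body <- paste(sprintf("r%07d", aln$id), aln$flag, aln$chrom,
                      aln$pos, 255L, aln$cigar, "*", 0L, 0L,
                      strrep("A", aln$L), strrep("I", aln$L), "NH:i:1",
                      sep = "\t")
    }
    sam <- paste0(tools::file_path_sans_ext(bamPath), ".tmp.sam")
    writeLines(c(header, body), sam)
    on.exit(unlink(sam))
    out <- Rsamtools::asBam(sam, tools::file_path_sans_ext(bamPath),
                            overwrite = TRUE, indexDestination = TRUE)
    invisible(out)
}

sampleFrames <- function(n, phase) {
    sample(0:2, n, replace = TRUE,
           prob = c(phase, (1 - phase) / 2, (1 - phase) / 2))
}

#' Simulate a ribosome-profiling BAM with known ground truth
#'
#' For each periodic length `L`, 5' ends are placed at
#' `codon position - trueOffsets[L]` with codons sampled over the CDS
#' (first/last codon up-weighted by `startPeak`/`stopPeak`) and reading
#' frame jittered per the phase concentration; noise lengths are placed
#' uniformly over transcripts. Genes are drawn with the scenario's
#' expression weights. Sampling order is documented and fixed: periodic
#' lengths ascending, then noise lengths ascending; within a length the
#' gene assignment vector first, then per-gene position draws in gene
#' order. Output is coordinate-sorted and indexed; repeated calls with
#' the same scenario produce identical files.
#'
#' @param scn a [SimScenario-class].
#' @param sim result of [simulateAnnotation()] for the same scenario.
#' @param bamPath output BAM path.
#' @return the BAM path, invisibly.
#' @export
simulateFootprints <- function(scn, sim, bamPath) {
    models <- sim$ts@transcripts
    reads <- withSeed(scn@seed + 1000003L, {
        acc <- list()
        for (L in sort(scn@periodicLengths)) {
            off <- scn@trueOffsets[[as.character(L)]]
            gi <- sample.int(scn@nGenes, scn@readsPerLength,
                             replace = TRUE, prob = scn@geneWeights)
            for (g in sort(unique(gi))) {
                tm <- models[[g]]
                m <- sum(gi == g)
                ncod <- cdsLength(tm) %/% 3L
                cw <- rep(1, ncod)
                cw[1L] <- scn@startPeak; cw[ncod] <- scn@stopPeak
                codon <- sample.int(ncod, m, replace = TRUE, prob = cw)
                fr <- sampleFrames(m, scn@phase)
                tpos5 <- tm@cdsStartT + 3L * (codon - 1L) + fr - off
                acc[[length(acc) + 1L]] <-
                    data.frame(gene = g, tpos5 = tpos5, L = L)
            }
        }
        for (L in sort(scn@noiseLengths)) {
            gi <- sample.int(scn@nGenes, scn@noiseReads, replace = TRUE,
                             prob = scn@geneWeights)
            for (g in sort(unique(gi))) {
                tm <- models[[g]]
                m <- sum(gi == g)
                tpos5 <- sample.int(txLength(tm) - L + 1L, m,
                                    replace = TRUE)
                acc[[length(acc) + 1L]] <-
                    data.frame(gene = g, tpos5 = tpos5, L = L)
            }
        }
        do.call(rbind, acc)
    })
    bad <- reads$tpos5 < 1L
    if (any(bad)) reads <- reads[!bad, , drop = FALSE]
    writeSimBam(reads, sim, bamPath)
    invisible(bamPath)
}

#' Simulate a matched RNA-seq BAM
#'
#' Uniform, non-periodic coverage: fixed-length reads placed uniformly
#' over each transcript, genes drawn with the scenario's RNA weights.
#' Deterministic under the scenario seed; zero `rnaReads` yields a valid
#' empty BAM.
#'
#' @param scn a [SimScenario-class].
#' @param sim result of [simulateAnnotation()].
#' @param bamPath output BAM path.
#' @return the BAM path, invisibly.
#' @export
simulateRnaSeq <- function(scn, sim, bamPath) {
    models <- sim$ts@transcripts
    reads <- withSeed(scn@seed + 2000003L, {
        if (scn@rnaReads == 0L) {
            data.frame(gene = integer(), tpos5 = integer(), L = integer())
        } else {
            gi <- sample.int(scn@nGenes, scn@rnaReads, replace = TRUE,
                             prob = scn@rnaWeights)
            acc <- list()
            for (g in sort(unique(gi))) {
                tm <- models[[g]]
                m <- sum(gi == g)
                tpos5 <- sample.int(txLength(tm) - SIM_RNA_READ_LEN + 1L,
                                    m, replace = TRUE)
                acc[[length(acc) + 1L]] <- data.frame(
                    gene = g, tpos5 = tpos5, L = SIM_RNA_READ_LEN)
            }
            do.call(rbind, acc)
        }
    })
    writeSimBam(reads, sim, bamPath)
    invisible(bamPath)
}
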