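#' Construct a transcript model
#'
#' Builds a [TranscriptModel-class] from genomic exon intervals and
#' (optionally) the CDS span in transcript coordinates. Used directly in
#' tests and by the simulator; files are read with [readAnnotation()].
#'
#' @param transcriptId,geneId identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons an [IRanges::IRanges] of exon intervals, genomic order.
#' @param cdsStartT,cdsEndT CDS bounds in transcript coordinates (1-based,
#'   closed), or `NA` for a non-coding transcript.
#' @param biotype annotation biotype string.
#' @return a `TranscriptModel`.
#' @examples
#' tm <- transcriptModel("t1", "g1", "chr1", "+",
#'                       IRanges::IRanges(c(1, 201), c(100, 300)),
#'                       cdsStartT = 51, cdsEndT = 150)
#' txLength(tm)
#' @export
transcriptModel <- function(transcriptId, geneId, chrom, strand, exons,
                            cdsStartT = NA_integer_, cdsEndT = NA_integer_,
                            biotype = NA_character_) {
    new("TranscriptModel", transcriptId = as.character(transcriptId),
        geneId = as.character(geneId), chrom = as.character(chrom),
        strand = as.character(strand), exons = exons,
        cdsStartT = as.integer(cdsStartT), cdsEndT = as.integer(cdsEndT),
        biotype = as.character(biotype))
}

#' @rdname TranscriptModel-class
#' @aliases txLength,TranscriptModel-method
setMethod("txLength", "TranscriptModel",
          function(x) sum(IRanges::width(x@exons)))

#' @rdname TranscriptModel-class
#' @aliases isCoding,TranscriptModel-method
setMethod("isCoding", "TranscriptModel", function(x) !is.na(x@cdsStartT))

#' @rdname TranscriptModel-class
#' @aliases cdsLength,TranscriptModel-method
setMethod("cdsLength", "TranscriptModel", function(x) {
    if (!isCoding(x)) return(0L)
    x@cdsEndT - x@cdsStartT + 1L
})

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel %s (gene %s) %s:%s, %d exon(s), %d nt%s\n",
                object@transcriptId, object@geneId, object@chrom,
                object@strand, length(object@exons), txLength(object),
                if (isCoding(object))
                    sprintf(", CDS %d..%d", object@cdsStartT, object@cdsEndT)
                else ", non-coding"))
})

#' Map genomic positions into transcript coordinates
#'
#' Transcript coordinates are 1-based and count from the transcript 5' end,
#' so on the minus strand the genomic right end of the transcript maps to
#' position 1. Intronic or out-of-transcript positions map to `NA`.
#'
#' @param pos integer vector of genomic positions (1-based).
#' @param tm a [TranscriptModel-class].
#' @return integer vector of transcript positions (`NA` where unmapped).
#' @seealso [transcriptToGenome()] for the inverse on exonic positions.
#' @export
genomeToTranscript <- function(pos, tm) {
    ex <- tm@exons
    w <- IRanges::width(ex)
    offs <- c(0L, cumsum(w)[-length(w)])
    hit <- findInterval(pos, IRanges::start(ex))
    tplus <- rep(NA_integer_, length(pos))
    ok <- hit >= 1L & pos <= IRanges::end(ex)[pmax(hit, 1L)]
    tplus[ok] <- offs[hit[ok]] + (pos[ok] - IRanges::start(ex)[hit[ok]]) + 1L
    if (tm@strand == "-") {
        tl <- sum(w)
        tl - tplus + 1L
    } else tplus
}

#' Map transcript positions back to the genome
#'
#' Exact inverse of [genomeToTranscript()] on exonic positions.
#'
#' @param tpos integer vector of transcript positions, each in
#'   `1..txLength(tm)`; out-of-range values are an error.
#' @param tm a [TranscriptModel-class].
#' @return integer vector of genomic positions.
#' @export
transcriptToGenome <- function(tpos, tm) {
    tl <- txLength(tm)
    if (any(is.na(tpos)) || any(tpos < 1L) || any(tpos > tl))
        stop(sprintf("transcript position out of range 1..%d for %s",
                     tl, tm@transcriptId))
    tplus <- if (tm@strand == "-") tl - tpos + 1L else as.integer(tpos)
    ex <- tm@exons
    cums <- cumsum(IRanges::width(ex))
    offs <- c(0L, cums[-length(cums)])
    j <- findInterval(tplus - 1L, cums) + 1L
    IRanges::start(ex)[j] + (tplus - offs[j] - 1L)
}

#' Classify transcript positions into transcript regions
#'
#' @param tpos integer vector of transcript positions (1-based).
#' @param tm a [TranscriptModel-class].
#' @return character vector with values `"five_prime_leader"`, `"cds"`,
#'   `"three_prime_trailer"` or `"noncoding"`. For coding transcripts the
#'   three regions partition the transcript; the first base after the CDS
#'   is trailer.
#' @export
classifyRegion <- function(tpos, tm) {
    tl <- txLength(tm)
    if (any(is.na(tpos)) || any(tpos < 1L) || any(tpos > tl))
        stop(sprintf("transcript position out of range 1..%d for %s",
                     tl, tm@transcriptId))
    if (!isCoding(tm)) return(rep("noncoding", length(tpos)))
    out <- rep("cds", length(tpos))
    out[tpos < tm@cdsStartT] <- "five_prime_leader"
    out[tpos > tm@cdsEndT] <- "three_prime_trailer"
    out
}

# genomic intervals covered by the CDS of a coding transcript
cdsGenomicRanges <- function(tm) {
    stopifnot(isCoding(tm))
    gends <- transcriptToGenome(c(tm@cdsStartT, tm@cdsEndT), tm)
    span <- IRanges::IRanges(min(gends), max(gends))
    GRanges(tm@chrom, IRanges::intersect(tm@exons, span),
            strand = tm@strand)
}

#' Assemble a TranscriptSet from transcript models
#'
#' Builds the gene index, the exon interval index and the
#' representative-transcript map (per gene: longest CDS, ties broken by
#' lexicographic transcript id; for genes without a coding transcript the
#' longest transcript).
#'
#' @param models list of [TranscriptModel-class] objects.
#' @return a [TranscriptSet-class].
#' @export
transcriptSet <- function(models) {
    ids <- vapply(models, function(m) m@transcriptId, "")
    names(models) <- ids
    genes <- vapply(models, function(m) m@geneId, "")
    geneIndex <- split(ids, genes)
    exGr <- combineGRanges(lapply(models, function(m) {
        g <- GRanges(m@chrom, m@exons, strand = m@strand)
        mcols(g)$transcript_id <- m@transcriptId
        mcols(g)$gene_id <- m@geneId
        g
    }))
    repTx <- vapply(geneIndex, function(txs) {
        cl <- vapply(models[txs], cdsLength, 0L)
        if (all(cl == 0L)) {
            tl <- vapply(models[txs], txLength, 0L)
            txs[order(-tl, txs)][1L]
        } else txs[order(-cl, txs)][1L]
    }, "")
    new("TranscriptSet", transcripts = models, geneIndex = geneIndex,
        exons = exGr, repTx = repTx)
}

#' @rdname TranscriptSet-class
#' @aliases transcriptIds,TranscriptSet-method
setMethod("transcriptIds", "TranscriptSet",
          function(x) names(x@transcripts))

#' @rdname TranscriptSet-class
#' @aliases geneIds,TranscriptSet-method
setMethod("geneIds", "TranscriptSet", function(x) names(x@geneIndex))

#' @rdname TranscriptSet-class
#' @aliases representativeTranscripts,TranscriptSet-method
setMethod("representativeTranscripts", "TranscriptSet",
          function(x) x@repTx)

setMethod("show", "TranscriptSet", function(object) {
    nc <- sum(vapply(object@transcripts, isCoding, TRUE))
    cat(sprintf("TranscriptSet: %d transcripts (%d coding), %d genes, %d chromosome(s)\n",
                length(object@transcripts), nc, length(object@geneIndex),
                length(unique(as.character(
                    GenomicRanges::seqnames(object@exons))))))
})

#' Fetch one transcript model
#'
#' @param ts a [TranscriptSet-class].
#' @param id transcript id.
#' @return the [TranscriptModel-class].
#' @export
getTranscript <- function(ts, id) {
    tm <- ts@transcripts[[id]]
    if (is.null(tm)) stop(sprintf("unknown transcript '%s'", id))
    tm
}

# representative transcript model of a gene
repModel <- function(ts, gene) {
    id <- ts@repTx[[gene]]
    if (is.null(id)) stop(sprintf("unknown gene '%s'", gene))
    ts@transcripts[[id]]
}

# gene ids whose representative transcript is coding
codingGenes <- function(ts) {
    g <- geneIds(ts)
    g[vapply(g, function(x) isCoding(repModel(ts, x)), TRUE)]
}

sniffAnnotationFormat <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("gtf", "gff")) return("gtf")
    if (ext == "bed") return("bed12")
    lines <- readLines(path, n = 50L)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(lines) == 0L)
        stop(sprintf("cannot auto-detect annotation format of '%s': no data lines",
                     path))
    nf <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
    if (nf >= 9L) "gtf" else if (nf == 12L) "bed12"
    else stop(sprintf("cannot auto-detect annotation format of '%s'", path))
}

# minimal structural pre-validation so that errors carry line numbers,
# which rtracklayer's parser does not always provide
validateGtfLines <- function(path) {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln) || startsWith(ln, "#")) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(f) < 9L)
            stop(sprintf("malformed GTF line %d in '%s': expected 9 tab-separated fields, got %d",
                         i, path, length(f)))
        if (is.na(suppressWarnings(as.integer(f[4L]))) ||
            is.na(suppressWarnings(as.integer(f[5L]))))
            stop(sprintf("malformed GTF line %d in '%s': non-numeric coordinates",
                         i, path))
        if (f[3L] %in% c("exon", "CDS") &&
            !grepl("transcript_id", f[9L], fixed = TRUE))
            stop(sprintf("GTF line %d in '%s': %s feature without transcript_id",
                         i, path, f[3L]))
    }
    invisible(TRUE)
}

validateBedLines <- function(path, ncol) {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln) || grepl("^(#|track|browser)", ln)) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(f) < ncol)
            stop(sprintf("malformed BED line %d in '%s': expected >= %d fields, got %d",
                         i, path, ncol, length(f)))
        if (is.na(suppressWarnings(as.integer(f[2L]))) ||
            is.na(suppressWarnings(as.integer(f[3L]))))
            stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                         i, path))
    }
    invisible(TRUE)
}

gtfBiotype <- function(meta) {
    for (col in c("transcript_biotype", "gene_biotype", "transcript_type",
                  "gene_type"))
        if (!is.null(meta[[col]]) && !is.na(meta[[col]][1L]))
            return(as.character(meta[[col]][1L]))
    NA_character_
}

parseGtfAnnotation <- function(path) {
    validateGtfLines(path)
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type %in% c("exon", "CDS")]
    if (length(gr) == 0L)
        stop(sprintf("no exon features found in '%s'", path))
    if (any(is.na(gr$transcript_id)))
        stop(sprintf("feature without transcript_id in '%s'", path))
    byTx <- split(seq_along(gr), gr$transcript_id)
    models <- lapply(names(byTx), function(txid) {
        sub <- gr[byTx[[txid]]]
        ex <- sub[sub$type == "exon"]
        if (length(ex) == 0L)
            stop(sprintf("transcript '%s' in '%s' has CDS but no exon features",
                         txid, path))
        o <- order(GenomicRanges::start(ex))
        exr <- IRanges::IRanges(GenomicRanges::start(ex)[o],
                                GenomicRanges::end(ex)[o])
        strand <- as.character(GenomicRanges::strand(ex))[1L]
        chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
        gid <- as.character(ex$gene_id[1L])
        if (is.na(gid)) gid <- txid
        tm <- transcriptModel(txid, gid, chrom, strand, exr,
                              biotype = gtfBiotype(mcols(ex)))
        cds <- sub[sub$type == "CDS"]
        if (length(cds) > 0L) {
            gends <- c(min(GenomicRanges::start(cds)),
                       max(GenomicRanges::end(cds)))
            tp <- genomeToTranscript(gends, tm)
            if (any(is.na(tp)))
                stop(sprintf("CDS of transcript '%s' in '%s' falls outside its exons",
                             txid, path))
            tm@cdsStartT <- min(tp)
            tm@cdsEndT <- max(tp)
            methods::validObject(tm)
        }
        tm
    })
    transcriptSet(models)
}

parseBed12Annotation <- function(path) {
    validateBedLines(path, 12L)
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop(sprintf("no records in '%s'", path))
    if (is.null(gr$blocks))
        stop(sprintf("'%s' is not BED12: block structure missing", path))
    models <- lapply(seq_along(gr), function(i) {
        rec <- gr[i]
        blocks <- gr$blocks[[i]]   # exon intervals relative to chromStart
        exr <- IRanges::shift(blocks, GenomicRanges::start(rec) - 1L)
        strand <- as.character(GenomicRanges::strand(rec))
        if (!strand %in% c("+", "-")) strand <- "+"
        txid <- if (!is.null(rec$name) && !is.na(rec$name)) rec$name
                else sprintf("bed_record_%d", i)
        tm <- transcriptModel(txid, txid,
                              as.character(GenomicRanges::seqnames(rec)),
                              strand, exr)
        thick <- gr$thick[i]
        if (!is.null(thick) && IRanges::width(thick) > 0L) {
            tp <- genomeToTranscript(c(IRanges::start(thick),
                                       IRanges::end(thick)), tm)
            if (any(is.na(tp)))
                stop(sprintf("thick region of '%s' in '%s' falls outside its blocks",
                             txid, path))
            tm@cdsStartT <- min(tp)
            tm@cdsEndT <- max(tp)
            methods::validObject(tm)
        }
        tm
    })
    transcriptSet(models)
}

#' Read a transcript annotation
#'
#' Parses an Ensembl-style GTF (exon and optional CDS features carrying
#' `transcript_id`/`gene_id` attributes) or a BED12 file into a
#' [TranscriptSet-class]. GTF and BED12 representations of the same
#' transcript parse to identical models. BED12 records use their `name`
#' field as both transcript and gene id (BED carries no gene grouping).
#'
#' @param path annotation file.
#' @param format `"gtf"`, `"bed12"` or `"auto"` (extension, then content
#'   sniffing).
#' @return a [TranscriptSet-class].
#' @export
readAnnotation <- function(path, format = c("auto", "gtf", "bed12")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop(sprintf("annotation file '%s' not found", path))
    if (format == "auto") format <- sniffAnnotationFormat(path)
    switch(format,
           gtf = parseGtfAnnotation(path),
           bed12 = parseBed12Annotation(path))
}

#' Read a mask annotation
#'
#' Loads genomic regions (e.g. rRNA genes, repeats) to be excluded from all
#' analyses. Intervals are merged and strand is discarded: masking removes
#' reads regardless of strand.
#'
#' @param path BED or GTF file; an empty file yields an empty (no-op) mask.
#' @param format `"bed"`, `"gtf"` or `"auto"`.
#' @return a [MaskSet-class].
#' @export
readMask <- function(path, format = c("auto", "gtf", "bed")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop(sprintf("mask file '%s' not found", path))
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
    }
    lines <- readLines(path)
    dataLines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(dataLines) == 0L) {
        return(new("MaskSet", ranges = GRanges(), source = path))
    }
    if (format == "gtf") validateGtfLines(path) else validateBedLines(path, 3L)
    gr <- rtracklayer::import(path, format = format)
    merged <- GenomicRanges::reduce(granges(gr), ignore.strand = TRUE)
    GenomicRanges::strand(merged) <- "*"
    new("MaskSet", ranges = merged, source = path)
}

#' @rdname MaskSet-class
#' @aliases maskRanges,MaskSet-method
setMethod("maskRanges", "MaskSet", function(x) x@ranges)

setMethod("show", "MaskSet", function(object) {
    cat(sprintf("MaskSet: %d merged interval(s), %d nt total (from %s)\n",
                length(object@ranges),
                sum(IRanges::width(object@ranges)), object@source))
})
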