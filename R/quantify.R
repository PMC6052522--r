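regionCategories <- c("cds", "five_prime_leader", "three_prime_trailer",
                      "intron", "noncoding_transcript", "intergenic")

# classify indexed positions against representative transcripts;
# returns a character vector of categories per row of cnt
classifyPositions <- function(cnt, ts) {
    out <- rep("intergenic", nrow(cnt))
    if (nrow(cnt) == 0L) return(out)
    rex <- repExonRanges(ts)
    posGr <- GRanges(cnt$chrom, IRanges::IRanges(cnt$pos, cnt$pos),
                     strand = cnt$strand)
    ov <- GenomicRanges::findOverlaps(posGr, rex)
    qh <- S4Vectors::queryHits(ov)
    txh <- mcols(rex)$transcript_id[S4Vectors::subjectHits(ov)]
    o <- order(qh, txh)
    first <- !duplicated(qh[o])
    qh <- qh[o][first]; txh <- txh[o][first]
    for (tx in unique(txh)) {
        sel <- txh == tx
        tm <- ts@transcripts[[tx]]
        tpos <- genomeToTranscript(cnt$pos[qh[sel]], tm)
        reg <- classifyRegion(tpos, tm)
        reg[reg == "noncoding"] <- "noncoding_transcript"
        out[qh[sel]] <- reg
    }
    # exon misses inside a representative transcript's genomic span: intron
    rest <- setdiff(seq_len(nrow(cnt)), qh)
    if (length(rest) > 0L) {
        spans <- unlist(range(
            S4Vectors::split(rex, mcols(rex)$transcript_id)))
        inSpan <- IRanges::overlapsAny(posGr[rest], spans,
                                             ignore.strand = FALSE)
        out[rest[inSpan]] <- "intron"
    }
    out
}

#' Region summary statistics
#'
#' Assigns every counted read (optionally restricted to selected lengths
#' and shifted by calibrated offsets) to exactly one transcript region via
#' its representative transcript: `cds`, `five_prime_leader`,
#' `three_prime_trailer`, `intron` (within a representative transcript's
#' span but not exonic), `noncoding_transcript` (exonic on a non-coding
#' representative) or `intergenic`. Recompute after length/offset selection
#' to see how the composition changes.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param lengths optional read-length filter.
#' @param offsets optional [OffsetTable-class]; lengths present in the
#'   table are shifted to P-site positions first.
#' @return a [SummaryStats-class].
#' @export
regionStats <- function(idx, ts, lengths = NULL, offsets = NULL) {
    cnt <- endCounts(idx)
    if (!is.null(lengths))
        cnt <- cnt[cnt$length %in% lengths, , drop = FALSE]
    if (!is.null(offsets) && nrow(cnt) > 0L) {
        tab <- offsets@table
        known <- tab$length[!is.na(tab$offset)]
        sel <- cnt$length %in% known
        cnt[sel, ] <- shiftPositions(cnt[sel, , drop = FALSE], offsets)
    }
    cat0 <- classifyPositions(cnt, ts)
    lens <- sort(unique(cnt$length))
    mkRow <- function(sub, subCat) {
        vapply(regionCategories,
               function(k) sum(sub$count[subCat == k]), 0)
    }
    rows <- lapply(lens, function(L) {
        sel <- cnt$length == L
        mkRow(cnt[sel, , drop = FALSE], cat0[sel])
    })
    tab <- as.data.frame(do.call(rbind, c(rows, list(mkRow(cnt, cat0)))))
    tab <- cbind(data.frame(length = c(as.character(lens), "all"),
                            stringsAsFactors = FALSE), tab)
    rownames(tab) <- NULL
    new("SummaryStats", perLength = tab, masked = idx@masked,
        multimapped = idx@multimapped, deselected = idx@deselected,
        policyExcluded = idx@policyExcluded)
}

#' @rdname SummaryStats-class
#' @aliases regionCounts,SummaryStats-method
setMethod("regionCounts", "SummaryStats", function(x) x@perLength)

setMethod("show", "SummaryStats", function(object) {
    cat("SummaryStats (reads per region):\n")
    print(object@perLength, row.names = FALSE)
    cat(sprintf("masked %d | deselected %d | policy-excluded %d | multimapped %d\n",
                object@masked, object@deselected, object@policyExcluded,
                object@multimapped))
})

#' Write region summary statistics as TSV
#'
#' @param stats a [SummaryStats-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSummaryStats <- function(stats, path) {
    writeTsv(regionCounts(stats), path)
}

#' Per-gene RPKM expression table
#'
#' Reads per kilobase of feature per million counted reads. For ribosome
#' profiling (`mode = "ribo"`) the feature is the representative CDS and
#' counts are (optionally offset-shifted) P-site hits of the selected
#' lengths; for RNA-seq (`mode = "rna"`) the feature is the representative
#' transcript's exons and raw 5' ends of all lengths are counted. The
#' million-read denominator is all reads surviving filtering (the summed
#' counts after the optional length restriction), so RPKM is invariant
#' under uniform scaling of the library.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param lengths optional read-length filter (the selected periodic set).
#' @param offsets optional [OffsetTable-class] applied before counting.
#' @param mode `"ribo"` or `"rna"`.
#' @return data.frame with columns `gene_id`, `count`, `length_kb`,
#'   `rpkm`, sorted by gene id.
#' @export
rpkmTable <- function(idx, ts, lengths = NULL, offsets = NULL,
                      mode = c("ribo", "rna")) {
    mode <- match.arg(mode)
    cnt <- endCounts(idx)
    if (!is.null(lengths))
        cnt <- cnt[cnt$length %in% lengths, , drop = FALSE]
    if (!is.null(offsets) && nrow(cnt) > 0L) {
        tab <- offsets@table
        known <- tab$length[!is.na(tab$offset)]
        sel <- cnt$length %in% known
        cnt[sel, ] <- shiftPositions(cnt[sel, , drop = FALSE], offsets)
    }
    total <- sum(cnt$count)
    if (total <= 0) stop("no counted reads; cannot compute RPKM")
    genes <- sort(codingGenes(ts))
    featGr <- combineGRanges(lapply(genes, function(g) {
        tm <- repModel(ts, g)
        gr <- if (mode == "ribo") cdsGenomicRanges(tm)
              else GRanges(tm@chrom, tm@exons, strand = tm@strand)
        mcols(gr) <- NULL
        mcols(gr)$gene_id <- g
        gr
    }))
    kb <- vapply(genes, function(g) {
        tm <- repModel(ts, g)
        (if (mode == "ribo") cdsLength(tm) else txLength(tm)) / 1000
    }, 0)
    bad <- kb <= 0
    if (any(bad)) {
        warning(sprintf("skipping gene(s) with zero-length feature: %s",
                        paste(genes[bad], collapse = ", ")))
        genes <- genes[!bad]; kb <- kb[!bad]
        featGr <- featGr[mcols(featGr)$gene_id %in% genes]
    }
    gcount <- stats::setNames(numeric(length(genes)), genes)
    if (nrow(cnt) > 0L) {
        posGr <- GRanges(cnt$chrom, IRanges::IRanges(cnt$pos, cnt$pos),
                         strand = cnt$strand)
        ov <- GenomicRanges::findOverlaps(posGr, featGr)
        if (length(ov) > 0L) {
            per <- rowsum(cnt$count[S4Vectors::queryHits(ov)],
                          mcols(featGr)$gene_id[S4Vectors::subjectHits(ov)])
            gcount[rownames(per)] <- per[, 1L]
        }
    }
    data.frame(gene_id = genes, count = as.numeric(gcount),
               length_kb = as.numeric(kb),
               rpkm = as.numeric(gcount) / (kb * total / 1e6),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Translational efficiency per gene
#'
#' Ratio of ribosome-footprint RPKM to RNA-seq RPKM over the genes shared
#' by the two tables. Genes with zero RNA RPKM get an `NA` efficiency and
#' `te_defined = FALSE`.
#'
#' @param ribo,rna RPKM tables from [rpkmTable()].
#' @return data.frame with columns `gene_id`, `ribo_rpkm`, `rna_rpkm`,
#'   `te`, `te_defined`.
#' @export
translationalEfficiency <- function(ribo, rna) {
    shared <- intersect(ribo$gene_id, rna$gene_id)
    if (length(shared) == 0L)
        stop("no genes shared between ribosome profiling and RNA-seq tables")
    shared <- sort(shared)
    rb <- ribo$rpkm[match(shared, ribo$gene_id)]
    rn <- rna$rpkm[match(shared, rna$gene_id)]
    ok <- rn > 0
    data.frame(gene_id = shared, ribo_rpkm = rb, rna_rpkm = rn,
               te = ifelse(ok, rb / rn, NA_real_), te_defined = ok,
               stringsAsFactors = FALSE)
}
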