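#' Construct a 5' end index from a count table
#'
#' Programmatic constructor used by tests and by code that composes indices
#' without going through a BAM file. Duplicate keys are aggregated.
#'
#' @param counts data.frame with columns `length`, `chrom`, `strand`, `pos`
#'   and optionally `count` (default 1 per row).
#' @param totalReads,multimapped,masked,deselected,policyExcluded library
#'   tallies; `totalReads` defaults to the summed counts.
#' @return a [FivePrimeEndIndex-class].
#' @export
fivePrimeEndIndex <- function(counts, totalReads = NULL, multimapped = 0L,
                              masked = 0L, deselected = 0L,
                              policyExcluded = 0L) {
    agg <- aggregateEndCounts(counts)
    total <- sum(agg$count)
    if (is.null(totalReads))
        totalReads <- total + masked + deselected + policyExcluded
    new("FivePrimeEndIndex", counts = agg,
        totalReads = as.integer(totalReads),
        totalAfterMask = as.integer(total),
        multimapped = as.integer(multimapped),
        masked = as.integer(masked), deselected = as.integer(deselected),
        policyExcluded = as.integer(policyExcluded))
}

#' @rdname FivePrimeEndIndex-class
#' @aliases endCounts,FivePrimeEndIndex-method
setMethod("endCounts", "FivePrimeEndIndex", function(x) x@counts)

setMethod("show", "FivePrimeEndIndex", function(object) {
    ls <- sort(unique(object@counts$length))
    cat(sprintf(paste0("FivePrimeEndIndex: %d reads at %d positions, ",
                       "lengths %s\n  mapped seen %d | masked %d | ",
                       "deselected %d | policy-excluded %d | multimapped %d\n"),
                object@totalAfterMask, nrow(object@counts),
                if (length(ls)) paste(range(ls), collapse = "-") else "-",
                object@totalReads, object@masked, object@deselected,
                object@policyExcluded, object@multimapped))
})

bamIndexPath <- function(bam) {
    cand <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
    cand[file.exists(cand)][1L]
}

#' Build the per-length 5' end index from a BAM file
#'
#' Streams mapped alignments from a coordinate-sorted, indexed BAM,
#' applies the multimapper policy, the optional mask and gene deselection,
#' and tallies footprint 5' ends by (read length, chromosome, strand,
#' position). Read length is the aligned query length (`qwidth`, i.e.
#' M/I/S-consuming bases); the 5' end is the first aligned reference base
#' (leftmost for `+`, rightmost for `-`), so soft-clipped bases do not
#' shift it. The mask is tested against the 5' end position only; gene
#' deselection removes reads whose alignment span overlaps an exon of a
#' deselected gene. Filters apply in the order policy, mask, deselection.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param ts a [TranscriptSet-class] (used for gene deselection and for
#'   chromosome-name diagnostics).
#' @param mask optional [MaskSet-class].
#' @param deselect character vector of gene ids to remove.
#' @param multimapperPolicy `"primary_only"` (drop secondary/supplementary
#'   records, keep primary alignments of multimappers but tally them),
#'   `"all"` (keep every mapped record) or `"none"` (additionally drop
#'   reads whose NH tag reports multiple hits).
#' @return a [FivePrimeEndIndex-class].
#' @export
buildEndIndex <- function(bam, ts, mask = NULL, deselect = character(),
                          multimapperPolicy = c("primary_only", "all",
                                                "none")) {
    multimapperPolicy <- match.arg(multimapperPolicy)
    if (!file.exists(bam)) stop(sprintf("BAM file '%s' not found", bam))
    if (is.na(bamIndexPath(bam)))
        stop(sprintf("BAM index (.bai) for '%s' not found; coordinate-sort and index the file",
                     bam))
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    tsChroms <- unique(as.character(GenomicRanges::seqnames(ts@exons)))
    if (length(hdr) > 0L && length(tsChroms) > 0L &&
        length(intersect(names(hdr), tsChroms)) == 0L)
        warning(sprintf(paste0("no chromosome names shared between BAM and ",
                               "annotation.\n  BAM: %s\n  annotation: %s"),
                        paste(utils::head(names(hdr), 10L), collapse = ", "),
                        paste(utils::head(tsChroms, 10L), collapse = ", ")))
    param <- Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
        what = "flag", tag = "NH")
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    totalReads <- length(ga)
    if (totalReads == 0L) {
        warning(sprintf("no mapped reads in '%s'; returning an empty index", bam))
        return(fivePrimeEndIndex(data.frame(length = integer(),
                                            chrom = character(),
                                            strand = character(),
                                            pos = integer())))
    }
    flag <- mcols(ga)$flag
    nh <- mcols(ga)$NH
    if (is.null(nh)) nh <- rep(NA_integer_, totalReads)
    secondary <- bitwAnd(flag, 256L) > 0L
    supplementary <- bitwAnd(flag, 2048L) > 0L
    multi <- secondary | supplementary | (!is.na(nh) & nh > 1L)
    keep <- switch(multimapperPolicy,
        primary_only = !(secondary | supplementary),
        all = rep(TRUE, totalReads),
        none = !(secondary | supplementary) & !(!is.na(nh) & nh > 1L))
    policyExcluded <- sum(!keep)
    multimapped <- sum(multi)
    ga <- ga[keep]

    str <- as.character(GenomicAlignments::strand(ga))
    pos5 <- ifelse(str == "+", GenomicAlignments::start(ga),
                   GenomicAlignments::end(ga))
    df <- data.frame(
        length = GenomicAlignments::qwidth(ga),
        chrom = as.character(GenomicAlignments::seqnames(ga)),
        strand = str, pos = pos5, stringsAsFactors = FALSE)

    maskedN <- 0L
    if (!is.null(mask) && length(maskRanges(mask)) > 0L && nrow(df) > 0L) {
        hit <- IRanges::overlapsAny(
            GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos)),
            maskRanges(mask), ignore.strand = TRUE)
        maskedN <- sum(hit)
        df <- df[!hit, , drop = FALSE]
        ga <- ga[!hit]
    }

    deselectedN <- 0L
    if (length(deselect) > 0L && nrow(df) > 0L) {
        desExons <- ts@exons[mcols(ts@exons)$gene_id %in% deselect]
        if (length(desExons) > 0L) {
            hit <- IRanges::overlapsAny(granges(ga), desExons,
                                              ignore.strand = TRUE)
            deselectedN <- sum(hit)
            df <- df[!hit, , drop = FALSE]
        }
    }

    fivePrimeEndIndex(df, totalReads = totalReads,
                      multimapped = multimapped, masked = maskedN,
                      deselected = deselectedN,
                      policyExcluded = policyExcluded)
}

#' Read-length histogram of an index
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @return data.frame with columns `length` and `count`, sorted by length;
#'   counts sum to the index's reads after filtering.
#' @export
lengthHistogram <- function(idx) {
    cnt <- endCounts(idx)
    if (nrow(cnt) == 0L)
        return(data.frame(length = integer(), count = integer()))
    agg <- rowsum(cnt$count, cnt$length)
    data.frame(length = as.integer(rownames(agg)),
               count = as.integer(agg[, 1L]))
}

#' Rank coding genes by CDS coverage and keep the top fraction
#'
#' Protein-coding genes are ranked by the total 5' end count (all read
#' lengths) falling inside the CDS of their representative transcript;
#' the top `ceiling(fraction * n)` genes are returned, ties at the cutoff
#' broken by lexicographic gene id. These genes anchor the periodicity
#' and metagene computations.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param fraction proportion of coding genes to keep (default 0.1).
#' @return character vector of gene ids, ordered by decreasing coverage.
#' @export
selectTopGenes <- function(idx, ts, fraction = 0.1) {
    stopifnot(fraction > 0, fraction <= 1)
    genes <- codingGenes(ts)
    if (length(genes) == 0L)
        stop("annotation contains no protein-coding genes")
    cdsGr <- combineGRanges(lapply(genes, function(g) {
        gr <- cdsGenomicRanges(repModel(ts, g))
        mcols(gr)$gene_id <- g
        gr
    }))
    cnt <- endCounts(idx)
    total <- stats::setNames(numeric(length(genes)), genes)
    if (nrow(cnt) > 0L) {
        posGr <- GRanges(cnt$chrom, IRanges::IRanges(cnt$pos, cnt$pos),
                         strand = cnt$strand)
        ov <- GenomicRanges::findOverlaps(posGr, cdsGr)
        if (length(ov) > 0L) {
            per <- rowsum(cnt$count[S4Vectors::queryHits(ov)],
                          mcols(cdsGr)$gene_id[S4Vectors::subjectHits(ov)])
            total[rownames(per)] <- per[, 1L]
        }
    }
    ord <- order(-total, names(total))
    k <- ceiling(fraction * length(genes))
    names(total)[ord][seq_len(k)]
}
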