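# representative-transcript exon index: GRanges with transcript_id mcol,
# restricted to one transcript per gene
repExonRanges <- function(ts) {
    ts@exons[mcols(ts@exons)$transcript_id %in% ts@repTx]
}

# shift 5' end positions by per-length offsets towards 3'
shiftPositions <- function(cnt, ot) {
    off <- ot@table$offset[match(cnt$length, ot@table$length)]
    cnt$pos <- cnt$pos + ifelse(cnt$strand == "+", off, -off)
    cnt
}

#' P-site coverage tracks
#'
#' Shifts every 5' end by its length's offset towards the 3' end of the
#' read (rightwards on `+`, leftwards on `-`) and accumulates P-site
#' counts, either in genomic coordinates or mapped through representative
#' transcripts into transcript coordinates. Lengths without a calibrated
#' offset are excluded with a warning. In transcriptomic space, shifted
#' positions not on a representative transcript's exons are dropped and
#' tallied in the track's `droppedReads`; positions on several
#' representative transcripts are assigned to the lexicographically
#' smallest transcript id.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param offsets an [OffsetTable-class].
#' @param ts a [TranscriptSet-class].
#' @param space `"genomic"` or `"transcriptomic"`.
#' @param perLength when `TRUE`, return a named list with one track per
#'   read length; the merged track is their position-wise sum.
#' @return a [CoverageTrack-class], or a named list of them.
#' @export
psiteTrack <- function(idx, offsets, ts,
                       space = c("genomic", "transcriptomic"),
                       perLength = FALSE) {
    space <- match.arg(space)
    tab <- offsets@table
    covered <- tab$length[!is.na(tab$offset)]
    cnt <- endCounts(idx)
    missing <- setdiff(unique(cnt$length), covered)
    if (length(missing) > 0L)
        warning(sprintf("lengths without calibrated offsets excluded from tracks: %s",
                        paste(sort(missing), collapse = ", ")))
    cnt <- cnt[cnt$length %in% covered, , drop = FALSE]
    cnt <- shiftPositions(cnt, offsets)
    makeTrack <- function(sub) {
        if (space == "genomic") {
            agg <- aggregateEndCounts(
                data.frame(length = 0L, chrom = sub$chrom,
                           strand = sub$strand, pos = sub$pos,
                           count = sub$count))
            return(new("CoverageTrack", space = "genomic",
                       data = data.frame(seq = agg$chrom,
                                         strand = agg$strand,
                                         pos = agg$pos, value = agg$count,
                                         stringsAsFactors = FALSE),
                       droppedReads = 0L))
        }
        rex <- repExonRanges(ts)
        dropped <- 0L
        out <- data.frame(seq = character(), strand = character(),
                          pos = integer(), value = integer())
        if (nrow(sub) > 0L) {
            posGr <- GRanges(sub$chrom, IRanges::IRanges(sub$pos, sub$pos),
                             strand = sub$strand)
            ov <- GenomicRanges::findOverlaps(posGr, rex)
            qh <- S4Vectors::queryHits(ov)
            txh <- mcols(rex)$transcript_id[S4Vectors::subjectHits(ov)]
            o <- order(qh, txh)
            first <- !duplicated(qh[o])
            qh <- qh[o][first]; txh <- txh[o][first]
            dropped <- sum(sub$count[setdiff(seq_len(nrow(sub)), qh)])
            if (length(qh) > 0L) {
                tpos <- integer(length(qh))
                for (tx in unique(txh)) {
                    sel <- txh == tx
                    tpos[sel] <- genomeToTranscript(
                        sub$pos[qh[sel]], ts@transcripts[[tx]])
                }
                agg <- aggregateEndCounts(
                    data.frame(length = 0L, chrom = txh, strand = "*",
                               pos = tpos, count = sub$count[qh]))
                out <- data.frame(seq = agg$chrom, strand = agg$strand,
                                  pos = agg$pos, value = agg$count,
                                  stringsAsFactors = FALSE)
            }
        }
        new("CoverageTrack", space = "transcriptomic", data = out,
            droppedReads = as.integer(dropped))
    }
    if (!perLength) return(makeTrack(cnt))
    tracks <- lapply(sort(intersect(covered, unique(cnt$length))),
                     function(L) makeTrack(cnt[cnt$length == L, ,
                                               drop = FALSE]))
    names(tracks) <- as.character(sort(intersect(covered,
                                                 unique(cnt$length))))
    tracks
}

#' @rdname CoverageTrack-class
#' @aliases trackData,CoverageTrack-method
setMethod("trackData", "CoverageTrack", function(x) x@data)

setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf("CoverageTrack (%s): %d positions, %d counts%s\n",
                object@space, nrow(object@data), sum(object@data$value),
                if (object@droppedReads > 0L)
                    sprintf(" (%d reads dropped)", object@droppedReads)
                else ""))
})

formatWigValue <- function(v) {
    ifelse(v == round(v), as.character(as.integer(round(v))),
           vapply(v, function(x) format(x, digits = 10,
                                        scientific = FALSE, trim = TRUE),
                  ""))
}

writeWigFile <- function(df, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("# ribocal P-site coverage", con)
    if (nrow(df) > 0L) {
        for (sq in unique(df$seq)) {
            sub <- df[df$seq == sq, , drop = FALSE]
            sub <- sub[order(sub$pos), , drop = FALSE]
            writeLines(sprintf("variableStep chrom=%s", sq), con)
            writeLines(paste(sub$pos, formatWigValue(sub$value)), con)
        }
    }
    invisible(path)
}

#' Write a coverage track in wiggle format
#'
#' Writes variableStep wiggle (1-based positions, integer values without a
#' decimal point). Wiggle has no strand field, so a genomic track is split
#' into two files with suffixes `.fwd.wig` and `.rev.wig` (any `.wig`
#' extension on `path` is treated as the common prefix); a transcriptomic
#' track is one file, strand being implicit in transcript orientation.
#' An empty track yields a file holding only the header comment.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path (prefix for genomic tracks).
#' @return character vector of the files written, invisibly.
#' @export
writeWiggle <- function(track, path) {
    df <- track@data
    if (track@space == "genomic") {
        base <- sub("\\.wig$", "", path)
        files <- c(paste0(base, ".fwd.wig"), paste0(base, ".rev.wig"))
        writeWigFile(df[df$strand == "+", , drop = FALSE], files[1L])
        writeWigFile(df[df$strand == "-", , drop = FALSE], files[2L])
    } else {
        files <- if (grepl("\\.wig$", path)) path else paste0(path, ".wig")
        writeWigFile(df, files)
    }
    invisible(files)
}
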