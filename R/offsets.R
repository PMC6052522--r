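#' Metagene window of 5' ends around a CDS anchor
#'
#' Sums, over the representative transcripts of the given genes, the 5' end
#' counts of one read length at positions -30..+10 relative to the anchor.
#' The start anchor is the first base of the start codon; the stop anchor
#' is the first base of the last sense codon (three bases upstream of the
#' CDS end boundary), so that a change point at window position `-o` means
#' a 5'-to-P-site offset of `o` under either anchor. Genes whose window
#' extends beyond the transcript contribute only in-bounds positions;
#' windows over disjoint gene sets are additive.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param genes coding gene ids.
#' @param L read length.
#' @param anchor `"start"` or `"stop"`.
#' @return a [MetageneWindow-class].
#' @export
metageneWindow <- function(idx, ts, genes, L, anchor = c("start", "stop")) {
    anchor <- match.arg(anchor)
    positions <- -30:10
    counts <- numeric(41L)
    for (g in genes) {
        tm <- repModel(ts, g)
        if (!isCoding(tm)) next
        anchorT <- if (anchor == "start") tm@cdsStartT else tm@cdsEndT - 2L
        tpos <- anchorT + positions
        inb <- tpos >= 1L & tpos <= txLength(tm)
        if (!any(inb)) next
        counts[inb] <- counts[inb] + countsAtTpos(idx, tm, L, tpos[inb])
    }
    new("MetageneWindow", length = as.integer(L), anchor = anchor,
        positions = positions, counts = counts,
        genesUsed = as.character(genes))
}

#' @rdname MetageneWindow-class
#' @aliases windowCounts,MetageneWindow-method
setMethod("windowCounts", "MetageneWindow",
          function(x) stats::setNames(x@counts, x@positions))

setMethod("show", "MetageneWindow", function(object) {
    cat(sprintf("MetageneWindow: length %d, %s anchor, %d reads over %d genes\n",
                object@length, object@anchor, sum(object@counts),
                length(object@genesUsed)))
})

#' Segment-mean change-point of a metagene window
#'
#' For every boundary between adjacent positions computes the difference
#' of segment means, `mean(right of b) - mean(left of b)`, and returns the
#' window position immediately right of the boundary maximizing the shift
#' (ties broken towards the most 5' position). This is the rising edge of
#' initiating (start anchor) or terminating (stop anchor) ribosome density.
#' The `"adjacent_pair"` statistic replaces segment means by the difference
#' of the two values flanking each boundary (a discrete gradient); it is
#' exposed for comparison, not used by default.
#'
#' @param counts numeric vector (a 41-entry metagene window in normal use).
#' @param positions positions attached to the entries; defaults to
#'   `-30:10` for 41-vectors, `seq_along(counts)` otherwise. A
#'   [MetageneWindow-class] may be passed as `counts`.
#' @param statistic `"segment_means"` (default) or `"adjacent_pair"`.
#' @return list with `dstar` (change-point position), `boundary` (its
#'   index), `delta` (all boundary statistics) and `maxDelta`.
#' @export
changePoint <- function(counts, positions = NULL,
                        statistic = c("segment_means", "adjacent_pair")) {
    statistic <- match.arg(statistic)
    if (is(counts, "MetageneWindow")) {
        if (is.null(positions)) positions <- counts@positions
        counts <- counts@counts
    }
    n <- length(counts)
    stopifnot(n >= 2L)
    if (is.null(positions))
        positions <- if (n == 41L) -30:10 else seq_len(n)
    if (all(counts == 0))
        noSignalError("all-zero window: no change point")
    if (statistic == "segment_means") {
        csum <- cumsum(counts)
        b <- seq_len(n - 1L)
        delta <- (csum[n] - csum[b]) / (n - b) - csum[b] / b
    } else {
        delta <- diff(counts)
    }
    bstar <- which.max(delta)          # ties: smallest index = most 5'
    list(dstar = positions[bstar + 1L], boundary = bstar, delta = delta,
         maxDelta = delta[bstar])
}

#' Peak clarity of a metagene window
#'
#' Ratio of the window's maximum count to its mean count: a window with a
#' distinct initiation/termination peak scores high (tens for phased
#' libraries), a flat or diffuse window scores near 1-3. Used by
#' [calibrateOffsets()] to decide whether an anchor shows a clear peak at
#' all before trusting its change point.
#'
#' @param window a [MetageneWindow-class] or numeric count vector.
#' @return the clarity ratio (0 for an all-zero window).
#' @export
windowClarity <- function(window) {
    counts <- if (is(window, "MetageneWindow")) window@counts else window
    m <- mean(counts)
    if (m <= 0) return(0)
    max(counts) / m
}

#' Offset implied by a change-point position
#'
#' The maximum shift in means is taken as the 5' end position of
#' initiating (or terminating) ribosomes; its distance to the anchor --
#' where the P-site sits by construction -- is the offset. Under both
#' anchors this is simply `-dstar`. A change point downstream of the
#' anchor yields an implausible negative offset: a warning is raised but
#' the value returned for inspection.
#'
#' @param dstar change-point position from [changePoint()].
#' @param anchor `"start"` or `"stop"` (informational; the arithmetic is
#'   identical by the anchor definitions of [metageneWindow()]).
#' @return integer offset in nt.
#' @export
offsetFromChangepoint <- function(dstar, anchor = c("start", "stop")) {
    anchor <- match.arg(anchor)
    if (dstar > 0)
        warning(sprintf("change point at %+d lies downstream of the %s anchor; offset %d is implausible",
                        dstar, anchor, -as.integer(dstar)))
    -as.integer(dstar)
}

#' Calibrate per-length P-site offsets
#'
#' For each periodic read length builds the metagene window, locates the
#' change point and derives the offset. Under `anchorPolicy = "auto"` the
#' start anchor is used, falling back to the stop anchor when the start
#' window shows no clear peak ([windowClarity()] at or below
#' `clarityRatio`); when neither anchor shows one, the length gets an `NA`
#' offset with a warning and is excluded from offset-shifted exports
#' unless overridden via [setOffset()].
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param genes coding gene ids anchoring the windows.
#' @param lengths read lengths to calibrate (the periodic set).
#' @param anchorPolicy `"auto"`, `"start"` or `"stop"`.
#' @param clarityRatio peak-clarity threshold for the auto fallback
#'   (default 5).
#' @param statistic change-point statistic, see [changePoint()].
#' @return an [OffsetTable-class].
#' @export
calibrateOffsets <- function(idx, ts, genes, lengths,
                             anchorPolicy = c("auto", "start", "stop"),
                             clarityRatio = 5,
                             statistic = "segment_means") {
    anchorPolicy <- match.arg(anchorPolicy)
    stopifnot(length(lengths) > 0L)
    tryAnchor <- function(L, a) {
        w <- metageneWindow(idx, ts, genes, L, a)
        cp <- tryCatch(changePoint(w, statistic = statistic),
                       ribocalNoSignal = function(e) NULL)
        if (is.null(cp)) return(NULL)
        cp$clear <- cp$maxDelta > 0 && windowClarity(w) > clarityRatio
        cp
    }
    rows <- lapply(as.integer(lengths), function(L) {
        used <- NA_character_; cp <- NULL
        if (anchorPolicy %in% c("start", "stop")) {
            cp <- tryAnchor(L, anchorPolicy)
            used <- anchorPolicy
        } else {
            cp <- tryAnchor(L, "start")
            used <- "start"
            if (is.null(cp) || !cp$clear) {
                alt <- tryAnchor(L, "stop")
                if (!is.null(alt) && alt$clear) {
                    cp <- alt
                    used <- "stop"
                } else {
                    cp <- NULL   # neither anchor has a clear edge
                }
            }
        }
        if (is.null(cp)) {
            warning(sprintf("length %d: no usable signal over either anchor; offset undefined",
                            L))
            return(data.frame(length = L, offset = NA_integer_,
                              anchorUsed = NA_character_,
                              changepoint = NA_integer_,
                              userOverridden = FALSE))
        }
        off <- offsetFromChangepoint(cp$dstar, used)
        data.frame(length = L, offset = off, anchorUsed = used,
                   changepoint = as.integer(cp$dstar),
                   userOverridden = FALSE)
    })
    new("OffsetTable",
        table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' @rdname OffsetTable-class
#' @aliases offsetTable,OffsetTable-method
setMethod("offsetTable", "OffsetTable", function(x) x@table)

#' @rdname OffsetTable-class
#' @aliases setOffset,OffsetTable-method
setMethod("setOffset", "OffsetTable", function(x, length, offset) {
    tab <- x@table
    i <- match(as.integer(length), tab$length)
    row <- data.frame(length = as.integer(length),
                      offset = as.integer(offset), anchorUsed = "manual",
                      changepoint = NA_integer_, userOverridden = TRUE)
    if (is.na(i)) tab <- rbind(tab, row) else tab[i, ] <- row
    tab <- tab[order(tab$length), , drop = FALSE]
    rownames(tab) <- NULL
    new("OffsetTable", table = tab)
})

setMethod("show", "OffsetTable", function(object) {
    cat("OffsetTable:\n")
    print(object@table, row.names = FALSE)
})

# offset for one length, NA when absent
offsetFor <- function(ot, L) {
    i <- match(as.integer(L), ot@table$length)
    if (is.na(i)) NA_integer_ else ot@table$offset[i]
}

#' Write an offset table as TSV
#'
#' @param ot an [OffsetTable-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOffsetTable <- function(ot, path) {
    tab <- offsetTable(ot)
    names(tab) <- c("length", "offset", "anchor_used",
                    "changepoint_position", "user_overridden")
    writeTsv(tab, path)
}

#' Reading-frame fractions of one read length
#'
#' Every length-`L` 5' end whose (optionally offset-shifted) position falls
#' inside the CDS of a representative transcript contributes to frame
#' `(tpos + offset - cdsStart) mod 3`; fractions are normalized over the
#' three frames. Genuine footprints with the correct offset concentrate in
#' frame 0.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param genes coding gene ids.
#' @param L read length.
#' @param offset P-site offset to apply (default 0 = none).
#' @return named numeric vector `c(frame0=, frame1=, frame2=)` with
#'   attributes `n` (reads counted), `length` and `offset`. With zero CDS
#'   reads all fractions are 0 and attribute `noReads` is set.
#' @export
frameFractions <- function(idx, ts, genes, L, offset = 0L) {
    offset <- as.integer(offset)
    tot <- numeric(3L)
    for (g in genes) {
        tm <- repModel(ts, g)
        if (!isCoding(tm)) next
        cnt <- idx@counts
        sub <- cnt[cnt$length == L & cnt$chrom == tm@chrom &
                   cnt$strand == tm@strand, , drop = FALSE]
        if (nrow(sub) == 0L) next
        tpos <- genomeToTranscript(sub$pos, tm)
        shifted <- tpos + offset
        sel <- !is.na(shifted) & shifted >= tm@cdsStartT &
               shifted <= tm@cdsEndT
        if (!any(sel)) next
        fr <- (shifted[sel] - tm@cdsStartT) %% 3L
        agg <- rowsum(sub$count[sel], fr)
        tot[as.integer(rownames(agg)) + 1L] <-
            tot[as.integer(rownames(agg)) + 1L] + agg[, 1L]
    }
    n <- sum(tot)
    out <- if (n > 0) tot / n else c(0, 0, 0)
    names(out) <- c("frame0", "frame1", "frame2")
    attr(out, "n") <- n
    attr(out, "length") <- as.integer(L)
    attr(out, "offset") <- offset
    if (n == 0) attr(out, "noReads") <- TRUE
    out
}
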