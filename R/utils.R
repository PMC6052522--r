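# internal helpers shared across modules

# error condition for empty signals; callers treat it as "non-periodic" /
# "calibration failed" rather than a hard failure
noSignalError <- function(msg) {
    stop(structure(class = c("ribocalNoSignal", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

isNoSignal <- function(e) inherits(e, "ribocalNoSignal")

# evaluate expr under a fixed RNG state, restoring the caller's stream
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

# aggregate a (length, chrom, strand, pos) data.frame into unique keyed
# counts; `count` column optional (defaults to 1 per row)
aggregateEndCounts <- function(df) {
    if (nrow(df) == 0L)
        return(data.frame(length = integer(), chrom = character(),
                          strand = character(), pos = integer(),
                          count = integer(), stringsAsFactors = FALSE))
    cnt <- if ("count" %in% names(df)) df$count else rep(1L, nrow(df))
    key <- paste(df$length, df$chrom, df$strand, df$pos, sep = "\r")
    agg <- rowsum(cnt, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    out <- data.frame(
        length = as.integer(vapply(parts, `[`, "", 1L)),
        chrom  = vapply(parts, `[`, "", 2L),
        strand = vapply(parts, `[`, "", 3L),
        pos    = as.integer(vapply(parts, `[`, "", 4L)),
        count  = as.integer(agg[, 1L]),
        stringsAsFactors = FALSE)
    out <- out[order(out$length, out$chrom, out$strand, out$pos), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

# concatenate a list of GRanges without pairwise Seqinfo merging
# (c() over many single-chromosome GRanges is quadratic and noisy)
combineGRanges <- function(lst) {
    lst <- lst[vapply(lst, length, 0L) > 0L]
    if (length(lst) == 0L) return(GRanges())
    gr <- GRanges(
        unlist(lapply(lst, function(g)
            as.character(GenomicRanges::seqnames(g)))),
        IRanges::IRanges(unlist(lapply(lst, GenomicRanges::start)),
                         unlist(lapply(lst, GenomicRanges::end))),
        strand = unlist(lapply(lst, function(g)
            as.character(GenomicRanges::strand(g)))))
    mc <- do.call(rbind, lapply(lst, function(g) as.data.frame(mcols(g))))
    if (!is.null(mc) && ncol(mc) > 0L) mcols(gr) <- mc
    names(gr) <- NULL
    gr
}

# write a data.frame as a plain TSV (deterministic, no quoting surprises)
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
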