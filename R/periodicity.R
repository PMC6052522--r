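# counts of length-L five-prime ends at given transcript positions of tm
countsAtTpos <- function(idx, tm, L, tpos) {
    cnt <- idx@counts
    sub <- cnt[cnt$length == L & cnt$chrom == tm@chrom &
               cnt$strand == tm@strand, , drop = FALSE]
    out <- numeric(length(tpos))
    if (nrow(sub) == 0L) return(out)
    gpos <- transcriptToGenome(tpos, tm)
    m <- match(gpos, sub$pos)
    hit <- !is.na(m)
    out[hit] <- sub$count[m[hit]]
    out
}

#' Summed 5' end profile over the first N CDS nucleotides
#'
#' For one read length, sums the 5' end counts at CDS-relative positions
#' 0..N-1 over the representative transcripts of the given genes. Genes
#' with a CDS shorter than N contribute only their covered prefix. Profiles
#' over disjoint gene sets are additive.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param genes gene ids (typically from [selectTopGenes()]).
#' @param L read length.
#' @param N prefix length in nt (default 150).
#' @return a [CdsPrefixProfile-class].
#' @export
cdsPrefixProfile <- function(idx, ts, genes, L, N = 150L) {
    stopifnot(N >= 3L, length(genes) > 0L)
    prof <- numeric(N)
    for (g in genes) {
        tm <- repModel(ts, g)
        if (!isCoding(tm)) next
        M <- min(N, cdsLength(tm))
        tpos <- tm@cdsStartT + seq_len(M) - 1L
        prof[seq_len(M)] <- prof[seq_len(M)] + countsAtTpos(idx, tm, L, tpos)
    }
    new("CdsPrefixProfile", length = as.integer(L), counts = prof,
        genesUsed = as.character(genes))
}

#' Dominant period of a count vector by discrete Fourier transform
#'
#' Computes DFT amplitudes `|C(k)|` for frequencies `k = 1..floor(N/2)`
#' (the zero-frequency mean term is excluded) and reports the period
#' `N / argmax_k |C(k)|` together with the maximum amplitude and the
#' amplitude at the period-3 bin `k = round(N/3)`. The result is invariant
#' to positive rescaling of the input, and circular shifts leave the
#' dominant period unchanged.
#'
#' @param counts numeric vector, length >= 3. An all-zero (or constant)
#'   vector carries no periodicity signal and raises a `"ribocalNoSignal"`
#'   error, which callers treat as a non-periodic classification.
#' @return list with elements `period`, `maxAmplitude`, `amplitudeAt3`
#'   and `k` (the argmax frequency index).
#' @examples
#' v <- numeric(150); v[seq(1, 150, 3)] <- 1
#' dominantPeriod(v)$period   # 3
#' @export
dominantPeriod <- function(counts) {
    N <- length(counts)
    stopifnot(N >= 3L)
    if (all(counts == 0))
        noSignalError("all-zero profile: no periodicity signal")
    amps <- Mod(stats::fft(counts))[2:(N %/% 2L + 1L)]
    if (max(amps) <= 1e-9 * sum(abs(counts)))
        noSignalError("constant profile: no periodicity signal")
    kstar <- which.max(amps)
    k3 <- as.integer(round(N / 3))
    list(period = N / kstar,
         maxAmplitude = amps[kstar],
         amplitudeAt3 = if (k3 >= 1L && k3 <= length(amps)) amps[k3]
                        else NA_real_,
         k = kstar)
}

#' Classify read lengths as periodic or noise
#'
#' For each read length present in the index (optionally restricted to a
#' range), sums the 5' ends over the first `N` CDS nucleotides of the given
#' genes and calls the length periodic when the highest-amplitude DFT
#' frequency is exactly the period-3 bin (`k = round(N/3)`; `k = 50` for
#' the default `N = 150`). Lengths with fewer than `minReads` profile reads
#' are not called and lengths failing the call are labelled noise but kept
#' in the table so the user can override the selection.
#'
#' @param idx a [FivePrimeEndIndex-class].
#' @param ts a [TranscriptSet-class].
#' @param genes gene ids anchoring the profiles.
#' @param lengthRange optional `c(min, max)` read-length filter.
#' @param N CDS prefix length (default 150).
#' @param minReads minimum profile reads to attempt a call (default 100).
#' @return a [PeriodicitySet-class].
#' @export
classifyPeriodicLengths <- function(idx, ts, genes, lengthRange = NULL,
                                    N = 150L, minReads = 100L) {
    lens <- sort(unique(endCounts(idx)$length))
    if (!is.null(lengthRange)) {
        stopifnot(length(lengthRange) == 2L,
                  lengthRange[1] <= lengthRange[2])
        lens <- lens[lens >= lengthRange[1] & lens <= lengthRange[2]]
    }
    rows <- lapply(lens, function(L) {
        prof <- cdsPrefixProfile(idx, ts, genes, L, N)
        n <- sum(prof@counts)
        if (n < minReads)
            return(data.frame(length = L, nReads = n, period = NA_real_,
                              maxAmplitude = NA_real_,
                              amplitudeAt3 = NA_real_, isPeriodic = FALSE))
        res <- tryCatch(dominantPeriod(prof@counts), ribocalNoSignal =
                        function(e) NULL)
        if (is.null(res))
            return(data.frame(length = L, nReads = n, period = NA_real_,
                              maxAmplitude = NA_real_,
                              amplitudeAt3 = NA_real_, isPeriodic = FALSE))
        data.frame(length = L, nReads = n, period = res$period,
                   maxAmplitude = res$maxAmplitude,
                   amplitudeAt3 = res$amplitudeAt3,
                   isPeriodic = res$k == as.integer(round(N / 3)))
    })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(tab))
        tab <- data.frame(length = integer(), nReads = numeric(),
                          period = numeric(), maxAmplitude = numeric(),
                          amplitudeAt3 = numeric(), isPeriodic = logical())
    if (nrow(tab) > 0L && !any(tab$nReads >= minReads))
        warning(sprintf("no read length reaches minReads = %d in the CDS-prefix profiles",
                        minReads))
    new("PeriodicitySet", table = tab)
}

#' @rdname PeriodicitySet-class
#' @aliases periodicityTable,PeriodicitySet-method
setMethod("periodicityTable", "PeriodicitySet", function(x) x@table)

#' @rdname PeriodicitySet-class
#' @aliases periodicLengths,PeriodicitySet-method
setMethod("periodicLengths", "PeriodicitySet",
          function(x) x@table$length[x@table$isPeriodic])

setMethod("show", "PeriodicitySet", function(object) {
    p <- periodicLengths(object)
    cat(sprintf("PeriodicitySet: %d length(s) examined; periodic: %s\n",
                nrow(object@table),
                if (length(p)) paste(p, collapse = ", ") else "none"))
})

#' Write the per-length periodicity table as TSV
#'
#' @param ps a [PeriodicitySet-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePeriodicityTable <- function(ps, path) {
    tab <- periodicityTable(ps)
    names(tab) <- c("length", "n_reads", "period", "max_amplitude",
                    "amplitude_at_3", "is_periodic")
    writeTsv(tab, path)
}
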