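#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges
NULL

#' Single-transcript model
#'
#' The coordinate backbone of the package: one transcript with its exon
#' structure and (for coding transcripts) the CDS span in transcript space.
#' Transcript space is 1-based and runs 5'->3', i.e. reversed relative to
#' the genome on the minus strand. The CDS is taken exactly as annotated;
#' no divisibility-by-3 check is imposed because annotations are imperfect.
#'
#' @slot transcriptId,geneId transcript and gene identifiers.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons an [IRanges::IRanges] of genomic exon intervals, sorted in
#'   genomic order, non-overlapping.
#' @slot cdsStartT,cdsEndT first and last CDS base in transcript coordinates
#'   (1-based, closed), or `NA` for non-coding transcripts.
#' @slot biotype annotation biotype string (`NA` when the source lacks one).
#'
#' @exportClass TranscriptModel
setClass("TranscriptModel",
    representation(
        transcriptId = "character",
        geneId       = "character",
        chrom        = "character",
        strand       = "character",
        exons        = "IRanges",
        cdsStartT    = "integer",
        cdsEndT      = "integer",
        biotype      = "character"
    ))

setValidity("TranscriptModel", function(object) {
    ex <- object@exons
    if (length(ex) == 0L)
        return("transcript must have at least one exon")
    if (!object@strand %in% c("+", "-"))
        return("strand must be '+' or '-'")
    st <- IRanges::start(ex)
    if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L)
        return("exons must be sorted by genomic start")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
        return("exons must be non-overlapping and non-adjacent-sorted")
    txLen <- sum(IRanges::width(ex))
    cs <- object@cdsStartT; ce <- object@cdsEndT
    if (is.na(cs) != is.na(ce))
        return("cdsStartT and cdsEndT must both be set or both be NA")
    if (!is.na(cs) && !(cs >= 1L && cs <= ce && ce <= txLen))
        return("CDS bounds must satisfy 1 <= cdsStartT <= cdsEndT <= transcript length")
    TRUE
})

#' A set of transcript models with gene and interval indices
#'
#' @slot transcripts named list of [TranscriptModel-class] objects.
#' @slot geneIndex named list mapping gene id to the character vector of its
#'   transcript ids.
#' @slot exons a [GenomicRanges::GRanges] of all exons with `transcript_id`
#'   and `gene_id` metadata, used for overlap queries.
#' @slot repTx named character vector: gene id -> representative transcript
#'   id (longest CDS, ties broken by lexicographic transcript id).
#'
#' @exportClass TranscriptSet
setClass("TranscriptSet",
    representation(
        transcripts = "list",
        geneIndex   = "list",
        exons       = "GRanges",
        repTx       = "character"
    ))

setValidity("TranscriptSet", function(object) {
    ids <- names(object@transcripts)
    if (is.null(ids) || any(duplicated(ids)))
        return("transcripts must be uniquely named by transcript id")
    idxIds <- unlist(object@geneIndex, use.names = FALSE)
    if (!setequal(idxIds, ids))
        return("every transcript must be reachable from the gene index")
    if (!all(object@repTx %in% ids))
        return("representative transcripts must exist in the set")
    TRUE
})

#' Genomic mask regions
#'
#' Strand-agnostic genomic intervals (e.g. rRNA, repeats) whose reads are
#' removed from all analyses. Intervals are stored merged.
#'
#' @slot ranges merged [GenomicRanges::GRanges] (strand `*`).
#' @slot source path of the file the mask was read from.
#'
#' @exportClass MaskSet
setClass("MaskSet",
    representation(ranges = "GRanges", source = "character"))

setValidity("MaskSet", function(object) {
    r <- object@ranges
    if (length(r) > 1L) {
        red <- GenomicRanges::reduce(r, ignore.strand = TRUE)
        if (length(red) != length(r))
            return("mask intervals must be merged (reduced)")
    }
    TRUE
})

#' Per-length 5' end count index
#'
#' The single statistic every estimator in the package consumes: counts of
#' footprint 5' ends keyed by read length, chromosome, strand and genomic
#' position (1-based). The 5' end is the biological one: leftmost aligned
#' base for plus-strand alignments, rightmost for minus.
#'
#' @slot counts data.frame with columns `length`, `chrom`, `strand`, `pos`,
#'   `count` (all counts >= 1, keys unique).
#' @slot totalReads mapped records seen in the source BAM.
#' @slot totalAfterMask reads surviving policy, mask and gene deselection;
#'   equals `sum(counts$count)`.
#' @slot multimapped informational tally of reads flagged/tagged as mapping
#'   to multiple positions.
#' @slot masked,deselected,policyExcluded reads removed at each filter.
#'
#' @exportClass FivePrimeEndIndex
setClass("FivePrimeEndIndex",
    representation(
        counts         = "data.frame",
        totalReads     = "integer",
        totalAfterMask = "integer",
        multimapped    = "integer",
        masked         = "integer",
        deselected     = "integer",
        policyExcluded = "integer"
    ))

setValidity("FivePrimeEndIndex", function(object) {
    cn <- c("length", "chrom", "strand", "pos", "count")
    if (!identical(colnames(object@counts), cn))
        return(sprintf("counts must have columns %s", paste(cn, collapse = ", ")))
    if (nrow(object@counts) > 0L) {
        if (any(object@counts$count < 1L))
            return("all stored counts must be >= 1")
        if (!all(object@counts$strand %in% c("+", "-")))
            return("strand must be '+' or '-'")
    }
    if (sum(object@counts$count) != object@totalAfterMask)
        return("counts must sum to totalAfterMask")
    TRUE
})

#' Summed 5' end profile over CDS prefixes
#'
#' @slot length footprint length (nt).
#' @slot counts numeric vector of length `N` (default 150); entry `j` is the
#'   summed 5' end count at CDS-relative position `j-1` over the genes used.
#' @slot genesUsed gene ids contributing to the profile.
#'
#' @exportClass CdsPrefixProfile
setClass("CdsPrefixProfile",
    representation(length = "integer", counts = "numeric",
                   genesUsed = "character"))

setValidity("CdsPrefixProfile", function(object) {
    if (any(object@counts < 0)) return("profile counts must be >= 0")
    TRUE
})

#' Per-length periodicity classification
#'
#' One row per read length: number of reads in the CDS-prefix profile, the
#' dominant DFT period, the maximum amplitude, the amplitude at the period-3
#' frequency bin and the periodic/noise call. Lengths failing the call are
#' retained (classified as noise) so the user can override.
#'
#' @slot table data.frame with columns `length`, `nReads`, `period`,
#'   `maxAmplitude`, `amplitudeAt3`, `isPeriodic`.
#'
#' @exportClass PeriodicitySet
setClass("PeriodicitySet", representation(table = "data.frame"))

#' Metagene window around a CDS anchor
#'
#' Position-wise sum of 5' end counts of one read length over many genes,
#' at window positions -30..+10 relative to the anchor: the first base of
#' the start codon, or the first base of the last sense codon before the
#' stop boundary.
#'
#' @slot length read length (nt).
#' @slot anchor `"start"` or `"stop"`.
#' @slot positions integer window positions, `-30:10`.
#' @slot counts numeric vector of 41 non-negative counts.
#' @slot genesUsed contributing gene ids.
#'
#' @exportClass MetageneWindow
setClass("MetageneWindow",
    representation(length = "integer", anchor = "character",
                   positions = "integer", counts = "numeric",
                   genesUsed = "character"))

setValidity("MetageneWindow", function(object) {
    if (length(object@positions) != 41L || length(object@counts) != 41L)
        return("metagene window must have exactly 41 positions")
    if (any(object@counts < 0)) return("window counts must be >= 0")
    if (!object@anchor %in% c("start", "stop"))
        return("anchor must be 'start' or 'stop'")
    TRUE
})

#' Per-length P-site offset table
#'
#' @slot table data.frame with columns `length`, `offset` (nt from the 5'
#'   end to the P-site, `NA` when calibration failed), `anchorUsed`
#'   (`"start"`, `"stop"` or `"manual"`), `changepoint` (window-relative
#'   change-point position) and `userOverridden`.
#'
#' @exportClass OffsetTable
setClass("OffsetTable", representation(table = "data.frame"))

setValidity("OffsetTable", function(object) {
    cn <- c("length", "offset", "anchorUsed", "changepoint", "userOverridden")
    if (!identical(colnames(object@table), cn))
        return(sprintf("offset table must have columns %s",
                       paste(cn, collapse = ", ")))
    if (any(duplicated(object@table$length)))
        return("one offset row per length")
    TRUE
})

#' Sparse P-site coverage track
#'
#' @slot space `"genomic"` or `"transcriptomic"`.
#' @slot data data.frame with columns `seq` (chromosome or transcript id),
#'   `strand` (`+`/`-` for genomic, `*` for transcriptomic), `pos` (1-based)
#'   and `value` (P-site count, > 0).
#' @slot droppedReads reads that could not be placed on a representative
#'   transcript (transcriptomic space only).
#'
#' @exportClass CoverageTrack
setClass("CoverageTrack",
    representation(space = "character", data = "data.frame",
                   droppedReads = "integer"))

setValidity("CoverageTrack", function(object) {
    if (!object@space %in% c("genomic", "transcriptomic"))
        return("space must be 'genomic' or 'transcriptomic'")
    if (nrow(object@data) > 0L && any(object@data$value <= 0))
        return("stored track values must be > 0")
    TRUE
})

#' Library-level region summary statistics
#'
#' @slot perLength data.frame with one row per read length plus a final
#'   `"all"` row; columns `cds`, `five_prime_leader`, `three_prime_trailer`,
#'   `intron`, `noncoding_transcript`, `intergenic`.
#' @slot masked,multimapped,deselected,policyExcluded library tallies
#'   carried over from ingest.
#'
#' @exportClass SummaryStats
setClass("SummaryStats",
    representation(perLength = "data.frame", masked = "integer",
                   multimapped = "integer", deselected = "integer",
                   policyExcluded = "integer"))

#' Simulation scenario for synthetic ribosome-profiling libraries
#'
#' Defines a deterministic toy genome and footprint library with known
#' ground truth: which lengths are periodic, the per-length 5'-to-P-site
#' offsets, the phasing strength, and non-periodic noise lengths placed
#' uniformly over transcripts. First and last CDS codons receive an
#' elevated sampling weight, emulating the initiation/termination pausing
#' that gives real (CHX-treated) libraries their distinct start/stop
#' metagene peaks.
#'
#' @slot nGenes number of protein-coding genes.
#' @slot leaderLen,trailerLen 5' leader and 3' trailer lengths (nt).
#' @slot cdsCodonsRange CDS length range in codons (sampled uniformly).
#' @slot periodicLengths read lengths generated with phased 5' ends.
#' @slot trueOffsets named integer, length -> true 5'-to-P-site offset (nt).
#' @slot readsPerLength reads generated per periodic length.
#' @slot phase probability mass on reading frame 0 (in [1/3, 1]).
#' @slot noiseLengths read lengths generated uniformly over transcripts.
#' @slot noiseReads reads generated per noise length.
#' @slot startPeak,stopPeak sampling-weight multiplier of the first/last
#'   CDS codon relative to an ordinary codon.
#' @slot geneWeights per-gene expression weights (default Zipf, 1/rank).
#' @slot rnaWeights per-gene RNA-seq weights (default equal to geneWeights).
#' @slot rnaReads total reads for the matched RNA-seq library.
#' @slot seed integer seed; all sampling derives from it.
#'
#' @exportClass SimScenario
setClass("SimScenario",
    representation(
        nGenes = "integer", leaderLen = "integer", trailerLen = "integer",
        cdsCodonsRange = "integer", periodicLengths = "integer",
        trueOffsets = "integer", readsPerLength = "integer",
        phase = "numeric", noiseLengths = "integer", noiseReads = "integer",
        startPeak = "numeric", stopPeak = "numeric",
        geneWeights = "numeric", rnaWeights = "numeric",
        rnaReads = "integer", seed = "integer"
    ))

setValidity("SimScenario", function(object) {
    if (object@nGenes < 1L) return("scenario must have at least one gene")
    if (object@phase < 1/3 || object@phase > 1)
        return("phase concentration must lie in [1/3, 1]")
    if (!all(as.character(object@periodicLengths) %in% names(object@trueOffsets)))
        return("every periodic length needs a true offset")
    if (length(object@geneWeights) != object@nGenes ||
        length(object@rnaWeights) != object@nGenes)
        return("gene weight vectors must have one entry per gene")
    if (length(object@cdsCodonsRange) != 2L ||
        object@cdsCodonsRange[1] > object@cdsCodonsRange[2])
        return("cdsCodonsRange must be c(min, max)")
    TRUE
})

#' Session configuration
#'
#' Every input path, parameter and per-library decision of a processing
#' run, serializable to a versioned XML session file so that a run can be
#' reproduced exactly or applied to further libraries in batch. When
#' `selectedLengths`/`offsets` are filled, detection and calibration are
#' skipped on replay and the stored values applied.
#'
#' @slot bam,annotation,mask,rnaBam input paths (`NA` when absent).
#' @slot prefixN CDS-prefix length for periodicity detection (nt).
#' @slot window metagene window relative to the anchor, `c(-30L, 10L)`.
#' @slot topFraction fraction of highest-coverage coding genes used for
#'   metaprofiles.
#' @slot lengthRange read-length range considered.
#' @slot minReads minimum profile reads to attempt a periodicity call.
#' @slot anchorPolicy `"auto"`, `"start"` or `"stop"`.
#' @slot multimapperPolicy `"primary_only"`, `"all"` or `"none"`.
#' @slot clarityRatio auto-anchor clarity threshold.
#' @slot selectedLengths explicit periodic lengths (empty = detect).
#' @slot offsets explicit offset table rows (0-row data.frame = calibrate).
#' @slot deselectedGenes gene ids removed at ingest.
#' @slot space,perLength track export options.
#' @slot toolVersion package version string.
#' @slot seed integer seed (`NA`; the pipeline itself is deterministic).
#'
#' @exportClass SessionConfig
setClass("SessionConfig",
    representation(
        bam = "character", annotation = "character", mask = "character",
        rnaBam = "character",
        prefixN = "integer", window = "integer", topFraction = "numeric",
        lengthRange = "integer", minReads = "integer",
        anchorPolicy = "character", multimapperPolicy = "character",
        clarityRatio = "numeric",
        selectedLengths = "integer", offsets = "data.frame",
        deselectedGenes = "character",
        space = "character", perLength = "logical",
        toolVersion = "character", seed = "integer"
    ))

setValidity("SessionConfig", function(object) {
    if (!object@anchorPolicy %in% c("auto", "start", "stop"))
        return("anchorPolicy must be auto, start or stop")
    if (!object@multimapperPolicy %in% c("primary_only", "all", "none"))
        return("multimapperPolicy must be primary_only, all or none")
    if (!object@space %in% c("genomic", "transcriptomic"))
        return("space must be genomic or transcriptomic")
    if (!identical(object@window, c(-30L, 10L)))
        return("window is fixed at c(-30L, 10L)")
    if (object@topFraction <= 0 || object@topFraction > 1)
        return("topFraction must be in (0, 1]")
    TRUE
})
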