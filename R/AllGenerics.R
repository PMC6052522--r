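#' @rdname TranscriptModel-class
#' @param x a `TranscriptModel` (or, where documented, another container).
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("isCoding", function(x) standardGeneric("isCoding"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))

#' @rdname TranscriptSet-class
#' @param x a `TranscriptSet`.
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("representativeTranscripts",
           function(x) standardGeneric("representativeTranscripts"))

#' @rdname MaskSet-class
#' @param x a `MaskSet`.
#' @export
setGeneric("maskRanges", function(x) standardGeneric("maskRanges"))

#' @rdname FivePrimeEndIndex-class
#' @param x a `FivePrimeEndIndex`.
#' @export
setGeneric("endCounts", function(x) standardGeneric("endCounts"))

#' @rdname PeriodicitySet-class
#' @param x a `PeriodicitySet`.
#' @export
setGeneric("periodicityTable", function(x) standardGeneric("periodicityTable"))

#' @rdname PeriodicitySet-class
#' @export
setGeneric("periodicLengths", function(x) standardGeneric("periodicLengths"))

#' @rdname MetageneWindow-class
#' @param x a `MetageneWindow`.
#' @export
setGeneric("windowCounts", function(x) standardGeneric("windowCounts"))

#' @rdname OffsetTable-class
#' @param x an `OffsetTable`.
#' @export
setGeneric("offsetTable", function(x) standardGeneric("offsetTable"))

#' @rdname OffsetTable-class
#' @param length read length whose offset is modified.
#' @param offset new offset value (nt).
#' @export
setGeneric("setOffset",
           function(x, length, offset) standardGeneric("setOffset"))

#' @rdname CoverageTrack-class
#' @param x a `CoverageTrack`.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' @rdname SummaryStats-class
#' @param x a `SummaryStats`.
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))
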