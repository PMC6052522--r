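SESSION_SCHEMA_VERSION <- "1.0"

emptyOffsetFrame <- function() {
    data.frame(length = integer(), offset = integer(),
               anchorUsed = character(), changepoint = integer(),
               userOverridden = logical(), stringsAsFactors = FALSE)
}

#' Create a session configuration
#'
#' Collects every input path and parameter of a processing run. Leave
#' `selectedLengths`/`offsets` empty for automatic detection and
#' calibration; fill them (e.g. from a loaded session) to apply stored
#' decisions to further libraries without re-calibration.
#'
#' @param bam,annotation,mask,rnaBam input paths (`NA` for the optional
#'   ones).
#' @param prefixN CDS prefix length for periodicity detection (nt).
#' @param topFraction fraction of top-coverage coding genes used.
#' @param lengthRange read-length range considered, `c(min, max)`.
#' @param minReads minimum profile reads for a periodicity call.
#' @param anchorPolicy,multimapperPolicy,clarityRatio see
#'   [calibrateOffsets()] and [buildEndIndex()].
#' @param selectedLengths explicit periodic lengths (empty = detect).
#' @param offsets explicit offset table: an [OffsetTable-class] or its
#'   data.frame (0 rows = calibrate).
#' @param deselectedGenes gene ids excluded at ingest.
#' @param space,perLength track export options.
#' @param seed integer seed stored for provenance (the pipeline itself is
#'   deterministic).
#' @return a [SessionConfig-class].
#' @export
sessionConfig <- function(bam = NA_character_, annotation = NA_character_,
                          mask = NA_character_, rnaBam = NA_character_,
                          prefixN = 150L, topFraction = 0.1,
                          lengthRange = c(20L, 40L), minReads = 100L,
                          anchorPolicy = "auto",
                          multimapperPolicy = "primary_only",
                          clarityRatio = 5,
                          selectedLengths = integer(),
                          offsets = emptyOffsetFrame(),
                          deselectedGenes = character(),
                          space = "genomic", perLength = FALSE,
                          seed = NA_integer_) {
    if (is(offsets, "OffsetTable")) offsets <- offsets@table
    new("SessionConfig", bam = as.character(bam),
        annotation = as.character(annotation), mask = as.character(mask),
        rnaBam = as.character(rnaBam), prefixN = as.integer(prefixN),
        window = c(-30L, 10L), topFraction = as.numeric(topFraction),
        lengthRange = as.integer(lengthRange),
        minReads = as.integer(minReads),
        anchorPolicy = anchorPolicy,
        multimapperPolicy = multimapperPolicy,
        clarityRatio = as.numeric(clarityRatio),
        selectedLengths = as.integer(selectedLengths), offsets = offsets,
        deselectedGenes = as.character(deselectedGenes), space = space,
        perLength = as.logical(perLength),
        toolVersion = as.character(utils::packageVersion("ribocal")),
        seed = as.integer(seed))
}

setMethod("show", "SessionConfig", function(object) {
    cat(sprintf(paste0("SessionConfig (ribocal %s)\n  bam: %s\n  annotation: %s\n",
                       "  lengths: %s | offsets: %d row(s) | anchor: %s\n"),
                object@toolVersion, object@bam, object@annotation,
                if (length(object@selectedLengths))
                    paste(object@selectedLengths, collapse = ",")
                else "(auto)",
                nrow(object@offsets), object@anchorPolicy))
})

naToEmpty <- function(x) if (is.na(x)) "" else as.character(x)
emptyToNa <- function(x) if (!nzchar(x)) NA_character_ else x

#' Save a session configuration as XML
#'
#' Writes a versioned XML session file with a fixed element order, so that
#' serialize -> parse -> serialize is byte-stable and a run can be
#' reproduced or applied to other libraries later.
#'
#' @param cfg a [SessionConfig-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveSession <- function(cfg, path) {
    methods::validObject(cfg)
    doc <- xml2::xml_new_root("ribocalSession",
                              version = SESSION_SCHEMA_VERSION)
    inp <- xml2::xml_add_child(doc, "inputs")
    xml2::xml_add_child(inp, "bam", naToEmpty(cfg@bam))
    xml2::xml_add_child(inp, "annotation", naToEmpty(cfg@annotation))
    xml2::xml_add_child(inp, "mask", naToEmpty(cfg@mask))
    xml2::xml_add_child(inp, "rnaBam", naToEmpty(cfg@rnaBam))
    par <- xml2::xml_add_child(doc, "parameters")
    xml2::xml_add_child(par, "prefixN", as.character(cfg@prefixN))
    xml2::xml_add_child(par, "windowStart", as.character(cfg@window[1L]))
    xml2::xml_add_child(par, "windowEnd", as.character(cfg@window[2L]))
    xml2::xml_add_child(par, "topFraction", as.character(cfg@topFraction))
    xml2::xml_add_child(par, "lengthMin", as.character(cfg@lengthRange[1L]))
    xml2::xml_add_child(par, "lengthMax", as.character(cfg@lengthRange[2L]))
    xml2::xml_add_child(par, "minReads", as.character(cfg@minReads))
    xml2::xml_add_child(par, "anchorPolicy", cfg@anchorPolicy)
    xml2::xml_add_child(par, "multimapperPolicy", cfg@multimapperPolicy)
    xml2::xml_add_child(par, "clarityRatio", as.character(cfg@clarityRatio))
    sl <- xml2::xml_add_child(doc, "selectedLengths")
    for (L in cfg@selectedLengths)
        xml2::xml_add_child(sl, "length", as.character(L))
    off <- xml2::xml_add_child(doc, "offsets")
    if (nrow(cfg@offsets) > 0L)
        for (i in seq_len(nrow(cfg@offsets))) {
            r <- cfg@offsets[i, ]
            xml2::xml_add_child(off, "offset",
                length = as.character(r$length),
                value = if (is.na(r$offset)) "" else as.character(r$offset),
                anchor = if (is.na(r$anchorUsed)) "" else r$anchorUsed,
                changepoint = if (is.na(r$changepoint)) ""
                              else as.character(r$changepoint),
                userOverridden = tolower(as.character(r$userOverridden)))
        }
    des <- xml2::xml_add_child(doc, "deselectedGenes")
    for (g in cfg@deselectedGenes) xml2::xml_add_child(des, "gene", g)
    exp <- xml2::xml_add_child(doc, "export")
    xml2::xml_add_child(exp, "space", cfg@space)
    xml2::xml_add_child(exp, "perLength",
                        tolower(as.character(cfg@perLength)))
    xml2::xml_add_child(doc, "toolVersion", cfg@toolVersion)
    xml2::xml_add_child(doc, "seed",
                        if (is.na(cfg@seed)) "" else as.character(cfg@seed))
    xml2::write_xml(doc, path)
    invisible(path)
}

xmlText1 <- function(doc, xpath, path) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing"))
        stop(sprintf("session file '%s' (schema %s): required element '%s' missing",
                     path, SESSION_SCHEMA_VERSION, xpath))
    xml2::xml_text(node)
}

#' Load a session configuration from XML
#'
#' Exact inverse of [saveSession()]. The schema version is checked and
#' unknown elements are rejected, so a file written by a different schema
#' fails loudly instead of being silently misread.
#'
#' @param path session XML file.
#' @return a [SessionConfig-class].
#' @export
loadSession <- function(path) {
    if (!file.exists(path)) stop(sprintf("session file '%s' not found", path))
    doc <- xml2::read_xml(path)
    if (xml2::xml_name(doc) != "ribocalSession")
        stop(sprintf("'%s' is not a ribocal session file (root element '%s')",
                     path, xml2::xml_name(doc)))
    ver <- xml2::xml_attr(doc, "version")
    if (is.na(ver) || ver != SESSION_SCHEMA_VERSION)
        stop(sprintf("session schema version mismatch in '%s': file has '%s', this version of ribocal reads '%s'",
                     path, if (is.na(ver)) "(none)" else ver,
                     SESSION_SCHEMA_VERSION))
    known <- c("inputs", "parameters", "selectedLengths", "offsets",
               "deselectedGenes", "export", "toolVersion", "seed")
    children <- xml2::xml_name(xml2::xml_children(doc))
    unknown <- setdiff(children, known)
    if (length(unknown) > 0L)
        stop(sprintf("unknown element(s) in session file '%s' (schema %s): %s",
                     path, SESSION_SCHEMA_VERSION,
                     paste(unknown, collapse = ", ")))
    missing <- setdiff(known, children)
    if (length(missing) > 0L)
        stop(sprintf("session file '%s' (schema %s): required element(s) missing: %s",
                     path, SESSION_SCHEMA_VERSION,
                     paste(missing, collapse = ", ")))
    offNodes <- xml2::xml_find_all(doc, "offsets/offset")
    offsets <- if (length(offNodes) == 0L) emptyOffsetFrame() else
        data.frame(
            length = as.integer(xml2::xml_attr(offNodes, "length")),
            offset = suppressWarnings(
                as.integer(xml2::xml_attr(offNodes, "value"))),
            anchorUsed = ifelse(nzchar(xml2::xml_attr(offNodes, "anchor")),
                                xml2::xml_attr(offNodes, "anchor"),
                                NA_character_),
            changepoint = suppressWarnings(
                as.integer(xml2::xml_attr(offNodes, "changepoint"))),
            userOverridden = xml2::xml_attr(offNodes, "userOverridden") ==
                "true",
            stringsAsFactors = FALSE)
    lens <- as.integer(xml2::xml_text(
        xml2::xml_find_all(doc, "selectedLengths/length")))
    genes <- xml2::xml_text(xml2::xml_find_all(doc, "deselectedGenes/gene"))
    seedTxt <- xmlText1(doc, "seed", path)
    cfg <- sessionConfig(
        bam = emptyToNa(xmlText1(doc, "inputs/bam", path)),
        annotation = emptyToNa(xmlText1(doc, "inputs/annotation", path)),
        mask = emptyToNa(xmlText1(doc, "inputs/mask", path)),
        rnaBam = emptyToNa(xmlText1(doc, "inputs/rnaBam", path)),
        prefixN = as.integer(xmlText1(doc, "parameters/prefixN", path)),
        topFraction = as.numeric(xmlText1(doc, "parameters/topFraction",
                                          path)),
        lengthRange = c(as.integer(xmlText1(doc, "parameters/lengthMin",
                                            path)),
                        as.integer(xmlText1(doc, "parameters/lengthMax",
                                            path))),
        minReads = as.integer(xmlText1(doc, "parameters/minReads", path)),
        anchorPolicy = xmlText1(doc, "parameters/anchorPolicy", path),
        multimapperPolicy = xmlText1(doc, "parameters/multimapperPolicy",
                                     path),
        clarityRatio = as.numeric(xmlText1(doc, "parameters/clarityRatio",
                                           path)),
        selectedLengths = lens, offsets = offsets,
        deselectedGenes = genes,
        space = xmlText1(doc, "export/space", path),
        perLength = xmlText1(doc, "export/perLength", path) == "true",
        seed = if (nzchar(seedTxt)) as.integer(seedTxt) else NA_integer_)
    cfg@toolVersion <- xmlText1(doc, "toolVersion", path)
    cfg
}

#' Run the full processing pipeline
#'
#' Executes ingest, length detection, offset calibration, summary
#' statistics, RPKM/TE tables and track export according to a session
#' configuration, writing all outputs into `outDir`. When the
#' configuration carries explicit `selectedLengths` and `offsets` (batch
#' replay), detection and calibration are skipped and the stored values
#' applied. The pipeline is deterministic: the same configuration and
#' inputs yield byte-identical outputs. On error, partial outputs are
#' removed.
#'
#' Outputs: `length_histogram.tsv`, `periodicity.tsv` (when detection
#' ran), `offsets.tsv`, `frame_fractions.tsv`, `region_stats.tsv`,
#' `rpkm.tsv`, `te.tsv` (when RNA-seq is configured), wiggle tracks
#' (`coverage[.L]{.fwd,.rev}.wig` or `coverage[.L].tx.wig`),
#' `session.xml` (the effective, replayable session) and `report.json`.
#'
#' @param cfg a [SessionConfig-class].
#' @param bam optional BAM path overriding `cfg`'s (batch application of
#'   one session to further libraries).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results and the
#'   vector of files written.
#' @export
runPipeline <- function(cfg, bam = NULL, outDir) {
    methods::validObject(cfg)
    if (!is.null(bam)) cfg@bam <- bam
    if (is.na(cfg@bam) || is.na(cfg@annotation))
        stop("session must name a BAM and an annotation file")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character()
    addFile <- function(f) written <<- c(written, f)
    logStep <- function(fmt, ...) message(sprintf(paste0("[ribocal] ", fmt),
                                                  ...))
    result <- tryCatch({
        logStep("annotation: %s", cfg@annotation)
        ts <- readAnnotation(cfg@annotation)
        mask <- if (!is.na(cfg@mask)) readMask(cfg@mask) else NULL
        logStep("ingest: %s (policy %s)", cfg@bam, cfg@multimapperPolicy)
        idx <- buildEndIndex(cfg@bam, ts, mask = mask,
                             deselect = cfg@deselectedGenes,
                             multimapperPolicy = cfg@multimapperPolicy)
        logStep("reads: %d counted | %d masked | %d deselected | %d policy-excluded",
                idx@totalAfterMask, idx@masked, idx@deselected,
                idx@policyExcluded)
        addFile(writeTsv(lengthHistogram(idx),
                         file.path(outDir, "length_histogram.tsv")))
        genes <- selectTopGenes(idx, ts, cfg@topFraction)
        logStep("metaprofile genes (top %.0f%%): %s", 100 * cfg@topFraction,
                paste(genes, collapse = ", "))
        ps <- NULL
        if (length(cfg@selectedLengths) > 0L) {
            lengths <- cfg@selectedLengths
            logStep("lengths from session: %s",
                    paste(lengths, collapse = ", "))
        } else {
            ps <- classifyPeriodicLengths(idx, ts, genes,
                                          lengthRange = cfg@lengthRange,
                                          N = cfg@prefixN,
                                          minReads = cfg@minReads)
            addFile(writePeriodicityTable(ps,
                        file.path(outDir, "periodicity.tsv")))
            lengths <- periodicLengths(ps)
            logStep("periodic lengths detected: %s",
                    paste(lengths, collapse = ", "))
            if (length(lengths) == 0L)
                stop("no periodic read lengths detected")
        }
        if (nrow(cfg@offsets) > 0L) {
            ot <- new("OffsetTable", table = cfg@offsets)
            logStep("offsets from session (no re-calibration)")
        } else {
            ot <- calibrateOffsets(idx, ts, genes, lengths,
                                   anchorPolicy = cfg@anchorPolicy,
                                   clarityRatio = cfg@clarityRatio)
            logStep("calibrated offsets: %s",
                    paste(sprintf("%d:%s", ot@table$length,
                                  ot@table$offset), collapse = " "))
        }
        addFile(writeOffsetTable(ot, file.path(outDir, "offsets.tsv")))
        ff <- do.call(rbind, lapply(lengths, function(L) {
            f <- frameFractions(idx, ts, genes, L,
                                offset = ifelse(is.na(offsetFor(ot, L)), 0L,
                                                offsetFor(ot, L)))
            data.frame(length = L, frame0 = f[[1L]], frame1 = f[[2L]],
                       frame2 = f[[3L]], n = attr(f, "n"))
        }))
        addFile(writeTsv(ff, file.path(outDir, "frame_fractions.tsv")))
        stats <- regionStats(idx, ts, lengths = lengths, offsets = ot)
        addFile(writeSummaryStats(stats,
                                  file.path(outDir, "region_stats.tsv")))
        rpkm <- rpkmTable(idx, ts, lengths = lengths, offsets = ot,
                          mode = "ribo")
        addFile(writeTsv(rpkm, file.path(outDir, "rpkm.tsv")))
        te <- NULL
        if (!is.na(cfg@rnaBam)) {
            logStep("RNA-seq ingest: %s", cfg@rnaBam)
            rnaIdx <- buildEndIndex(cfg@rnaBam, ts, mask = mask,
                                    multimapperPolicy =
                                        cfg@multimapperPolicy)
            rnaRpkm <- rpkmTable(rnaIdx, ts, mode = "rna")
            te <- translationalEfficiency(rpkm, rnaRpkm)
            addFile(writeTsv(te, file.path(outDir, "te.tsv")))
        }
        cntSel <- endCounts(idx)
        idxSel <- fivePrimeEndIndex(
            cntSel[cntSel$length %in% lengths, , drop = FALSE],
            totalReads = idx@totalReads, multimapped = idx@multimapped,
            masked = idx@masked, deselected = idx@deselected,
            policyExcluded = idx@policyExcluded)
        tracks <- psiteTrack(idxSel, ot, ts, space = cfg@space,
                             perLength = cfg@perLength)
        if (cfg@perLength) {
            for (L in names(tracks)) {
                base <- file.path(outDir, sprintf("coverage.L%s%s", L,
                    if (cfg@space == "transcriptomic") ".tx" else ""))
                for (f in writeWiggle(tracks[[L]], base)) addFile(f)
            }
        } else {
            base <- file.path(outDir, if (cfg@space == "transcriptomic")
                "coverage.tx" else "coverage")
            for (f in writeWiggle(tracks, base)) addFile(f)
        }
        effective <- cfg
        effective@selectedLengths <- as.integer(lengths)
        effective@offsets <- ot@table
        addFile(saveSession(effective, file.path(outDir, "session.xml")))
        report <- list(
            toolVersion = cfg@toolVersion,
            bam = cfg@bam, annotation = cfg@annotation,
            totalReads = idx@totalReads,
            countedReads = idx@totalAfterMask, masked = idx@masked,
            deselected = idx@deselected,
            policyExcluded = idx@policyExcluded,
            multimapped = idx@multimapped,
            metaprofileGenes = genes,
            selectedLengths = as.integer(lengths),
            offsets = stats::setNames(as.list(ot@table$offset),
                                      as.character(ot@table$length)),
            anchors = stats::setNames(as.list(ot@table$anchorUsed),
                                      as.character(ot@table$length)))
        reportPath <- file.path(outDir, "report.json")
        jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                             pretty = TRUE, digits = NA, na = "null")
        addFile(reportPath)
        list(index = idx, periodicity = ps, offsets = ot,
             lengths = as.integer(lengths), stats = stats, rpkm = rpkm,
             te = te, session = effective, files = written)
    }, error = function(e) {
        unlink(written)
        stop(e)
    })
    invisible(result)
}
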