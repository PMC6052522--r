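Package: ribocal
Title: Automated Footprint-Length Selection and P-Site Calibration for
    Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing toolkit for ribosome profiling libraries. Detects
    which footprint lengths carry genuine translating ribosomes by testing
    the 3-nucleotide periodicity of summed 5' end profiles over coding-region
    prefixes with a discrete Fourier transform, calibrates a per-length
    P-site offset by change-point analysis of metagene windows around start
    and stop codons, and exports P-site-shifted coverage tracks (wiggle,
    genomic or transcriptomic), region summary statistics, RPKM expression
    tables and translational efficiency. Every processing decision can be
    serialized to an XML session file and replayed for exact reproduction,
    including batch application to further libraries. A deterministic
    simulator generates toy annotations and footprint alignments with known
    ground-truth lengths and offsets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
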