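Package: druidr
Title: Transcriptome-Wide mRNA Half-Lives from Metabolic-Labeling Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes transcriptome-wide mRNA half-lives from
    approach-to-equilibrium metabolic-labeling (e.g. 4-thiouridine) RNA-seq
    time courses. Exon-mapping signal is normalized per time point either to
    the summed coverage of a k-means-selected set of rapidly equilibrating
    endogenous introns or to exogenous whole-organism spike-ins, and a
    bounded-growth kinetic model N(t) = N0*(1 - exp(-(lambda + gamma)*t)) is
    fit per gene by weighted nonlinear least squares, with half-life
    ln(2)/lambda. Also supports transcription-shutoff exponential-decay
    fitting, annotation-driven exon/intron feature models, purification
    enrichment QC, replicate-comparison statistics (Spearman/Pearson, Fisher
    r-to-z), and a generative simulator of labeling experiments with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    methods,
    stats,
    utils
Suggests:
    GenomicAlignments,
    Rsamtools,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
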