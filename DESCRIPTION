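Package: ribostep
Title: Frame-Calling, ORF Discovery and Footprint Geometry for Ribosome
    Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis engine for ribosome profiling (Ribo-seq) data aligned
    to a transcriptome. Exploits the triplet periodicity of translating
    ribosomes to call the reading-frame phase of ribosome-protected
    fragments per length class, filters annotated or de novo coding
    regions by in-frame footprint support, scans transcripts for
    candidate open reading frames (including upstream, downstream and
    overlapping ORFs), builds weighted metagene profiles around start and
    stop codons and infers P-site/A-site footprint geometry, renders
    per-transcript frame-coloured read profiles, quantifies rRNA-depletion
    bias (library composition, FPKM concordance, fixed-slope R-squared,
    chi-square envelopes over distinct read species), and exports
    per-CDS count matrices for downstream differential-translation
    analysis. A synthetic footprint simulator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
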