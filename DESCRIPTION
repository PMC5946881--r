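Package: oncotier
Title: Tiered Clinical Interpretation of Somatic Cancer Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretation engine for individual tumor genomes. Annotates
    somatic SNVs/indels and copy-number segments against an oncology knowledge
    bundle (clinical evidence items, mutational hotspots, driver genes,
    tumor-type variant frequencies, pathogenicity predictions), classifies
    variants into a five-tier clinical-relevance scheme, estimates mutational
    signature contributions over the 96 trinucleotide substitution contexts by
    non-negative least squares, predicts microsatellite instability from
    whole-profile features, computes tumor mutational burden, and renders a
    structured tiered report as JSON, per-tier TSV tables and static HTML.
    Includes a deterministic synthetic bundle and tumor generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    pracma,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
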