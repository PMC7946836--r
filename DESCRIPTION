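Package: tcrfocus
Title: Paired T Cell Receptor Repertoire Diversity, Expansion and Persistence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing paired T cell receptor (TCR) repertoires, such as
    bone-marrow samples taken at diagnosis and after autologous stem cell
    transplantation. Implements depth matching by iterative subsampling without
    replacement, Renyi entropy diversity spectra, clonal-expansion detection at a
    fixed frequency threshold, CDR3 similarity networks built from a cosine-normalised
    amino-acid triplet spectrum kernel, and paired clonotype persistence tracking.
    Reads AIRR Rearrangement TSV and Decombinator-style clonotype tables, and ships a
    synthetic paired-repertoire generator with heavy-tailed clone sizes, a
    post-treatment richness bottleneck, clonotype persistence and plantable CDR3
    motif families for validating the analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
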