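Package: hostadapt
Title: Host Adaptation Analysis of Gut Bacteroides from qPCR, Comparative
    Genomics and Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify Bacteroides species across host groups from
    qPCR Ct tables via delta-Ct relative abundance (100 x 2^-dCt against a
    pan-bacterial 16S reference) and classify host adaptation with
    Kruskal-Wallis and Dunn rank tests; to screen annotated genomes for
    host-specific genes with a reference-anchored amino-acid similarity
    matrix (absent below 50 percent, recent horizontal transfer above 99
    percent), detect near-identical transfer candidates and conserved
    syntenic islands, and contrast gene-family counts and genome sizes
    with exact Mann-Whitney tests; and to summarise peptide spectral match
    (PSM) tables into per-protein expression counts and mean relative
    abundances. Includes a seeded synthetic-data generator that plants
    host-specific genes, transfer islands and abundance contrasts with
    recorded ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
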