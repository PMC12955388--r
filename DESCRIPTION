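Package: famshare
Title: Family-Level Sharing of Gut Microbiome Strains and Diversity
Version: 0.1.0
Authors@R:
    person("famshare", "developers", email = "famshare@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for family-level analysis of gut-microbiome
    macro- and microdiversity from metagenome-assembled genomes: quality
    filtering and fragment-based average nucleotide identity (ANI)
    dereplication, abundance (RPKM), Shannon diversity and Bray-Curtis
    dissimilarity with within- versus between-family contrasts, PERMANOVA
    with marginal effects, detection of species populations whose genome
    variation is structured by family (shared strains), sharing-event and
    family-prevalence counts, classical multidimensional scaling of ANI
    matrices, nucleotide diversity and gene-level pN/pS selection
    statistics, KEGG-module coverage calling, and Spearman co-occurrence
    networks. A family-structured synthetic cohort generator with planted
    ground truth (transmission events, family abundance effects) provides
    reproducible end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
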