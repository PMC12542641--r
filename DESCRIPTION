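Package: tierminer
Title: Tiered Discovery, Classification and Quantification of Soluble
    Di-Iron Monooxygenase Genes in Assembled Metagenomes
Version: 0.1.0
Authors@R:
    person("Lowry", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Discovers soluble di-iron monooxygenase (SDIMO) alpha-hydroxylase
    genes in assembled metagenomes by screening predicted proteins against a
    labelled reference panel, applies a two-tier evidence gate (amino-acid
    identity, alignment length, query coverage, and validation of the DE*RH
    carboxylate di-iron centre motif), dereplicates contigs with greedy
    identity clustering, assigns candidates to dioxane-degrader or outgroup
    clades and SDIMO groups I-VI on a neighbor-joining tree, aggregates
    contig RPKM abundances per clade and sample, and inspects gene
    neighborhoods for operon order, inverted terminal repeats and
    fixed-length terminal contig overlaps. A synthetic-metagenome generator
    with full planted ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
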