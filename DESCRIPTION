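Package: cibmut
Title: Mutation Spectrum Analysis for Carbon-Ion Beam Mutagenized Arabidopsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome resequencing of carbon-ion
    beam (CIB) mutagenized Arabidopsis thaliana M2 lines. Implements
    allele-fraction based retention filtering of line-private induced
    mutations, seven-category mutation classification (SBS, single-base and
    >=2 bp insertions/deletions, complex mutations, structural variants),
    strand-collapsed substitution spectra, junction-microhomology signature
    classification (homopolymer / polynucleotide-repeat / independent),
    SnpEff-style impact tiering, per-bp-per-Gy mutation frequency statistics
    with per-plant averaging, TSS-relative mutation profiles, multi-caller
    structural-variant consensus and size summaries, one-way ANOVA with
    Duncan's multiple-range letters, and a synthetic genome/variant
    generator with genotype-specific mutation profiles so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
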