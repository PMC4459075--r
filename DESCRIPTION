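Package: cosmidbias
Title: Promoter-Driven Sequence Bias in Metagenomic Cosmid Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify sequence bias introduced during large-insert
    (cosmid/fosmid) metagenomic library construction. Provides degenerate
    sigma-factor consensus-promoter scanning with bounded variable-length
    spacers, per-sample GC and promoter-content profiling of reads and
    genomes, exact-identity subtraction of host and vector contamination,
    a per-taxon bias statistic (fold change in percent abundance between a
    crude DNA extract and the final clone library) correlated against genome
    GC and rpoD consensus density, and a seeded generative simulator of the
    library-construction workflow (fragmentation with sheared debris, size
    selection, promoter-dependent clone loss, paired-end read sampling with
    truth labels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
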