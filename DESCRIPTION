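Package: taxmix
Title: Mixture-Model Taxonomic Assignment of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomic binning of metagenomic sequencing reads from tabular
    homology-search hits. Candidate genomes identified by a nucleotide search
    (e.g. MegaBLAST against a reference database) are modelled as components of
    a finite mixture: each read arises from genome j with probability pi_j and
    accumulates per-base mismatches with probability p. Both parameter sets are
    estimated jointly by an expectation-maximisation algorithm over a sparse
    read-by-genome scoring matrix, after which each read is assigned to its
    maximum-posterior genome, assignments are rolled up the taxonomy to named
    ranks, and read proportions are converted to relative genome abundance
    (copy number) using genome lengths. Includes percentile-bootstrap
    confidence intervals for the mixture proportions with Bonferroni family
    correction, and a synthetic community generator that emits hit files,
    taxonomies, genome lengths and truth tables so the whole pipeline is
    testable without reference databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
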