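Package: haplofinger
Title: Haplotype-Based DNA Fingerprinting of Clonally Propagated Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building haplotype-based DNA fingerprinting systems
    for clonally propagated crops from multi-SNP amplicon (segment)
    genotypes. Covers heterozygote calling from Sanger-style peak traces,
    SNP extraction from IUPAC consensus alignments, haplotype phasing by
    expectation-maximisation, per-segment diversity statistics (haplotype
    diversity, observed heterozygosity, polymorphic information content),
    probability-of-identity and discrimination-capacity statistics, clone
    and somatic-mutant classification via differential segment numbers,
    candidate parent-offspring detection with parentage non-exclusion
    probabilities, distance-based clustering with bootstrap support,
    principal coordinates analysis, allele-coverage core-set selection,
    minimal fingerprinting marker subsets, and a synthetic-panel generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
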