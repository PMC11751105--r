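Package: selfseg
Title: Segregation-Signature Mapping of Mutant Genes in Self-Fertilizing
    Isogenic Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate causal mutations from pooled sequencing of
    mutant, sibling and parental wild-type pools in self-fertilizing isogenic
    lines (bulk segregant analysis without genetic mapping). Implements the
    three-pool segregation-signature filter for a fully penetrant recessive
    allele (fixed in the mutant pool, absent from the wild-type strain,
    Mendelian 2:1 wild-type:mutant allele ratio among phenotypically normal
    siblings), an exact sibling-ratio consistency test that accounts for
    finite embryo pools, codon-level coding-effect annotation of point
    substitutions, and candidate prioritization by Grantham substitution
    severity, cross-species residue conservation and functional-domain
    overlap. A synthetic selfing-pedigree generator with known ground truth
    emulates an ENU-mutagenized, multi-generation selfed line so the whole
    pipeline can be exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
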