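Package: hlatrio
Title: Family-Based HLA Haplotype Phasing and Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based association analysis of high-resolution
    HLA genotypes. Phases trio families into transmitted and non-transmitted
    parental haplotypes by Mendelian segregation, resolves allelic and
    genotypic (phase) ambiguity in Genotype List String (GL string) notation,
    decomposes 11-locus haplotypes into analysis blocks at untruncated and
    two-field nomenclature resolution, and tests association with the
    genotypic transmission disequilibrium test (additive, dominant and
    recessive codings, with a MAX statistic and permutation p-values), the
    Bradley-Terry multiallelic TDT, conditional-logistic TDT with gene-gene
    interaction, and case-control allele tests with Hardy-Weinberg
    diagnostics. Includes cumulative risk scoring (net risk/protection score
    and HLA genetic burden) and a synthetic trio-family and cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
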