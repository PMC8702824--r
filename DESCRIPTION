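Package: pgtlink
Title: Variant Classification and SNP-Haplotype Linkage Analysis for
    Preimplantation Genetic Testing of Monogenic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting single-gene disease variants and for
    deducing embryo genotypes in preimplantation genetic testing for
    monogenic disease (PGT-M). Implements an ACMG/AMP evidence-combination
    engine with strength-modified criteria and a Bayesian posterior
    probability of pathogenicity; pedigree co-segregation eLOD scoring with
    mapping to PP1 evidence strength; HGVS parsing, molecular-consequence
    classification and protein-domain annotation for fibrillin-1 (FBN1)
    variants; and SNP-haplotype linkage analysis of embryo genotypes around
    a disease locus using a two-state hidden Markov model tolerant of
    allele dropout from whole-genome amplification. A synthetic-family
    simulator generates pedigrees, SNP panels and embryo genotypes with
    Mendelian transmission, recombination and amplification artifacts so
    every stage can be validated without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
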