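# pgtlink

Variant interpretation and SNP-haplotype linkage analysis for
preimplantation genetic testing of monogenic disease (PGT-M), built around
the workup of *FBN1* variants in Marfan-syndrome families. The package is
aimed at clinical-genetics analysts and method developers who need the
computational steps of a PGT-M workflow as tested, reusable functions
rather than spreadsheet arithmetic:

- **ACMG/AMP classification engine** — strength-modified evidence codes
  (`PS4_Moderate`, `PP1_Strong`, …) combined by the 2015 categorical rules
  into the five-tier classification, together with the Bayesian posterior
  probability of pathogenicity. Each very-strong item carries odds
  *O* = 350, and strong / moderate / supporting items carry
  *O*^(1/2), *O*^(1/4), *O*^(1/8); benign items contribute reciprocal odds.
  With prior *P* and combined odds *O*<sub>c</sub>,

  posterior = *O*<sub>c</sub>·*P* / ((*O*<sub>c</sub> − 1)·*P* + 1), with *P* = 0.10.

- **Co-segregation eLOD** — under a fully penetrant autosomal-dominant
  model, each informative meiosis contributes log₁₀(2), so
  eLOD = *m*·log₁₀(2) with *m* counted from a PED pedigree; the eLOD maps
  to the applied strength of the PP1 criterion (supporting ≥ 0.6,
  moderate ≥ 1.2, strong ≥ 1.5).

- **Embryo genotype deduction** — around the disease gene, markers where
  the carrier parent is heterozygous and the other parent homozygous reveal
  which parental haplotype (disease-linked "0" or normal "1") an embryo
  inherited. A two-state hidden Markov model with a Haldane transition map
  (p_switch = (1 − e^(−2rd))/2) and an emission model derived from
  MDA allele dropout (surviving-allele convention) decodes each embryo's
  transmitted haplotype, reports per-haplotype informative-SNP support
  counts, localizes recombination events, and calls each embryo
  carrier / non-carrier / no-call.

- **Synthetic family generator** — pedigree templates, SNP panels, Mendelian
  transmission with recombination, and MDA noise, so the whole pipeline is
  testable without raw sequencing data.

There are also HGVS parsing and consequence classification, fibrillin-1
domain annotation (cbEGF membership, cysteine substitutions), plain-text
VCF/PED fixture I/O, and a `run_pipeline()` driver with a thin CLI at
`inst/cli/pgtlink.R`.

## Worked example

Classify the packaged 11-variant cohort and run a simulated PGT-M cycle:

```r
library(pgtlink)

ev <- readr::read_tsv(system.file("extdata", "fbn1_cohort_evidence.tsv",
                                  package = "pgtlink"),
                      comment = "#", show_col_types = FALSE)
cohort <- classify_variants(ev)
glance(cohort)
#> # A tibble: 1 × 7
#>   n_variants n_pathogenic n_likely_pathogenic n_uncertain n_likely_benign ...
#> 1         11            6                   3           2               0
```

Nine of eleven variants are likely pathogenic/pathogenic (`n_lp_plus_p = 9`);
`tidy(cohort)` gives the per-variant class, fired rule and posterior
(e.g. 81.2% for the uncertain synonymous variant under one-moderate +
three-supporting evidence).

```r
# a paternal-carrier couple with 8 embryos; a carrier embryo anchors phase
cfg <- sim_config(template = "fam8", n_markers = 160, n_embryos = 8,
                  ado_rate = 0.05, geno_error = 0.005, seed = 13)
fam <- simulate_embryos(simulate_family(cfg))
ref <- names(Filter(function(e) e$carrier_status, fam$truth$embryos))[[1]]
fam$gm$samples$role[fam$gm$samples$sample == ref] <- "reference_relative"

an <- pgt_analyse(fam$gm, gene = cfg$gene)
an
#> PGT haplotype analysis: 7 embryos over 25 informative SNPs ( hmm )
#>   carrier: 1  non-carrier: 6  no-call: 0
#>   embryo   verdict     support0 support1 gene_posterior0 n_recombinations
#> 1 embryo_1 non_carrier        0       23    0.0000000145                0
#> ...
#> 7 embryo_8 carrier           25        0    1.000                       0
```

`support0`/`support1` are the informative-SNP counts backing the
disease-linked and normal haplotype (the layout of a clinical PGT report),
`gene_posterior0` is the HMM posterior that the disease haplotype was
transmitted at the gene, and `autoplot(an)` draws the per-embryo haplotype
map. Co-segregation works the same way from a PED file:

```r
ped <- read_ped(system.file("extdata", "fbn1_families.ped", package = "pgtlink"))
cosegregate(ped)
#>   family_id n_affected_carriers     m  elod elod_display pp1_strength
#> 1 1                           5     4 1.20          1.2  moderate
#> 2 2                           4     3 0.903         0.9  supporting
#> 3 5                           3     2 0.602         0.6  supporting
```

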