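---
title: "Models and methods behind pgtlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgtlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtlink)
```

pgtlink implements the computational core of a preimplantation genetic
testing (PGT-M) workflow for an autosomal-dominant single-gene disorder,
organized as in a Marfan-syndrome (*FBN1*) workup: classify the family's
candidate variant, quantify its co-segregation with disease, and deduce
which embryos inherited the disease-linked haplotype. This vignette
explains each model, its assumptions, the tunable parameters, and what the
synthetic-data generator does and does not emulate.

## Variant model

HGVS coding-DNA and protein descriptions are parsed into a fixed
consequence taxonomy with a total precedence order: canonical splice site
(intron offset ±1/±2) > frameshift (protein `fs` term) > in-frame indel
(del/dup/ins/delins with length divisible by 3) > synonymous (`X#=`) >
missense / nonsense (`X#Y`). Every parseable input receives exactly one
consequence; anything outside the grammar is an error naming the offending
token rather than a silent `unknown`. Internal whitespace is stripped
(published tables typeset `c.6615A > G`), one-letter residues are
normalized to three-letter codes, and the frameshift new-stop offset
(`*11`) is parsed but deliberately not validated against a reference
sequence — the package carries no transcript FASTA.

Domain annotation is an interval lookup on a packaged table of fibrillin-1
domain blocks. The table (`fbn1_domains_synthetic.tsv`) is an intentionally
coarse, synthetic map: real fibrillin-1 alternates 47 EGF-like modules with
TB and hybrid modules, and per-module boundaries matter for structural work
but not for the package's accounting of cbEGF membership and cysteine
substitutions. Residue 2520 is labelled cbEGF to match the variant table
the map accompanies, although some published annotations place it in a
TB/hybrid region; the file header records the discrepancy.

## ACMG/AMP engine

Evidence codes are inputs, not computed annotations: assigning PM2 from
population databases or PP3 from predictors is a curation task upstream of
this package. A token like `PS4_Moderate` is PS4 *applied at* moderate
strength, and the engine counts items entirely by applied strength — this
is how the curated evidence totals reconcile with the published classes.
Benign items applied at moderate strength (no such tier exists in the 2015
rules) are counted with benign-supporting.

Two results are reported side by side and deliberately not merged:

* **Categorical class** from the 2015 combining rules, evaluated on the
  applied-strength counts. The rules are checked pathogenic before likely
  pathogenic, benign before likely benign; if rules of both polarities
  fire, or none fires, the class is uncertain significance. BA1 is
  standalone and dominates the benign side. One consequence worth knowing:
  a set with one strong, two moderate and two supporting items satisfies a
  *pathogenic* clause, which is why one cohort variant curated as likely
  pathogenic classifies as pathogenic here; the divergence is pinned by a
  characterization test rather than patched.
* **Bayesian posterior** under the exponential framework: a very-strong
  item carries odds 350, and strong/moderate/supporting items carry
  exponents 1/2, 1/4, 1/8 on that odds; benign items contribute the
  negative exponent (BA1 counted like a very-strong benign item, a choice
  the 2015 framework leaves open). With prior 0.10 the framework
  reproduces the published "pathogenic possibility" values: one moderate +
  two supporting gives 67.5%, one moderate + three supporting 81.2%, one
  strong + two moderate + three supporting 99.7%.

The published range "67.5%–81.2%" for the uncertain synonymous variant is
consistent with dropping one supporting item from its four-code evidence
set; which item is dropped is not identified in the source material, and
the package simply exposes `bayes_posterior()` so either subset can be
computed. The posterior is displayed at one decimal in percent.

## Co-segregation eLOD

Under full penetrance, zero recombination between marker and locus, and an
autosomal-dominant model, each informative meiosis doubles the segregation
likelihood ratio, so eLOD = m·log10(2). The default `affected_only` mode
counts m = (affected carriers − 1): the index carrier anchors the
haplotype and is not an observed meiosis. The `full` mode additionally
counts each unaffected non-carrier offspring of a carrier, which is the
only reading under which a three-affected pedigree reaches eLOD 0.90 (two
affected meioses plus one unaffected). Untested individuals contribute
nothing in either mode. Thresholds for the PP1 applied strength
(supporting ≥ 0.6, moderate ≥ 1.2, strong ≥ 1.5) were chosen to reproduce
the published eLOD/strength pairs (0.90 → supporting, 1.20 → moderate,
1.50 and 2.00 → strong).

Display rounding is round-half-even at two decimals and divergences are
tested, not hidden: m = 5 gives 1.50515, displayed 1.51, one hundredth
above a published 1.50. A published "eight affected patients, eLOD = 2.00"
is not m·log10(2) for any integer m and is treated as an unresolved
inconsistency of the source rather than something to reproduce.

## Haplotype linkage and the HMM

A marker is *informative* when the carrier parent is heterozygous and the
other parent homozygous: the embryo's genotype then reveals the transmitted
carrier-parent allele (genotype minus the other parent's obligate
contribution). Phase — which carrier allele sits on the disease-linked
haplotype ("0") — comes from one reference relative of known variant
status: a child or embryo (its transmitted allele lies on hap0 if it is a
carrier) or a parent of the carrier (a homozygous genotype identifies the
allele the carrier inherited from it; heterozygous sites are ambiguous and
dropped). Phasing through a parent assumes no recombination between marker
and gene in that single meiosis — a 700 kb window keeps that probability
below ~1%.

Decoding is a two-state HMM over the informative markers; the state is
which carrier haplotype the embryo inherited there. Transitions follow a
Haldane no-interference map, p_switch = (1 − exp(−2rd))/2 at inter-marker
distance d, with r defaulting to 1e-8 per bp (≈1 cM/Mb); only distances
matter, not absolute coordinates. The emission is derived from the MDA
allele-dropout process with the surviving-allele convention. At an
informative site the embryo's two alleles are the transmitted allele t and
the other parent's allele b (equal at about half the markers): when t ≠ b,
dropout of b leaves a homozygote that is undeducible, while dropout of t
leaves a homozygote that *mimics the opposite haplotype*; when t = b,
dropout is harmless unless both alleles drop. Marginalizing, with
per-allele dropout probability `ado_rate` and a per-allele miscall
probability `geno_error`:

* P(missing) = (ado + ado²)/2
* P(wrong allele) = ado·(1 − ado)/2 + (1 − ado)²·err
* P(correct allele) = the remainder.

Treating the wrong-allele channel as ordinary rare genotyping error — the
naive emission — materially underestimates conflict rates at realistic
dropout (at ado = 0.3, about 13% of observations are wrong) and produces
borderline posteriors; the derived emission is what the package uses.

Verdicts are read at the gene: the mean posterior of the disease state over
the informative markers inside the gene span (or its two flanking markers
when none falls inside) must reach `min_posterior` (default 0.95) for a
carrier/non-carrier call; anything less is `no_call`. Ties under the
majority-rule fallback are likewise `no_call`, never an arbitrary pick — a
clinical-safety choice. Recombinations are reported as the interval between
the nearest flanking markers with *observed* alleles, because a crossover
cannot be localized across missing observations; a crossover outside the
gene interval changes support counts but not the verdict.

Defaults: `ado_rate = 0.10` and `geno_error = 0.01` (conventional
magnitudes for MDA single-cell libraries; true rates of any given library
are unknown and both are exposed in `hmm_params()` and `sim_config()`),
window = gene ± 350 kb (the probe-panel design around the target gene),
`min_posterior = 0.95`.

## Synthetic data

`simulate_family()` draws marker positions uniformly in a 1 Mb window
around a fictive 240 kb gene (positions sorted, deduplicated), per-marker
minor-allele frequencies from Uniform(0.1, 0.5), and founder haplotypes by
independent Bernoulli draws. One founder haplotype is flagged
disease-linked; the variant is a flag on the haplotype, not a VCF record,
so direct mutation detection and linkage stay decoupled. Meioses are
Poisson crossovers at r per bp with uniform positions; carrier status of a
non-founder is descent of the disease haplotype at the gene midpoint.
Where a template fixes a carrier status (the carrier parent of the couple),
the meiosis is redrawn until that status is realized — a conditioning step
that slightly biases that one gamete's crossover count and is irrelevant to
every property tested. MDA noise (allele flips at `geno_error`, then
per-allele dropout at `ado_rate` with the surviving-allele convention) is
applied to embryo genotypes only; parental and relative genotypes emulate
genomic DNA.

What the generator does **not** emulate: linkage disequilibrium between
markers, population demography, state-dependent amplification bias beyond
the dropout convention, trophectoderm mosaicism, and aneuploidy/CNV. Tests
passing on this generator therefore validate the decoding mathematics and
the pipeline plumbing under the stated noise model — not performance on
real MDA libraries, whose error structure is richer.

## Numerical and design choices

* Forward–backward runs with per-step scaling and Viterbi in log space;
  switch probabilities are clamped to [1e-300, 1 − 1e-16] so r = 0 and
  d = 0 stay finite. Viterbi ties resolve deterministically toward state 0.
* Problem sizes in the test suite (500 embryos for the accuracy property,
  200 replicates for crossover localization, instances of ≤12 markers for
  the exhaustive Viterbi oracle, panels of 600 markers so every simulated
  family carries at least 30 informative SNPs) were chosen as the smallest
  sizes at which the binomial noise of the checked proportions is well
  inside the asserted margins.
* All randomness flows from a single integer seed per simulation config;
  equal configs give byte-identical output, and fixtures round-trip through
  plain-text VCF 4.2 and PED losslessly.
* `read_ped()` validates parent references and acyclicity and reports the
  offending line; `genotype_matrix()` enforces strictly increasing marker
  positions and biallelic single-base alleles.

## Known limitations

The co-segregation model is the fully penetrant, zero-recombination
special case — no liability classes, no Bayes-factor generalization, and
no marker-based linkage (that is the haplotype module's job). The ACMG
engine implements the 2015 categorical rules, not the later points-based
system. The HMM tracks the carrier parent only; a report showing both parents'
transmissions (as in a clinical PGT table with four haplotype columns) is
obtained by running the analysis a second time with the parental roles
swapped, and the verdict always comes from the carrier parent's run. HGVS support covers the substitution/indel grammar used in
clinical variant tables, not the full specification (no alleles in trans,
no mosaic or repeat notation).
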