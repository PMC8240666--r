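# hlatrio

Family-based association analysis of high-resolution HLA genotypes.

Trio families — an affected child and two unaffected parents — let HLA
haplotypes be phased *exactly*: tracing which allele each parent
transmitted yields, per family, two transmitted and two non-transmitted
haplotypes across the classical HLA genes, with no population phasing
model. Comparing transmitted against non-transmitted haplotypes then tests
disease association in a way that is robust to population stratification,
and decomposing full haplotypes into sub-blocks at two nomenclature
resolutions (untruncated and two-field) separates causal candidates from
"hitchhiking" alleles carried along by linkage disequilibrium.

`hlatrio` implements this workflow for 11 classical HLA genes (HLA-A, -C,
-B, -DRB3/4/5, -DRB1, -DQA1, -DQB1, -DPA1, -DPB1; the DRB3/4/5 paralogs
share one haplotype slot with an explicit absence allele), for anyone
analyzing trio or case-control HLA typing data at allele-name resolution —
immunogenetics labs, disease-association studies, methods teaching. It
provides:

* **Nomenclature**: parsing, ordering and truncation of HLA allele names
  and Genotype List (GL) strings, including allelic (`/`) and phase (`|`)
  ambiguity.
* **Phasing**: Mendelian resolution of typing ambiguity by family review,
  transmitted/non-transmitted haplotype construction, decomposition into
  19 standard haplotype blocks, transmission count tables.
* **Family statistics**: genotypic TDT (additive/dominant/recessive
  conditional-logistic codings, Wald inference, separation diagnostics),
  MAX-TDT with permutation p-values, Bradley–Terry multiallelic TDT,
  conditional-logistic TDT with gene×gene interaction, carrier
  stratification.
* **Case-control**: per-locus/per-block allele tests with rare-unit
  binning, odds ratios with Woolf intervals and Yates-corrected p-values,
  Monte-Carlo exact Hardy–Weinberg test and per-genotype outlier screen.
* **Risk scores**: the ±1 net score with five categories and category odds
  ratios, and the HLA genetic burden (HLAGB = Σ dose × ln OR).
* **Synthetic studies**: a seeded trio/cohort generator with known ground
  truth (haplotype pool, multiplicative ascertainment disease model,
  ambiguity injection) so the whole pipeline is testable without access
  to restricted genotype data.

The core family-based statistic: for each candidate unit (allele or block
haplotype), each trio contributes the child's genotype and the three
pseudo-control genotypes constructible from the untransmitted parental
haplotypes; the conditional likelihood

    L(β) = ∏_f exp(β·x(d_child)) / Σ_{g ∈ risk set} exp(β·x(d_g))

is maximized over the genetic coding x (dose, carrier, or homozygote), and
RR = exp(β̂) is reported with a Wald interval. At β = 0 the additive score
statistic reduces to the classic TDT, (T−U)²/(T+U).

## Worked example

Simulate a study of 477 trio families under the default disease model
(risk DR15 block RR 3.42 and DPB1\*104:01 RR 2.90; protective
DRB1\*01:01:01 RR 0.38, among others), phase it, and test the main block:

```r
library(hlatrio)

sim <- sample_trios(477, seed = 1)
ph  <- phase_trios(sim$trios)
ph
#> <hla_phased> 477 trio families, 1908 haplotypes; 19 origin-ambiguous
#> and 0 Mendel-inconsistent locus flags

gtdt(ph, "DRB5*01:01:01~DRB1*15:01:01:01", scope = "DRB345~DRB1")
#> <hla_gtdt> DRB5*01:01:01~DRB1*15:01:01:01 [additive]
#>   RR = 3.55 (95% CI 2.8-4.49), p = 1e-25, n = 322

mtdt(ph, "DRB345~DRB1")
#> <hla_mtdt> DRB345~DRB1: 29 units
#>   LR = 210.9 on 28 df, p = 5.764e-30

gtdt(ph, "DRB1*01:01:01", scope = "DRB1")
#> <hla_gtdt> DRB1*01:01:01 [additive]
#>   RR = 0.211 (95% CI 0.121-0.369), p = 4.48e-08, n = 79
```

The estimated RR of 3.55 (CI 2.80–4.49) recovers the generating risk of
3.42 for the DR15 block from 322 informative families; the protective
allele is likewise recovered (true RR 0.38, estimate 0.21 with a wide CI —
79 informative families). Raw transmission counts show the distortion
directly:

```r
ct <- count_transmissions(ph, "DRB345~DRB1", het_only = TRUE)
head(ct[order(-ct$T), ], 3)
#>                                 unit   T   U
#> 25    DRB5*01:01:01~DRB1*15:01:01:01 312  88
#> 1  DRB3*01:01:02:01~DRB1*03:01:01:01  60 105
#> 20 DRB4*01:03:01:03~DRB1*04:04:01:01  59  56
```

Published carrier comparisons are a one-liner — among DR15-haplotype
carriers, 9/252 affected children versus 42/370 parents also carry
DRB1\*01:01:01:

```r
or_ci_yates(9, 243, 42, 328)
#> <hla_or> OR = 0.289 (95% CI 0.138-0.606), Yates p = 0.0008904
```

The full 60-test battery (11 genes + 19 blocks, both resolutions, gTDT +
mTDT + case-control) runs with `run_all()` and writes a unified results
table; `report_significant()` filters it. A thin command-line wrapper
lives in `inst/scripts/hlatrio-cli.R` (subcommands `simulate`, `run-all`,
`score`).

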