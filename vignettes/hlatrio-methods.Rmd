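---
title: "Family-based HLA association analysis with hlatrio"
author: "hlatrio authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based HLA association analysis with hlatrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlatrio)
```

## The problem

Disease association studies of the human MHC face two obstacles that
ordinary SNP pipelines do not: HLA alleles are massively multiallelic, with
names resolved at up to four colon-separated fields
(`DRB1*15:01:01:01`), and the region's strong linkage disequilibrium means
an allele can appear associated merely because it rides on a haplotype with
the causal variant (a *hitchhiking* allele). Family trios — an affected
child and both parents — solve a third problem: haplotypes can be phased
*exactly* by tracing which allele each parent transmitted, with no
population-level phasing model, and transmission itself provides an
association test that is immune to population stratification.

`hlatrio` implements that workflow end to end for eleven classical HLA
genes (A, C, B, DRB3/4/5, DRB1, DQA1, DQB1, DPA1, DPB1) modeled as nine
haplotype slots; the paralogous DRB3/DRB4/DRB5 genes share one slot,
`DRB345`, with an explicit `DRB345*absent` allele for haplotypes carrying
none of them, because at most one paralog is present per haplotype.

## Ambiguity resolution and phasing

Typing results arrive as Genotype List (GL) strings, whose operators encode
allelic ambiguity (`/`), genotype (`+`), phase ambiguity (`|`), in-phase
haplotypes (`~`) and locus separation (`^`). `resolve_family_ambiguity()`
expands each subject-locus into its candidate genotypes and keeps the
combination compatible with Mendelian segregation across the trio. When the
family is uninformative, the lowest-digit combination under the canonical
allele order is kept (child first, then father, then mother) — the
convention used when typing ambiguity cannot be resolved. The resolved
genotype is always drawn from the offered alternatives, never invented.

`phase_trios()` then assigns each child allele to its transmitting parent.
Three outcomes are possible per locus:

* a forced assignment — the usual case — yields four haplotypes per family
  (paternal/maternal × transmitted/non-transmitted);
* *origin ambiguity*: father, mother and child are all heterozygous for the
  same two alleles, so both assignments are Mendel-consistent. The locus is
  flagged; the sort-minimal child allele is assigned as paternal. The choice
  cannot bias allele-level counts — both assignments produce identical
  transmitted/non-transmitted allele multisets — so such families are kept
  for single-gene analyses but excluded from multi-locus block assembly,
  where the two assignments genuinely differ;
* a *Mendelian error* (child allele absent from a parent) excludes the
  family from that locus and any block containing it, never from the whole
  study. Every exclusion is logged.

`decompose()` projects haplotypes onto analysis scopes: the 11 genes and 19
haplotype blocks (`hla_blocks()`), each at untruncated and two-field
resolution — 60 standard test groups. Truncation to two fields collapses
synonymous and non-coding variants of the same protein; comparing the two
resolutions is what localizes a signal to a protein versus a specific
extended haplotype.

## Association statistics

**Genotypic TDT.** For one unit (an allele or block haplotype, treated as
biallelic against all others), each family contributes a risk set of four
genotypes: the child's true genotype and the three pseudo-controls formed
by the untransmitted parental alternatives. The conditional likelihood

$$L(\beta) = \prod_f \frac{e^{\beta x(d_{c,f})}}{\sum_{g \in R_f} e^{\beta x(d_g)}}$$

is maximized by Newton-Raphson from $\beta = 0$, where $d$ is the unit dose
and $x(d)$ is the additive ($x = d$), dominant ($x = 1_{d \ge 1}$) or
recessive ($x = 1_{d = 2}$) coding. We report the relative risk
$e^{\hat\beta}$ with Wald 95% interval and p-value. Only families in which
the coding varies across the risk set contribute (informative families).
The score statistic at $\beta = 0$ under the additive coding is
algebraically the classic allelic TDT, $(T-U)^2/(T+U)$ over heterozygous
parents; the test suite verifies this identity numerically, and
cross-checks the full fit against an independent conditional-logistic
implementation (`survival::clogit`'s exact conditional likelihood).

Complete separation (every informative parent transmits, or none does) is
flagged rather than hidden: the point estimate is reported as infinite (or
zero) together with a one-sided profile-likelihood bound, obtained where
the conditional log likelihood falls $\chi^2_{1,0.95}/2$ below its
supremum, and the score-test p-value. Internally the Newton iteration is
damped (step clamp at ±2) and stopped at $|\beta| = 15$, beyond which the
likelihood is flat to machine precision.

**MAX-TDT.** Because the true genetic model is unknown, `max_gtdt()` takes
the maximum of the three Wald chi-squares and calibrates it by permutation:
within each parent, transmitted and non-transmitted haplotypes are swapped
with probability ½ — exchangeable under the null of no transmission
distortion — and the maximum statistic is recomputed; the p-value is
$(1 + \#\{perm \ge obs\})/(n_{perm}+1)$ with 1000 permutations by default.
The permutation scheme exploits the fact that a label swap merely moves the
child to a different column of the fixed 4-genotype risk set.

**Multiallelic TDT.** `mtdt()` treats every heterozygous-parent
transmission as a pairwise contest won by the transmitted allele and fits
Bradley-Terry worth parameters by MM iteration (relative tolerance
$10^{-10}$, worths normalized to sum to one). The likelihood ratio against
fair-coin transmission is compared with $\chi^2$ on (number of alleles − 1)
degrees of freedom. A disconnected comparison graph — possible in stratified
subsets — is fitted per connected component with additive degrees of
freedom. With two alleles the statistic reduces to the closed-form binomial
likelihood ratio, which the tests exploit as an oracle.

**Interaction.** `conditional_gtdt_interaction()` extends the additive
fit with a family-level exposure E (the family carries the conditioning
unit): linear predictor $\beta_G x + \beta_{G \times E} x E$, reported with
a 2-df Wald test. Published conventions for the single printed "RR" of such
models are ambiguous, so both $e^{\beta_G + \beta_{G\times E}}$ (exposed
stratum) and $e^{\beta_G}$ (unexposed) are returned, clearly labeled.

**Stratification.** `stratify_trios()` removes whole families carrying an
exclusion unit (any member; the four parental haplotypes cover all alleles
in the trio), `stratify_cohort()` removes individual carrier subjects. By
default a unit is matched at its own field depth, so a two-field key
excludes carriers of any finer variant.

**Case-control.** `locus_cc_test()` compares per-group allele (or block
haplotype) counts: units with minimum expected cell count below 5 are
pooled into a `binned` category (configurable), an overall R×2 chi-square
is computed on the pooled table, and each unit gets a unit-versus-rest 2×2
with odds ratio, Woolf interval
$\exp(\ln OR \pm 1.96\sqrt{\sum 1/n_{ij}})$ and Yates-corrected chi-square
$N(\max(0, |ad-bc|-N/2))^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, with
Haldane-Anscombe +0.5 when a cell is zero. Because cohort genotypes are
unphased and population phasing is out of scope, block-level case-control
tests require phased haplotype columns; the synthetic generator supplies
them as ground truth, and real data would need externally phased input.

**Hardy-Weinberg diagnostics.** `hwe_exact_mc()` is the conditional exact
test in the Monte-Carlo form: the 2n observed allele copies are repeatedly
re-paired at random and the probability of each table (conditional on
allele counts) compared with the observed one; 17,000 replicates by
default, seedable. Tests verify agreement with full enumeration on every
biallelic table of up to 12 individuals. `genotype_outliers()` screens each
genotype against its HWE expectation with a collapsed genotype-versus-rest
1-df chi-square, reporting direction (excess/deficit) at a 0.05 threshold —
a deliberately simple per-genotype screen whose results should be read as
flags, not calibrated simultaneous inference.

## Cumulative risk scores

`score_profiles()` assigns each subject +1 per risk factor present and −1
per protective factor present (presence = carrier status at the factor's
resolution) and classifies the net score into five exhaustive, mutually
exclusive categories: Risk, Neutral Zero (no factor), Neutral
Risk-Protective (equal nonzero counts), Protective Risk (negative score
with ≥1 risk factor), Protective (protective only). `category_or()`
compares any category against Neutral Zero in a case-control 2×2. The HLA
genetic burden (`hlagb()`) is $\sum_f \text{dose}_f \ln OR_f$; presence
uses carrier status while HLAGB uses allele dose because the two published
definitions differ, and both reading rules are separately configurable
(`hlagb_mode = "carrier"`). Whether block factors should count per copy or
per carrier is not standardized; dose-per-copy is the default. Group
comparisons use the two-sided Mann-Whitney test (medians with IQRs are
reported); the underlying publications do not name their test, and the
rank test makes no normality assumption about burden scores.

## The synthetic study generator

`sample_trios()` draws four parental haplotypes i.i.d. from a pool of 30
multi-locus templates with frequencies patterned on a European-ancestry
population (`default_pool()`), transmits one per parent uniformly, and
rejection-samples families until the child is affected — the
affected-proband ascertainment of real MS family collections; parents are
never ascertained. The disease model is multiplicative per haplotype copy
(`rr^dose`), with optional homozygote-only (recessive) and
condition-on-carrier (interaction) effects; the default mirrors the
magnitudes of the principal published MS associations (risk
`DRB5*01:01:01~DRB1*15:01:01:01` RR 3.42 and `DPB1*104:01` RR 2.90;
protective `DRB1*01:01:01` RR 0.38, `DQB1*03:01` RR 0.68, `B*27:05`
RR 0.38) at baseline penetrance 0.01. The pool anchors the DR15 haplotype
at frequency 0.14 and the `DPB1*104:01` haplotype at 0.018, matching the
published control-group frequency of that allele (0.018).

Two deliberate design choices matter for interpreting test results. First,
third- and fourth-field name variants in the pool are largely
haplotype-specific — as they are in full-gene sequencing data, where
extended haplotypes carry characteristic intron variants. This keeps
origin-ambiguous loci rare, which is why ≥99% exact phase recovery is an
achievable (and verified) property; typing at lower resolution would
phase less cleanly. Second, the generator draws haplotypes independently
(linkage equilibrium between the two haplotypes of a subject, no
recombination): it emulates ascertainment, Mendelian transmission, typing
ambiguity and multiplicative risk, but not LD decay within the region,
population substructure, or genotyping error. Passing tests therefore
validate the statistical machinery under the stated sampling model, not
robustness to those unmodeled features of real data.

`inject_ambiguity()` inserts `/` and `|` ambiguity by rule, always keeping
the true genotype among the alternatives, so resolution can be tested
against ground truth.

## Numerical and design choices

* Allele ordering is byte-wise on zero-padded numeric keys
  (locale-independent); a shorter field list precedes its extensions, the
  absence token sorts last, and expression suffixes (N, L, Q, ...) are
  carried but never ordered on.
* Wald p-values are reported for the gTDT, matching the conventions of the
  established family-TDT software; the score statistic is also exposed for
  the TDT equivalence.
* The 19-block list is shipped as data (`hla_blocks()`); the published
  enumeration contains one duplicated entry, collapsed here to the 19
  unique definitions. Users may add any chromosomally ordered block.
* No multiple-testing correction is applied across the 60-test battery by
  default, replicating the upstream 0.05-per-test convention;
  `report_significant(fdr = TRUE)` appends Benjamini-Hochberg q-values for
  readers who want them.
* Monte-Carlo p-values use the add-one estimator
  $(1+\#\{\cdot\})/(n+1)$, which cannot return zero.
* Problem sizes in the test suite — 200 null replicates of 500 trios for
  calibration, 100 replicates of 477 trios for interval coverage, 1000
  trios for phase recovery, all biallelic HWE tables to n = 12 — were
  chosen to give the binomial/Monte-Carlo bands quoted in each test while
  keeping the default suite comfortably runnable on a laptop.

## Known limitations

* Extended multi-case pedigrees are out of scope for statistical testing
  (only trios are analyzed); real studies treat them descriptively.
* Block-level case-control analysis requires phased input; no EM haplotype
  frequency estimation is provided, by design.
* The per-genotype HWE outlier screen is a simple collapsed chi-square; it
  is not an exact small-sample test.
* GL-string parsing covers the operator grammar used in genotype tables;
  multilocus phased `^`/`~` documents and registry ambiguity codes (MAC)
  are not interpreted.
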