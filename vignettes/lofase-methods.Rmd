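---
title: "Methods: paired tumor/normal allele-specific expression of LOF tumor-suppressor alleles"
author: "lofase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor/normal ASE of LOF tumor-suppressor alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofase)
```

## The problem

Classical two-hit reasoning holds that a recessive loss-of-function (LOF)
allele of a tumor-suppressor gene (TSG) is harmless while the wild-type
allele is intact. Bulk RNA-seq of matched normal/tumor pairs lets us test a
complementary route to functional loss: allele-specific expression (ASE), in
which the LOF allele of a heterozygote is transcribed at a higher level than
the wild-type allele. `lofase` implements the full analysis chain for this
question — from per-site allele counts to paired pattern classification and
mechanism attribution — together with a synthetic cohort generator that
plants known ASE patterns and mechanisms so that every stage can be
validated against truth without access to controlled patient data.

## SNP-level model

At a heterozygous site with `ref` and `alt` informative RNA reads
(`n = ref + alt`), the no-ASE null is `ref ~ Binomial(n, p0)`. The expected
reference ratio `p0` is *not* 0.5: reads carrying the alternative allele map
to the reference genome less efficiently, inflating the reference ratio.
Two defenses are applied, in order:

1. **Mapability filter.** Sites inside genomic windows with 50bp mapability
   below 1 are removed outright, along with sites failing the depth filters
   (at least 20 informative reads per site and 4 per allele; thresholds are
   inclusive, as "minimum" implies).
2. **Nucleotide-pair bias model.** For each of the 12 ordered `ref>alt`
   substitution pairs, `p0` is estimated as the pooled reference-read
   fraction over that pair's het sites and used in place of 0.5. Pairs
   observed at fewer than `min_sites_per_pair` sites fall back to 0.5.

The test itself is the exact two-sided binomial ("minimum-likelihood" tail
definition: the total probability of outcomes no more likely than the
observed count). A site is a significant ASE SNP only when **both** the raw
p-value is below 0.005 and its Benjamini–Hochberg q-value within the
sample is at most 0.05; the conjunction is deliberate and matches the
pipeline's published thresholds. Significant sites carry a directional
state (`REF` when the reference ratio exceeds `p0`, `ALT` otherwise);
non-significant sites are `BAL`.

```{r}
# 18 reference reads of 20 against an unbiased null
binomial_ase(18, 20, 0.5)
```

### Scope of the bias model

Whether bias should be estimated per library or across a cohort is a real
design choice. Mapping bias is partly library-specific, so
`fit_bias_model()` defaults to refusing multi-sample input unless pooling is
requested explicitly. The pipeline driver `run_pipeline()`, however,
defaults to the pooled, cohort-level estimate ("genome-wide" ratios over the
population of samples): on panels of a few hundred sites a per-library
estimate has only ~15–20 sites per nucleotide pair, and the ASE sites inside
the estimation window contaminate it enough to cost measurable sensitivity.
Pooling trades a small amount of library specificity for a much more stable
`p0`; both modes are exposed.

## Gene-level model

Gene-level ASE aggregates a gene's het SNPs by pseudo-phasing: each site's
higher-count allele is assigned to a putative major haplotype (ties break
toward the reference allele, a logged convention that only affects exact
50/50 sites), and the major allele frequency (MAF) is the summed
major-allele count over the summed depth — by construction at least 0.5.

Because the major haplotype is chosen *after* seeing the data, the naive
binomial p-value for the aggregate is anti-conservative. Instead of the
meta-analytic machinery of the original gene-level protocol, significance
is calibrated by Monte Carlo: each replicate redraws every site binomially
at its pair-specific `p0`, re-derives the major haplotype within the
replicate, and the p-value is the smoothed fraction
`(1 + #{MAF* >= MAF}) / (n_mc + 1)`. The post-hoc maximisation is thereby
built into the null, and the resulting p-values are conservative
(super-uniform) under no ASE — the property the calibration tests assert.
A gene is an ASE gene when MAF > 0.7 and the Monte-Carlo p-value is below
0.05 at FDR 5% across the sample's genes. The haplotype label is
`reference` if the major haplotype holds more reference than alternative
alleles, `alternative` in the opposite case, and `ambiguous` on ties.

## Paired patterns

Each site observed post-filter in both members of a pair is classified from
the two directional states plus a two-sided Fisher exact test on
`[[refN, altN], [refT, altT]]`:

| normal | tumor | pattern |
|--------|-------|---------|
| BAL | ALT | P1 |
| REF | BAL | P2 |
| REF | ALT | P3 |
| BAL | REF | P4 |
| ALT | BAL | P5 |
| ALT | REF | P6 |

All six require Fisher p < 0.05 (the combined binomial–Fisher rule applies
uniformly, including P3/P6 where the two binomial calls alone might seem
sufficient); otherwise the site is `no-change`. `(BAL, BAL)` is `no-change`;
same-direction significance in both samples (`(REF, REF)` or `(ALT, ALT)`)
has no pattern of its own and is labelled `concordant`, folded into the
"No ASE" row of summary tables so that rows stay exhaustive. Fisher tables
with a zero margin carry no ratio information and return p = 1 with a log
entry. Two exact symmetries follow from the definitions and are enforced in
tests: swapping the normal and tumor labels maps P1↔P5, P2↔P4, P3↔P6, and
swapping the allele roles (with `p0 → 1 − p0`) maps P1↔P4, P2↔P5, P3↔P6.

## Genotypes and the two-hit classifier

DNA genotypes are called from count tables by thresholds: depth ≥ 8, alt
reads ≥ 2, VAF ≥ 0.2, and a one-sided binomial test of the alt count
against a 1% sequencing error rate at p < 0.01. The hom-alt boundary (VAF ≥
0.8) follows the common variant-caller convention; it is configurable
because the source pipelines never state it.

A patient × TSG is consistent with a somatic second hit when a normal-tissue
het LOF site has, in priority order: the same site homozygous-alternative in
the tumor (`same_hom`); a tumor-novel LOF het phased to the opposite
haplotype (`compound_het` — unphased candidates are reported as
`compound_candidate_unphased` and never counted, since without phase the new
hit could sit on the already-damaged haplotype); or an overlapping tumor
segment with minor copy number 0 (`loh`). The priority order is a package
convention; the classes rarely co-occur and the ranking records the most
direct evidence first. LOF classification accepts the truncating classes
(nonsense, frameshift, splice acceptor/donor, whole-gene deletion — plus
start/stop lost in second-hit mode), missense called deleterious by SIFT
*and* damaging by PolyPhen-2 (both `probably_` and `possibly_damaging`
count by default; a strict mode restricts to `probably_`), with any
ClinVar benign/likely-benign label overriding everything.

## Mechanism attribution

For each site with a paired pattern, independent flags ask what could drive
the tumor's imbalance:

- **DNA concordance** — the matched tumor DNA counts are themselves
  significantly imbalanced (exact binomial vs 0.5, p < 0.05) in the same
  direction as the RNA. "Correlated DNA counts" is operationalized this way
  because the source material never defines it; the threshold is
  configurable. DNA below the genotype depth floor is undetermined and
  excluded from denominators.
- **CNV duplication** — an overlapping tumor segment with total copy
  number > 2 and unequal allele copies.
- **cis-eQTL phase** — the gene is an eGene and some het eQTL's
  high-expression allele (sign of the slope, alt-allele convention) lies on
  the gene's over-expressed (major) haplotype with LD `r ≥ 0.42` to the ASE
  variant. LD is consumed from an input table; computing it from a
  reference panel is out of scope.
- **Methylation** — gene-level methylation differs by more than 1.3-fold
  between normal and tumor, in either direction.
- **Splice-site overlap** — the SNP falls in a canonical 2-base donor or
  acceptor dinucleotide of an annotated intron, strand-aware.
- **Exon skipping / antisense** — the ISO1 split-read count (reads spanning
  the exons flanking the skipped exon), normalized to counts per million
  with pseudocount 1, rises at least 1.5-fold in the tumor; antisense
  support additionally requires both the donor and acceptor antisense folds
  to reach 1.5. Antisense is only evaluated at skipping events.

Summary percentages round half away from zero to one decimal, matching how
such tables are conventionally printed; `round_half_up(35.15) == 35.2`
where base `round()` would give 35.1.

## The synthetic cohort generator

`simulate_cohort()` emits every input the pipeline consumes, with truth.
Its defaults are the study conditions the package is validated under, fixed
once:

- **Cohort and panel**: 20 patients × 100 genes, 1–3 het SNPs per gene on
  4 contigs, exons of 150 bp separated by 400 bp introns.
- **Depth**: negative binomial, mean 60, dispersion (size) 5, for both RNA
  and DNA — overdispersed coverage typical of exome-scale data; the sources
  are silent on depth distributions, so these are placeholders chosen for
  realism, not estimates. `dispersion = Inf` gives fixed depth and is used
  by validation runs that specify an exact depth.
- **Bias**: fixed per-pair `p0` between 0.51 and 0.56 (transitions higher),
  injected by odds multiplication so that a balanced locus is observed at
  exactly the pair's `p0` and the bias estimator can recover it.
- **Pattern mix**: approximately the cohort-average rates seen in real
  paired data (P1 0.07, P4 0.035, the rest small, 86% no-change) with
  imbalanced states at reference ratio 0.75 / 0.25.
- **Mechanisms**: tumor-ASE loci (P1/P3/P4/P6) are split 30% CNV-driven
  (copy state 3:1, DNA ratio following the RNA direction), 30% exon
  skipping (ISO1 fold 2.5, antisense fold = coupling × skip fold with
  coupling 1), 40% pure-regulatory. Normal-side patterns (P2/P5) are always
  pure-regulatory: a somatic copy-number event cannot explain imbalance
  present only in the normal tissue. Mechanism labels are mutually
  exclusive per locus for clean truth evaluation; real tumors mix them.
- **Isoform/antisense scale**: library size 1e5 with baseline ISO1 rate
  1e-3 (≈100 split reads) and antisense rate 5e-4 — high enough that a
  1.5-fold decision threshold on CPM-with-pseudocount folds is not
  dominated by Poisson noise.
- **DNA counts are bias-free**: the nucleotide-pair model targets RNA read
  mapping; simulating DNA at the planted allelic ratio keeps the DNA
  concordance null exact. Real exome reads carry their own (smaller)
  mapping bias — a known simplification.

Randomness is organized in documented streams derived from the master seed
by integer hashing (`sub_seed()`): the gene panel uses stream (0), patient
`i` × gene `g` uses stream (1, i, g), gene-level Monte-Carlo replicates use
(2, ·) and (3, ·). Adding patients or genes therefore never perturbs the
draws of earlier units, and identical configurations are byte-identical on
disk.

What the generator does **not** emulate: read-level artifacts (FASTQ/BAM
are out of scope), overdispersion of allele counts beyond binomial
(beta-binomial noise from e.g. clonal heterogeneity), co-occurring
mechanisms at one locus, tumor purity/clonality, and genuinely
library-specific bias. Passing the validation suite therefore demonstrates
that the statistics are correctly implemented and calibrated under the
stated model — not that the model captures every property of patient data.

## Numerical choices

- Exact binomial and Fisher two-tail definitions use the standard
  minimum-likelihood convention with a 1e-7 relative tolerance for
  floating-point ties.
- Site-level major-allele ties break toward the reference allele (logged);
  Fisher tables with zero margins return p = 1 with a log entry;
  zero-information sites are skipped and logged, never silently dropped.
- Bias `p0` estimates are clamped to (1e-6, 1 − 1e-6) so degenerate pools
  cannot produce a boundary null.
- BH is applied within one sample and site universe, matching per-sample
  reporting of ASE proportions; gene-level BH is within sample across
  genes.
- Percentages round half away from zero to one decimal.

## Problem sizes used in validation

The validation suite measures: the exact-test oracle on all `n ≤ 25` at
`p0 ∈ {0.4, 0.5, 0.6}`; type-I error on 10,000 null sites at depth ~100
(and BH behaviour over 200 null cohorts of 1,000 sites); paired-pattern
recovery on a 20-patient × 100-gene cohort at fixed depth 100 and effect
ratio 0.75 with equal mass on P1–P6 (equal mass keeps every pattern's
precision/recall measurable on a few hundred sites); gene-level calibration
on 500 null genes with 10,000 Monte-Carlo replicates each; and mechanism
recovery at planted skip fold 2. These sizes were chosen so each estimate's
own sampling error is small relative to the property being asserted.

Under those conditions the pipeline recovers planted patterns with
per-pattern precision and recall above 0.9; the residual misses are
borderline binomial draws that fail the Fisher gate — a direct consequence
of the combined-test definition, not an implementation artifact. At the
generator's *default* overdispersed depth (NB mean 60), per-site power at
p < 0.005 is substantially lower and recall drops to roughly 0.4–0.8
depending on the pattern, which the analysis drivers report as-is.

## Known limitations

- Binomial (not beta-binomial) counts in both the model and the generator;
  real allele counts are overdispersed, so real-data type-I error will
  exceed the nominal rate at deeply covered sites.
- Count-based genotyping can misread strongly CNV-skewed tumor DNA as
  acquired homozygosity (see the second-hit analysis driver); a real
  pipeline faces the same confounding.
- Antisense orientation calling from unstranded libraries is consumed, not
  performed; the antisense counts are taken at face value.
- The eQTL stage consumes externally computed LD; unphased cohorts cannot
  assert compound heterozygosity.
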