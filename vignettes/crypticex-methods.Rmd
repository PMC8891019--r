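---
title: "Methods: quantifying UNC13A cryptic-exon inclusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying UNC13A cryptic-exon inclusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticex)
```

## Background and model

*UNC13A* is a minus-strand gene whose intron 20–21 harbours two overlapping
cryptic exons de-repressed when nuclear TDP-43 is lost: a 128-bp and a
178-bp form sharing their 3′ end, the longer extending 50 bp further 5′.
Because the 3′ boundary is shared, both CE isoforms produce a single CE–e21
junction, while the e20-side junction distinguishes the two forms. The
128-bp form dominates in expression data, so the package's generator defaults
to a small share (10%) for the 178-bp form; that share is a free parameter,
not an estimate — no measured abundance ratio for the two forms is
available.

The package works against a toy single-chromosome locus
(`build_toy_locus()`) that reproduces this geometry exactly (exon widths,
shared 3′ end, the 50-bp 5′ extension, an exonic SNP inside the CE, an
intronic SNP and a CATC-repeat site in the intron) at coordinates small
enough for fast, download-free tests. Real hg38 coordinates appear only in
documentation and in the geometry checks of the acceptance material.

## Junction quantification

Aligned blocks are reconstructed from CIGAR strings under SAM
reference-consumption rules: `M` and `D` extend the current block (a
deletion is not a splice), `N` closes it and opens the next, `I`/`S` consume
no reference, and any other operator is a parse error. One junction is
emitted per inter-block gap whose flanking blocks are both at least
`min_overhang` bases (default 6 nt — the overhang used when junction reads
were extracted for intron-cluster analysis in the source pipeline; the
original bedtools counting step states no overhang, so the same default is
applied uniformly and is configurable).

Read filters mirror the source pipeline's contract rather than re-running
its tools: reads flagged as PCR duplicates are removed (duplicate marking is
assumed done, as by Picard), and uniqueness is a single MAPQ threshold
(default 255, matching `samtools view -q 255` on STAR output). Junctions are
classified by exact boundary equality with the model junctions — no fuzz
window, because the statistic counts reads spanning specific annotated
junctions; near-misses are tallied as `unclassified`. A read spanning two
junctions increments both counts (counting is per junction), but contributes
at most once to any single junction.

Beyond junctions, `count_sample()` tallies reads wholly inside CE178
(`within_ce`, inclusion-supporting), reads with aligned bases in the
e20–e21 intron outside CE178 (`intron_body`, uninformative), reads
overlapping any model exon (`exonic_reads`) and a naive TPM,
`(exonic_reads / exon_union_kb) / (library_size / 10^6)`. This TPM
stand-in normalizes by the model-exon union only — adequate as the
expression gate on a one-gene locus, not a transcriptome-level estimate.

## Suitability gate and CE call

A sample is **suitable** when `naive_tpm >= 1.55` *or* `e19_e20 >= 20`
reads; both thresholds are inclusive ("at least"). The e19–e20 junction is
shared by the canonical and CE isoforms, so it gauges *UNC13A* coverage
independently of splicing state. A suitable sample is **CE-positive** when
CE-junction evidence reaches 2 reads. Two readings of that criterion exist,
and both are implemented: the default pools the union of the e20–CE and
CE–e21 junction classes (the plain-language reading, and the more sensitive
detection floor); `mode = "per-junction"` requires the threshold at a single
class. The gate strictly precedes the call: an unsuitable sample is never
positive.

Two inclusion statistics are computed, `NA` (a flag, never an exception)
when their denominator is zero:

* **inclusion fraction** — CE-supporting reads (the three CE junctions plus
  `within_ce`) over CE-supporting plus e20–e21 reads. Unspliced intron-body
  reads support neither inclusion nor exclusion and are excluded from the
  denominator; including them would make the statistic depth- and
  pre-mRNA-dependent. They remain available in `intron_body` for users who
  prefer the broader denominator.
* **junction PSI** — inclusion evidence is the *mean* of the two inclusion
  junction measurements (e20–CE128 + e20–CE178, and CE–e21), standard
  junction-PSI practice that avoids double-counting a read spanning both;
  `psi = inclusion / (inclusion + e20_e21)`.

As a cohort-level QC, `qc_junction_correlation()` computes the Pearson
correlation of e19–e20 versus e20–e21 counts across samples; when coverage
drives both (as in real cohorts), the correlation is near 1.

## Allele-specific inclusion

All stored alleles are forward-strand (the dbSNP/VCF convention);
`strand_convert()` maps to the transcribed strand (reverse complement on
minus; an involution). Amplicon reads spanning e19→e21 are classified by
exact junction-chain match into canonical/CE128/CE178/other, and the base at
the CE SNP is read from the covering block. Bases that are neither the risk
nor the reference allele are tallied as `other` and excluded from the
percentage — the neutral choice, biasing neither allele. Per-sample risk and
reference percentages are paired in a two-sided paired t-test
(`d = risk% − ref%`, `df = n − 1`); an exact per-sample binomial test
against 0.5 is available as a secondary check. Whether percentages should be
computed per read or after collapsing identical amplicons is not settled;
the package counts per read.

## Haplotype genetics

`genotype_chisq()` tests genotype independence between two loci on the
contingency table of observed genotype classes: no continuity correction, no
cell pooling, degrees of freedom `(rows − 1)(cols − 1)` over observed
non-empty classes — the behaviour contract of vcftools' genotype chi-square,
with sites restricted to 2–8 alleles. Loci with a single observed genotype
class are a degeneracy error. `repeat_dosage()` accepts only exact tandem
insertions of the motif ((length difference)/4 units for CATC), flagging
anything else non-conforming rather than guessing. `haplotype_dose()` codes
the risk-haplotype count additively from the two tag SNPs when their
risk-allele counts agree, excluding discordant or missing individuals with a
recorded reason — the same unphased argument that justifies dose coding in
strongly linked loci. `ols_association()` fits `abundance ~ dose`
(+ optional covariates; the covariate set behind the published dose effect
is not enumerated, so the default model is covariate-free) and flags
zero residual variance instead of reporting a meaningless p-value.

## The simulator: what it emulates, and what it does not

`simulate_rnaseq_sample()` draws single-end reads uniformly along each
isoform with mixture `{1 − ψ, ψ(1 − s), ψs}` (s = `ce178_share`). Read
counts per isoform are proportional to mixture weight × number of start
positions, so per-junction counts are proportional to isoform abundance and
junction PSI is unbiased. The total read number is scaled by the exact
junction-spanning start-position fraction so `depth` means *expected
junction-informative unique reads*. Duplicates are exact copies flagged
0x400 (simulating the output contract of duplicate marking, not re-deriving
it positionally); non-unique reads carry MAPQ 3; substitution errors are
applied per base. Identical seeds give byte-identical SAM/VCF/TSV output
(R's default generator, seed always logged).

Defaults chosen once, on the scale a bulk cortical RNA-seq sample of a
moderately expressed gene would show: `read_length` 100 nt,
`duplicate_rate` 0.05, `nonunique_rate` 0.02, `error_rate` 0.001. The
genotype simulator links each observed locus to a latent risk haplotype with
copy probability `sqrt(r2_link)`, giving pairwise LD r² = `r2_link`
(default 0.9, strong LD as for the two tag SNPs in Europeans);
`risk_haplotype_freq` defaults to 0.35, the scale of the risk-allele
frequency in European cohorts. Risk-class haplotypes add 3–5 CATC units,
reference 0–2, matching the reported stratification.

Known gaps between simulation and real data — hence what passing tests do
*not* show: no pre-mRNA, so intron-body reads never arise from the generator
(the tally is exercised with hand-built alignments); no fragment-length or
positional-bias model; no base-quality model or indel errors; single-end
reads with at most one junction per gap; one gene, so naive TPM is not a
transcriptome TPM; amplicon reads have no PCR or UMI structure. Cohort-scale
effects that depend on restricted patient data (tissue heterogeneity,
pathology-correlated covariates) are outside the generator's scope.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; junctions are represented by
  the intron interval; `interval_width()` is order-agnostic so minus-strand
  high-to-low printing does not change widths.
* Undefined statistics (zero denominators, zero variance) return `NA` flags
  with warnings where silent `NA`s could mislead; precondition violations
  (homozygous genotype for imbalance, < 2 paired samples, degenerate
  chi-square classes, collinear designs) are errors.
* Zero residual variance in OLS sets `zero_residual` and leaves the p-value
  `NA` rather than 0.
* Ct values above 40 are clamped to 40 before ΔΔCt, the standard handling of
  non-amplifying wells.
* Ties in Spearman correlation use average ranks.

## Problem sizes used by the test material

The suite validates at sizes chosen to give tight Monte-Carlo bounds while
keeping a full run in minutes: oracle equivalence on 20 samples of ≤ 10⁴
reads against an independent per-read rescan; PSI recovery on 40 samples at
2500 junction-informative reads (mean absolute error < 0.02); detection
specificity on 100 null samples (zero positives) and sensitivity at
ψ = 0.05 with 500 reads (≥ 95% of seeds); allelic-test calibration on 500
null triplicates (KS at α = 0.01) and power at odds ratio 3 with 1000 CE
reads (> 90% rejection); chi-square type-I error on 1000 cohorts of n = 500
(within [0.03, 0.07]); and 95%-CI coverage of the dose regression over 500
replicates of n = 85 (within [93%, 97%]).

## Limitations

The pipeline classifies junctions against a supplied model only — it is not
a discovery tool (no de novo junction finding, the role of MAJIQ/LeafCutter
in the original analyses). Survival modelling, differential expression and
image-based quantification are out of scope. The inclusion-fraction
denominator and the ≥ 2-read pooling are documented interpretations where
the published wording admits two readings; both alternatives are exposed as
options so users can match either convention.
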