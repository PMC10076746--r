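---
title: "Trio genomic diagnosis with expression-based dosage validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio genomic diagnosis with expression-based dosage validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodx)
```

## The problem

Roughly 5% of children with autism spectrum disorder (ASD) carry a single
diagnosable rare mutation: a de novo protein-truncating variant (PTV) in a
dominant ASD gene, or a copy-number variant (CNV) hitting a known
microdeletion/microduplication syndrome region. After whole-genome
sequencing of a proband–father–mother trio and upstream variant calling,
the diagnostic questions are mechanical but error-prone: which small
variants are truly de novo and truncating, which CNV calls correspond to a
known syndromic region, and — because variant calls alone can mislead —
does the patient's own peripheral-blood transcriptome show the expression
footprint the variant predicts? `triodx` implements this post-calling
stage: triage, RNA-seq dosage validation, qPCR copy-number confirmation,
and cohort-level yield reporting, plus a synthetic cohort generator that
stands in for controlled-access patient data.

## Triage model

**Inheritance.** A variant's origin is classified from the trio genotype
triple: the proband carries the allele and neither parent does (de novo);
one parent carries it (paternal/maternal); both (inherited from both). A
non-carrier proband or a missing parental genotype yields `ambiguous` — a
value, not an error, because downstream yield arithmetic must count such
variants as unresolved rather than crash.

**PTV definition.** Nonsense and frameshift consequences, plus splice
donor/acceptor variants whose intronic offset (parsed from the HGVS cDNA
string, e.g. `c.605+1G>A`) is within ±2 of the exon boundary. Deeper
splice-region variants are excluded; every published splicing diagnosis
this package's bundled cohort contains sits at ±1/±2, and the canonical
window is the standard clinical convention. A proband is **SNV-positive**
iff it carries at least one *de novo* PTV in a listed ASD gene (SFARI-style
list, user-supplied). Inherited PTVs never qualify — dominant de novo
inheritance is the model.

**CNVs.** Calls below the 100 kb calling resolution are dropped (inclusive
boundary). A CNV is diagnostic when it matches a catalog of known
syndromic regions at ≥ 50% reciprocal overlap — intersection divided by
each interval's length, both quotients past the threshold, the
field's conventional CNV-equivalence rule — **regardless of origin**
(known-region CNVs inherited from an unaffected parent are retained, with
reduced penetrance the usual explanation), or when a deletion overlaps a
haploinsufficiency-flagged listed gene. Parental carriage of a CNV is
decided by the same reciprocal-overlap rule against each parent's call
set, because CNV genotypes come from presence/absence of calls rather than
VCF GT fields at low depth. Ties among matching catalog regions break to
the higher reciprocal overlap, then the smaller region, then the
lexicographically first name, making the match deterministic.

Coordinates are 1-based and inclusive on both ends everywhere inside the
package; BED input/output converts at the file boundary. CNV size is
`end − start + 1`.

## Expression dosage validation

The validation substrate is a genes × samples matrix of blood RNA-seq
quantifications over the proband cohort, normalized by median-of-ratios
size factors (each sample's median ratio to the per-gene geometric-mean
profile over genes with nonzero geometric mean). A gene is **expressed in
blood** when its cohort mean normalized value reaches `min_mean` (default
1.0 on the normalized scale) — genes absent from the matrix are simply
not expressed.

Two per-gene statistics compare the carrier with the cohort:

- z-score: \(z_g = (x_{g,p} - \bar{x}_g) / \sigma_g\), with the mean and
  *population* (n-denominator) standard deviation taken over **all**
  samples, the index patient included; \(\sigma_g = 0\) gives \(z = 0\).
- log2 fold change: \(\log_2\!\big((x_{g,p} + 1)/(\bar{x}_g + 1)\big)\);
  the pseudocount of 1 guards zeros and is negligible at the typical
  normalized magnitudes of 10²–10³.

For a CNV, the genes overlapping its span by ≥ 1 bp (configurable to
fully-contained) form the in-CNV set; the **CNV statistic** is the mean of
each per-gene statistic over the blood-expressed in-CNV genes. Three
context summaries accompany it: the same mean over *all* expressed genes
on the CNV's chromosome (background; expected near 0 because per-gene
cohort z-scores average out), and over three independently drawn random
sets of expressed out-CNV genes on that chromosome, each the same size as
the expressed in-CNV set. Random sets are drawn without replacement from
expressed genes only — unexpressed genes would deflate the control means —
and exclude in-CNV genes. A duplication is **direction-consistent** when
both its z-score and fold change exceed the maxima of all control sets; a
deletion when both fall below the minima. A CNV whose genes are all
blood-silent is `not_expressed` and carries no statistics: this is a real
outcome (the bundled cohort contains a 2p16.3/NRXN1 deletion with exactly
this behaviour) and a stated limitation of blood-based validation.

Why these definitions? The exact formulas behind the published validation
tables are not stated anywhere, so they are fixed here by two
observations: per-gene cohort standardization averaged over many genes
makes the chromosome background hover near 0, which is what the published
background values do (0.04, 0.095, −0.06, …), whereas a within-sample
standardization would not; and including the index patient in the cohort
mean follows the published table footnote ("all 354 patients"), with
exclusion exposed as a flag (`include_patient = FALSE`). Consequently the
published per-CNV numbers are **not** bit-reproducible — the package
checks direction consistency on those rows instead, and parameter
recovery on simulated cohorts.

For a truncating SNV the check is simpler: the mutant gene's level in the
patient against the cohort mean (patient included), `reduced` being a
strict inequality — partial nonsense-mediated decay predicts a modest
reduction, not silence.

## qPCR confirmation (qBase)

Candidate CNVs are confirmed by efficiency-corrected relative
quantification: each (sample, assay) Cq triple is averaged (when ≥ 3
replicates span more than 0.5 cycles, the value farthest from the median
is dropped first — a plate-QC convention, not a published rule), then

\[ RQ = E^{\,Cq_{\text{calibrator}} - Cq_{\text{sample}}}, \qquad
   NRQ = RQ_{\text{target}} / RQ_{\text{reference}} \]

with one reference gene (GAPDH in the motivating design) and one
calibrator (normal control) sample whose NRQ is therefore exactly 1 — the
"normal control set to a value of 1" convention. Copy-number calls use
midpoints between the diploid expectation 1 and heterozygous expectations
0.5/1.5: deletion at NRQ ≤ 0.75, duplication at ≥ 1.25. Efficiency
defaults to perfect doubling (E = 2) when a plate omits it.

## The synthetic cohort generator

Patient-level data behind this class of study is controlled-access, so
every pipeline input is generated with the statistical structure the
analysis assumes:

- **Genome**: non-overlapping gene spans (2–20 kb, gaps 1–30 kb) per
  chromosome.
- **Cohort**: 354 trios by default, proband sex drawn to a 279:75
  male:female composition.
- **Expression**: per-gene lognormal baseline (meanlog 6, sdlog 1, giving
  normalized magnitudes of 10²–10³), multiplicative lognormal noise with
  sd 0.2 on the log2 scale, and ~40% of genes blood-expressed (the
  observed in-CNV expressed fractions in the motivating cohort cluster
  around 0.4); blood-silent genes are zero for everyone. Carrier probands
  have their expressed in-CNV genes multiplied by the copy ratio (1.5 /
  0.5 for heterozygous duplication/deletion) and their PTV gene by an
  expression ratio of 0.6 (partial nonsense-mediated decay — consistent
  with the modest reductions blood data shows, not a published
  parameter). Counts are rounded to integers for the raw matrix;
  `round_counts = FALSE` supports exact noise-free checks.
- **Variants**: trio genotypes consistent with each planted origin; CNV
  calls for the proband and, for inherited CNVs, the carrier parent.
- **qPCR plates**: test-sample Cq values offset by \(-\log_E r\) from a
  noise-free calibrator anchor, plus Gaussian well noise on the test
  sample's wells. Keeping the calibrator noise-free follows the
  generating model this module is specified against; it also means plate
  noise enters through two well groups rather than four, which is what
  makes ≥ 95% call recovery at Cq noise sd 0.15 attainable.
- **Read pairs**: plants exact counts of N-rich (> 3 N), low-quality
  (> 20% of bases under Phred 5) and adapter-flagged pairs, plus optional
  boundary pairs sitting exactly at both thresholds (which must be kept:
  the QC inequalities are strict).

Every draw happens inside a seed-scoped RNG (Mersenne-Twister), so the
same seed reproduces every file byte-for-byte; the test suite asserts
this end to end. What the generator does **not** emulate: count
overdispersion beyond lognormal noise, sex chromosomes and X-linkage,
mosaicism, batch effects, correlated co-expression, or read-level
sequences. Passing tests therefore demonstrate the statistical machinery,
not robustness to every artefact of real RNA-seq.

## Numerical choices and degenerate inputs

- Strict inequalities in the read QC filter ("more than three N", "more
  than 20%"); boundary reads pass. Removal is the union of the three
  rules; the report attributes each removal to the first tripped rule in
  the order N → low-quality → adapter (the rules are unordered in the
  motivating description; the precedence affects reporting only).
- Population sd with \(z = 0\) at \(\sigma = 0\); pseudocount 1 in the
  fold change; both fixed so exact tests are possible.
- `percent()` rounds half-up at one decimal (10/354 → 2.8, 15/354 → 4.2).
  Note 19/354 = 5.3694…% rounds to 5.4 under any standard rule; the
  package reports 5.4.
- Degenerate dosage inputs error with guidance (control pool smaller than
  the in-CNV set) or degrade to typed outcomes (`not_expressed`,
  `ambiguous`) rather than NA-silence.

## Problem sizes in the test suite

The suite validates parameter recovery on 100 simulated cohorts per CNV
direction (100 trios, 200 genes on one chromosome, one carrier of a
10-gene CNV at ratio 1.5 or 0.5, log2 noise sd 0.2), 200 simulated qPCR
plates per truth class at Cq noise sd 0.15, and exhaustive enumeration
oracles for trio-origin classification (all 4³ genotype triples) and the
dosage statistic (a 5-gene chromosome with all \(\binom{3}{2}\) control
subsets enumerated). These sizes give stable pass/fail behaviour at
conventional power while keeping a full run under half a minute.

## Known limitations

- Blood expression is a proxy tissue: genes silent in blood (a material
  fraction of ASD genes) cannot be validated, only flagged.
- The triage gene list and region catalog are user-supplied inputs; the
  bundled versions transcribe one cohort's diagnosed findings and are a
  demonstration, not a clinical knowledge base.
- The simplified PTV + known-region filter stands in for full ACMG
  classification, which is upstream expert work.
- Single-reference qPCR normalization; the multi-reference geometric-mean
  extension is not implemented.
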