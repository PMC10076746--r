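# triodx

Post-variant-calling diagnostic triage and validation for autism spectrum
disorder (ASD) trio cohorts, for clinical-genomics analysts who already have
trio small-variant calls, CNV calls and peripheral-blood RNA-seq
quantifications and need the last mile: which probands have a reportable
finding, does the transcriptome support it, and what is the cohort yield.

## What it computes

**Triage.** A proband is SNV-positive iff it carries a *de novo*
protein-truncating variant (nonsense, frameshift, or canonical ±1/±2
splice site) in a listed ASD gene; inheritance is classified from the trio
genotype triple. A CNV is diagnostic when it passes the 100 kb calling
resolution and either matches a catalog of known syndromic regions at
≥ 50% reciprocal overlap (any inheritance origin) or deletes a
haploinsufficiency-flagged gene.

**RNA-seq dosage validation.** On a median-of-ratios-normalized
genes × samples matrix, each gene's carrier expression is standardized
against the cohort,

    z_g = (x_gp − mean_g) / sd_g        (population sd, all samples)
    lfc_g = log2((x_gp + 1) / (mean_g + 1))

and averaged over the blood-expressed in-CNV genes. The CNV-set mean is
compared with the whole-chromosome background and with three equal-sized
random sets of expressed out-CNV genes on the same chromosome: a
duplication should exceed all control maxima, a deletion fall below all
minima (`direction_consistent()`). Truncating-variant genes are checked
for reduced expression against the cohort mean.

**qPCR confirmation.** qBase-style efficiency-corrected relative
quantification of triplicate Cq plates:

    RQ = E^(Cq_calibrator − Cq_sample),   NRQ = RQ_target / RQ_reference

with the calibrator (normal control) fixed at NRQ = 1 and midpoint call
thresholds (deletion ≤ 0.75, duplication ≥ 1.25).

**Reporting.** Diagnostic yields (half-up percentages), CNV breakdowns by
type and origin, proband sex ratio, and a comorbidity keyword tally.

**Synthetic cohorts.** `sim_config()` / `generate_cohort()` generate every
input — pedigree, trio VCF, CNV calls, expression matrix, qPCR plates,
paired FASTQ with planted QC violations — with known ground truth, so the
whole pipeline runs and is tested without access to patient data.

## Worked example

The package bundles a demonstration cohort transcribing the diagnosed
findings of a published 354-child ASD trio study:

```r
library(triodx)
d <- demo_cohort()
findings <- triage(d$snvs, d$cnvs, d$ped, d$genes_of_interest, d$catalog)
summarize_cohort(findings, d$sex)
#> Cohort: 354 probands (279 male / 75 female, ratio 3.72 : 1)
#> SNV-positive: 10 (2.8%)
#> CNV-positive: 9 (2.5%)  [6 dup / 3 del; 5 de novo / 4 inherited]
#> Total positive: 19 (5.4%); de novo positive: 15 (4.2%)
```

Ten probands carry de novo truncating SNVs (2.8% of the cohort), nine carry
known-region CNVs (2.5%), and the fifteen whose findings are all de novo
give the 4.2% de novo yield.

Dosage validation of a simulated duplication carrier:

```r
cfg <- sim_config(seed = 42, n_trios = 100, n_chromosomes = 1,
                  genes_per_chromosome = 200,
                  cnvs = list(plant_cnv(carrier = 1, chrom = 1,
                                        first_gene = 50, n_genes = 10,
                                        copy_ratio = 1.5)))
co <- generate_cohort(cfg)
m  <- normalize_counts(co$expression)
r  <- cnv_dosage_validation(m, co$cnvs[1, ], co$genes, seed = 42)
#> in-CNV genes 10, expressed 4
#> zscore_cnv 3.753 vs random {-0.365, 0.365, -0.835}
#> log2fc_cnv 0.610 vs random {-0.081, 0.058, -0.188}
direction_consistent(r)
#> TRUE
```

The carrier's four blood-expressed in-CNV genes average a z-score of 3.75
and a log2 fold change of 0.61 (≈ log2(1.5)), clear of every random
control set — the expression footprint a heterozygous duplication
predicts. A qPCR plate for a deletion carrier:

```r
quantify_plate(generate_qpcr_plate(ratio = 0.5, efficiency = 2,
                                   noise_sd = 0.1, seed = 7))
#>   sample_id target_gene  delta_cq       nrq     call
#> 1      CTRL        CNV1  0.000000 1.0000000   normal
#> 2        S1        CNV1 -1.013206 0.4694746 deletion
```

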