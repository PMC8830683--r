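# sipscape

Super-interactive promoter (SIP) analysis for promoter-capture Hi-C
interactomes, in R (Bioconductor-style S4 on top of GenomicRanges).

## The problem

Capture Hi-C assigns each promoter bait a set of significantly
interacting fragments (promoter-interacting regions, PIRs), each with a
per-cell-type significance score (CHiCAGO score, or −log10 q-value for
HiChIP/Hi-C). In hematopoietic cell types a small minority of promoters
(~7.5%) concentrates an outsized share of the significant interactome —
driven by *many* interactions rather than stronger ones. These
super-interactive promoters mark lineage genes, and their PIRs are
enriched for open chromatin and trait-associated GWAS variants, which
makes them useful for connecting noncoding variants to target genes.

`sipscape` is for regulatory genomicists who have an interaction score
matrix (e.g. the Javierre-style "peak matrix" TSV) plus the usual
companions (ATAC peaks as BED, GWAS variant tables, expression tables)
and want the full SIP workup: calling, sharing/specificity, PIR
profiling, annotation enrichment, subnetworks, expression analysis — and
a seeded synthetic-data generator so all of it is testable offline.

## The statistic

For bait *b* in cell type *c*, the cumulative interaction score is

```
S(b,c) = Σ { score(i,c) : i ∈ interactions(b), score(i,c) ≥ t, cis, |dist| ≤ D }
```

with *t* = 5 (CHiCAGO) or 2 (−log10 q at FDR 0.01) and *D* = 2 Mb;
bait-to-bait interactions credit both baits. Scores are ranked ascending
and the SIP cutoff is the ROSE-style tangent point: with the axes scaled
to the unit square, the rank where a slope-1 line is tangent to the
curve — computed as the minimizer of `y_r − r·(max−min)/n`, verified in
the tests against an exhaustive search. Baits strictly above the cutoff
score are SIPs. Downstream: promoter degree per PIR (≥ 4 distinct
promoter fragments = super PIR), per-bait PIR scores, ≥ 1 bp overlap
annotation, the bait-length-adjusted logistic enrichment model
`outcome ~ SIP-status + bait-length`, SIP subnetworks (≥ 2 PIRs, each
with an independent trait SNP and an ATAC peak), and expression quintile
fold enrichment with a one-sided Cochran–Armitage trend test.

## Worked example

```r
library(sipscape)

cfg <- sipSimConfig(seed = 42)          # study-like defaults, 2000 baits
sim <- simulateInteractome(cfg)         # planted SIP structure + truth
res <- runSipPipeline(sim$interactome)  # score -> cutoff -> call -> classify

res$sipCounts
#>    Ery MacMon     MK   nCD4    Neu
#>    195    214    214    214    205
round(res$sipFractions, 3)
#>    Ery MacMon     MK   nCD4    Neu
#>  0.098  0.107  0.107  0.107  0.102
res$sharedCount
#> [1] 22
res$calls$Ery
#> SipCall [Ery]: 2000 baits, cutoff 119.659 at rank 1805, 195 SIPs (9.75%)
```

About 10% of baits clear the tangent cutoff in each cell type (7.5%
planted, plus the cutoff's grab of the strongest non-planted tail); 22
baits are SIPs in all five cell types. `sipLabels(res$calls$Ery)` feeds
the downstream steps: `pirPromoterDegree()`, `baitPeakOverlap()`,
`baitVariantOverlap()` + `logisticEnrichment()`, `buildSubnetworks()`,
`assignQuintiles()` + `foldEnrichment()`. For real data, point
`runSipPipeline()` at a peak-matrix TSV with
`mergeSpec = list(MacMon = c("Mon", "Mac0", "Mac1", "Mac2"))`, and export
PIR annotations for heritability partitioning with
`writeAnnotationBed()`.

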