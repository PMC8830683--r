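---
title: "Calling super-interactive promoters from capture Hi-C score matrices"
author: "sipscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling super-interactive promoters from capture Hi-C score matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipscape)
```

## The model

Promoter-capture Hi-C assigns every promoter-containing restriction
fragment ("bait") a set of interacting fragments ("other ends", or PIRs
once an interaction is significant), each with a per-cell-type
significance score — a CHiCAGO score for pcHi-C, or a −log10 q-value for
HiChIP and Hi-C inputs. A minority of promoters concentrates a
disproportionate share of the significant interactome. `sipscape`
identifies these **super-interactive promoters (SIPs)** and characterizes
what distinguishes them.

The per-bait statistic is the **cumulative interaction score**: the sum of
the scores of all significant interactions of that bait (score ≥ 5 for
CHiCAGO-style inputs; ≥ 2, i.e. FDR < 0.01, for −log10 q-value inputs),
over both bait-to-other-end and bait-to-bait records. A bait-to-bait
record credits both member baits. Only cis pairs within a maximum 1-D
distance (default 2 Mb, 1 Mb as a sensitivity setting) contribute; trans
pairs are kept at parse time but never scored. Baits with no significant
interaction stay in the ranking with a score of zero — they form the flat
left flank of the curve and therefore shape the cutoff.

## The tangent cutoff

Ranking cumulative scores in ascending order yields a hockey-stick curve.
Following the super-enhancer tradition, the SIP threshold is the point at
which a line of slope 1 — after rescaling both axes to the unit square —
is tangent to the curve. Operationally the slope is `s = (max − min)/n`,
every data point anchors a candidate line of slope `s`, and the cutoff is
the anchor whose line leaves the fewest points on or below it. Because the
ranked curve is convex, this is the anchor minimizing `z_r = y_r − s·r`,
which the implementation computes in a single vectorized pass; the test
suite checks it against an exhaustive search over all anchors. Ties break
toward the largest rank, and baits are pre-sorted by (score, bait id) so
results never depend on input order. A bait is a SIP iff its cumulative
score is **strictly above** the cutoff value.

Two degenerate shapes are flagged and yield zero SIPs: a flat curve (all
scores equal), and a curve that rises at least as fast as the global slope
from rank 1 onward (e.g. perfectly linear scores), where there is no elbow
for the tangent to grip. Without the second guard, a featureless curve
would label nearly every bait a SIP, which is the wrong answer to an
uninformative input.

Useful invariances, all under test: positive affine transforms of the
scores change neither the cutoff rank nor any label; permuting input rows
changes nothing; adding a significant interaction never lowers a bait's
score or rank; lowering the significance threshold never lowers a score.

## Cell types, sharing, genes

Monocytes and the three macrophage states are one biological group; their
score columns are averaged per record (`mergeCellTypes`) **before**
thresholding — averaging after thresholding would make the merged group's
significance depend on arbitrary source-column ordering, and a single
merged cell type must have a single significance decision.

Across cell types, a bait SIP in exactly one is **cell-type-specific**,
in all of them **shared**, otherwise intermediate. At the gene level, a
gene is a SIP gene in a cell type when any bait naming it is a SIP there.
The "cell-type-specific SIP gene" label is stricter and the wording in
the field is ambiguous between "captured by exactly one bait" and "every
capturing bait is a specific SIP". We default to the unique-capture
reading (`uniqueCaptureOnly = TRUE`) because multi-bait capture makes the
specificity of any single bait uninformative about the gene; the relaxed
all-captures-specific rule is available as an option.

## PIR profiles and annotation overlap

Per cell type, each other end's **promoter degree** is its number of
distinct significantly interacting bait fragments; degree ≥ 4 defines a
**super PIR** (in the blood atlas ~59% of PIRs touch one promoter and
only ~10% touch four or more, so 4 marks the upper tail). A bait's **PIR
score** is the maximum degree among its PIRs. Degree counts fragments,
not interaction rows, and bait-typed other ends count as promoter
partners symmetrically.

Overlap annotation is ≥ 1 bp interval intersection (GenomicRanges
machinery; the tests hold it to an all-pairs oracle). A GWAS variant
counts for a bait when its phenotype is *relevant* to the cell type
(red-cell traits for erythrocytes, PLT/MPV for megakaryocytes, and so on;
`defaultRelevanceMap()`) and its 1-based position falls inside one of the
bait's PIR fragments. Because longer baits accumulate PIRs and overlaps
mechanically, enrichment inference uses the logistic model

```
anyRelevantVariant ~ sipStatus + baitLength
```

with a Wald test and 95% CI on the SIP-status odds ratio. Under complete
or quasi-complete separation — routine in small simulations — the fit
falls back to Firth's penalized likelihood (a hand-rolled Newton
iteration with the hat-diagonal score adjustment), flagged in the output.
Size-matched sampling of non-SIPs is a descriptive alternative in the
literature; the regression is the primary inference here since it uses
all baits and states its adjustment explicitly.

**Subnetworks.** A SIP subnetwork is a SIP with ≥ 2 distinct PIR
fragments, each containing a statistically independent trait variant and
each overlapping a cell-type ATAC peak. The ≥ 2 requirement counts PIRs,
not SNPs. Variant and peak need only co-occupy the PIR, not coincide at a
base pair. A cell type without a peak set (neutrophils in the blood
atlas) drops the peak condition; an *empty* peak set supplied explicitly
is honored as "no overlap possible".

## Expression

Within a cell type, genes are ranked into five near-equal quintiles
(quintile 1 = highest; sizes differ by at most one, earlier bins take the
remainder; ties break on the gene symbol). Zero-expression genes are
retained by default — they are real observations that populate the low
quintiles — with a `dropZeros` switch. Fold enrichment of SIP genes is
each quintile's SIP-gene proportion over quintile 5's, tested by
chi-square across the five proportions plus a one-sided Cochran–Armitage
trend test with scores 1..5 (alternative: higher expression ⇒ more SIP
genes; the two-sided statistic is verified against
`stats::prop.trend.test`). For the enrichment universe, "SIP gene" uses
the inclusive any-bait mapping; the unique-capture restriction applies
only to the specificity label. Genes never captured by a bait are
excluded — their SIP status is undefined, not negative.

## The synthetic interactome

`sipSimConfig()` fixes the study conditions the generator emulates; they
are anchored to the blood-atlas structure and are not tuning knobs:

* **Geometry** — 3 chromosomes × 50 Mb, 2,000 baits + 8,000 other ends,
  mean fragment width 4 kb: desk-scale HindIII-like geometry.
* **Counts** — per bait and cell type, significant-interaction counts are
  negative binomial, mean 5, size 2 (median 4–7 like non-SIPs in the
  atlas). Planted SIPs (7.5% of baits; 15% of them shared across all cell
  types, echoing 170 shared of ~1,150) have mean ×10 with the NB size
  scaled by the same factor — the inflation is systematic, so the
  variance-to-mean ratio, not the coefficient of variation, is preserved
  — yielding medians around 40–60. Overdispersion is what produces a
  realistic elbow; Poisson counts would make the cutoff trivial.
* **Scores** — significant scores are 5 + Exponential, with medians tuned
  so per-bait median scores land near 8.4 (SIP) vs 6.4 (non-SIP): the
  count gap is large, the score gap deliberately small, because that
  asymmetry — many interactions rather than stronger ones — is the
  phenomenon itself.
* **Annotations** — peaks placed per fragment with probability 0.8 at
  planted-SIP PIRs vs 0.3 elsewhere; Poisson variant counts at rates
  0.5 vs 0.1; half the variants flagged independent; 30% given a motif
  list. **Expression** is log-normal with a +1 log-scale shift for SIP
  genes in the matching cell type only, which makes shared-SIP genes
  blood-elevated relative to other tissues for free.

Everything is deterministic given the seed, and null settings (multiplier
1, equal score medians, shift 0) drive every downstream test to its null
behavior — the calibration property the test suite checks.

What the generator does **not** emulate: distance-decay of contact
frequency, LD among variants, sequence content, bait-capture bias and
replicate structure. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted effects, not that the
atlas-scale catalogue would be reproduced bit-for-bit; the published
counts require the external peak matrix, which `runSipPipeline()` accepts
unchanged.

## Numerical choices and problem sizes

Fisher's exact test is two-sided by the minimum-likelihood convention
(the tail sum of all tables no more likely than the observed), which is
what reproduces published CRISPRi p-values; the suite pins it to an
independent hypergeometric tail-sum oracle. The two-proportion test is
the continuity-corrected pooled z. Wilcoxon comparisons enumerate exactly
up to 50 per group and use the tie-corrected normal approximation above.
Quintile and decile binning always gives earlier bins the remainder.

Test and acceptance runs use 2,000-bait interactomes (a few seconds each),
100 random vectors (n ≤ 500) for the cutoff oracle, and 100–200 replicates
of n = 5,000 for the logistic recovery checks — sizes at which every
stochastic assertion has comfortable margin while a full run of the suite
stays in the minutes range.

## A worked run

```{r example}
cfg <- sipSimConfig(seed = 42)
sim <- simulateInteractome(cfg)
res <- runSipPipeline(sim$interactome)
res$sipCounts
round(res$sipFractions, 3)
res$sharedCount
res$calls$Ery
```

## Known limitations

* The tangent cutoff is a geometric rule on a ranked curve; with very few
  baits (tens) its rank resolution is coarse and the SIP fraction
  unstable. The callers refuse n < 3 and flag degeneracy, but sensible
  use starts at hundreds of baits.
* Bait-level outcomes ("any PIR overlaps") saturate for high-degree
  baits; the bait-length adjustment absorbs only part of that, which is
  why per-PIR proportions are also reported.
* The Firth fallback reports Wald intervals from the penalized
  information; profile-likelihood intervals are not implemented.
* Chromosome-dialect harmonization covers the "chr" prefix only, not
  assembly liftover.
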