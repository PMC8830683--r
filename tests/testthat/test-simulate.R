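# Small, fast configuration used in most generator tests.
smallConfig <- function(seed = 1, ...) {
  sipSimConfig(seed = seed, nBaits = 150, nOtherEnds = 600,
               nChromosomes = 2, chromLength = 1.5e7,
               cellTypes = c("Ery", "MK"), ...)
}

test_that("the generator is deterministic and satisfies the container invariants", {
  s1 <- simulateInteractome(smallConfig())
  s2 <- simulateInteractome(smallConfig())
  expect_identical(interactions(s1$interactome), interactions(s2$interactome))
  expect_identical(as.data.frame(fragments(s1$interactome)),
                   as.data.frame(fragments(s2$interactome)))
  expect_identical(s1$truth$sipLabels, s2$truth$sipLabels)
  sDiff <- simulateInteractome(smallConfig(seed = 2))
  expect_false(identical(interactions(s1$interactome),
                         interactions(sDiff$interactome)))

  expect_true(validObject(s1$interactome))
  ints <- interactions(s1$interactome)
  expect_true(all(ints$baitID != ints$oeID))
  expect_true(all(abs(ints$distance) <= 2e6))
  # truth labels cover every generated bait
  expect_equal(nrow(s1$truth$sipLabels), 150L)
  expect_equal(sort(as.integer(rownames(s1$truth$sipLabels))),
               sort(S4Vectors::mcols(fragments(s1$interactome))$fragID[
                 S4Vectors::mcols(fragments(s1$interactome))$isBait]))
  # fragments laid out non-overlapping per chromosome
  frag <- fragments(s1$interactome)
  for (chr in unique(as.character(GenomicRanges::seqnames(frag)))) {
    f <- frag[GenomicRanges::seqnames(frag) == chr]
    f <- GenomicRanges::sort(f)
    expect_true(all(GenomicRanges::start(f)[-1] >
                    GenomicRanges::end(f)[-length(f)]))
  }
})

test_that("planted count and score structure matches the blood-atlas shape", {
  sim <- simulateInteractome(sipSimConfig(seed = 3))
  prof <- cumulativeScores(sim$interactome, "Ery")
  lab <- sim$truth$sipLabels[as.character(prof$baitID), "Ery"]
  medSip <- median(prof$nSignificant[lab])
  medNon <- median(prof$nSignificant[!lab])
  expect_gte(medSip / medNon, 5)            # count inflation dominates
  # per-interaction score medians differ only modestly
  msSip <- median(prof$medianScore[lab], na.rm = TRUE)
  msNon <- median(prof$medianScore[!lab], na.rm = TRUE)
  expect_gt(msSip, msNon)
  expect_lt(msSip / msNon, 2)
  expect_equal(msSip, 8.4, tolerance = 0.05)
  expect_equal(msNon, 6.4, tolerance = 0.05)
})

test_that("a null configuration plants no count signal", {
  reps <- 30
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- smallConfig(seed = 100 + i, sipCountMultiplier = 1,
                       scoreMedianSip = 1.4, scoreMedianNonSip = 1.4)
    sim <- simulateInteractome(cfg)
    prof <- cumulativeScores(sim$interactome, "Ery")
    lab <- sim$truth$sipLabels[as.character(prof$baitID), "Ery"]
    pvals[i] <- suppressWarnings(
      wilcox.test(prof$nSignificant[lab], prof$nSignificant[!lab]))$p.value
  }
  # two-sided rank-sum p-values behave uniformly under the null
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_gt(mean(pvals > 0.05), 0.8)
})

test_that("annotations concentrate peaks and variants at SIP PIRs", {
  sim <- simulateInteractome(smallConfig(seed = 5))
  ann <- simulateAnnotations(sim)
  expect_named(ann$peaks, c("Ery", "MK"))
  frag <- fragments(sim$interactome)
  inSip <- S4Vectors::mcols(frag)$fragID %in% sim$truth$sipPirs$Ery
  hasPeak <- GenomicRanges::countOverlaps(frag, ann$peaks$Ery) > 0
  expect_gt(mean(hasPeak[inSip]), mean(hasPeak[!inSip]))
  # peak probabilities zero: empty peak sets
  simNoPeak <- simulateInteractome(
    smallConfig(seed = 6, peakProbSipPir = 0, peakProbOther = 0))
  annNoPeak <- simulateAnnotations(simNoPeak)
  expect_true(all(lengths(annNoPeak$peaks) == 0))

  # variant table is valid against the reader's vocabulary
  expect_true(all(ann$variants$phenotype %in% bloodTraitVocabulary()))
  expect_true(all(ann$variants$position >= 1))
  # motif disruption probability is recovered at n >= 500 variants
  bigSim <- simulateInteractome(sipSimConfig(seed = 7))
  bigAnn <- simulateAnnotations(bigSim)
  expect_gte(nrow(bigAnn$motifs), 500)
  expect_equal(mean(nzchar(bigAnn$motifs$motifs)), 0.3, tolerance = 0.05)
})

test_that("expression generator elevates SIP genes; zero shift is null", {
  sim <- simulateInteractome(smallConfig(seed = 9))
  expr <- simulateExpression(sim)
  gm <- sim$truth$geneMap
  sipBaits <- rownames(sim$truth$sipLabels)[sim$truth$sipLabels[, "Ery"]]
  sipGenes <- unique(gm$gene[as.character(gm$baitID) %in% sipBaits])
  expect_gt(median(expr$Ery[expr$gene %in% sipGenes]),
            median(expr$Ery[!expr$gene %in% sipGenes]))
  # other tissues carry no shift: shared-SIP genes are blood-elevated
  expect_gt(median(expr$Ery[expr$gene %in% sipGenes]),
            median(expr$Liver[expr$gene %in% sipGenes]))

  simNull <- simulateInteractome(smallConfig(seed = 10, exprSipShift = 0))
  exprNull <- simulateExpression(simNull)
  q <- assignQuintiles(exprNull, "Ery")
  sipBaits0 <- rownames(simNull$truth$sipLabels)[simNull$truth$sipLabels[, "Ery"]]
  sipGenes0 <- unique(simNull$truth$geneMap$gene[
    as.character(simNull$truth$geneMap$baitID) %in% sipBaits0])
  fe <- suppressWarnings(foldEnrichment(q, sipGenes0))
  expect_true(all(is.na(fe$fold) | abs(fe$fold - 1) < 1.5))
})

test_that("written datasets read back to the in-memory objects", {
  sim <- simulateInteractome(smallConfig(seed = 12))
  ann <- simulateAnnotations(sim)
  expr <- simulateExpression(sim)
  dir <- withr::local_tempdir()
  writeDataset(sim, ann, expr, file.path(dir, "ds"))
  expect_error(writeDataset(sim, ann, expr, file.path(dir, "ds")),
               "not empty")
  writeDataset(sim, ann, expr, file.path(dir, "ds"), force = TRUE)

  back <- readPeakMatrix(file.path(dir, "ds", "peak_matrix.tsv"),
                         c("Ery", "MK"))
  orig <- sim$interactome
  expect_equal(interactions(back)[order(interactions(back)$baitID,
                                        interactions(back)$oeID), ],
               interactions(orig)[order(interactions(orig)$baitID,
                                        interactions(orig)$oeID), ],
               tolerance = 1e-8, ignore_attr = TRUE)
  # fragment map identical up to row order (only linked fragments written)
  fb <- as.data.frame(fragments(back))
  fo <- as.data.frame(fragments(orig))
  fo <- fo[fo$fragID %in% fb$fragID, ]
  expect_equal(fb[order(fb$fragID), c("seqnames", "start", "end", "isBait")],
               fo[order(fo$fragID), c("seqnames", "start", "end", "isBait")],
               ignore_attr = TRUE)

  exprBack <- readExpressionTable(file.path(dir, "ds", "expression.tsv"))
  expect_equal(exprBack$Ery, expr$Ery, tolerance = 1e-8)
  varBack <- readVariantTable(file.path(dir, "ds", "variants.tsv"))
  expect_equal(nrow(varBack), nrow(ann$variants))
  peaksBack <- readBed(file.path(dir, "ds", "peaks_Ery.bed"))
  expect_equal(length(peaksBack), length(ann$peaks$Ery))
  truth <- read.delim(file.path(dir, "ds", "truth.tsv"))
  expect_equal(nrow(truth), 150L)
})
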