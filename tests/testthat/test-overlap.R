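grFromDf <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

test_that("interval overlap uses half-open BED boundary semantics", {
  # BED [0,10) and [10,20) are adjacent, not overlapping
  a <- readBed(writeTempTsv("chr1\t0\t10"))
  b <- readBed(writeTempTsv("chr1\t10\t20"))
  expect_equal(nrow(intervalOverlap(a, b)), 0L)
  # BED [0,10) and [9,20) share exactly 1 bp
  c1 <- readBed(writeTempTsv("chr1\t9\t20"))
  ov <- intervalOverlap(a, c1)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlapBp, 1L)
})

test_that("overlap engine equals the all-pairs oracle on random sets", {
  set.seed(13)
  for (rep in 1:3) {
    nq <- sample(50:200, 1); ns <- sample(50:200, 1)
    q <- data.frame(chrom = sample(c("chr1", "chr2"), nq, TRUE),
                    start = sample(1:5000, nq, TRUE))
    q$end <- q$start + sample(1:300, nq, TRUE)
    s <- data.frame(chrom = sample(c("chr1", "chr2"), ns, TRUE),
                    start = sample(1:5000, ns, TRUE))
    s$end <- s$start + sample(1:300, ns, TRUE)
    got <- intervalOverlap(grFromDf(q), grFromDf(s))
    want <- oracleOverlapPairs(q, s)
    gotKey <- sort(paste(got$queryIdx, got$subjectIdx))
    wantKey <- sort(paste(want[, 1], want[, 2]))
    expect_equal(gotKey, wantKey)
  }
})

test_that("mixed chromosome dialects are harmonized with a warning", {
  a <- GenomicRanges::GRanges("1", IRanges::IRanges(5, 20))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 30))
  expect_warning(ov <- intervalOverlap(a, b), "dialect")
  expect_equal(nrow(ov), 1L)
})

test_that("bait peak overlap counts PIR hits and compares groups", {
  x <- makeToyInteractome()
  # no peaks: no bait overlaps in either group
  none <- baitPeakOverlap(x, "Ery", GenomicRanges::GRanges())
  expect_true(all(!none$anyOverlap))

  # peak over fragment 4 only
  peaks <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(15001, 15200))
  ov <- baitPeakOverlap(x, "Ery", peaks)
  expect_equal(ov$nPirsOverlapping[ov$baitID == 1], 1L)  # oe4 is bait 1's PIR
  expect_equal(ov$nPirsOverlapping[ov$baitID == 3], 1L)  # and bait 3's
  expect_equal(ov$nPirsOverlapping[ov$baitID == 2], 0L)
  expect_equal(ov$anyOverlap, c(TRUE, FALSE, TRUE))

  # brute-force recount of per-bait overlap over the toy links
  frag <- fragments(x)
  ints <- interactions(x)
  sig <- ints[!is.na(ints$distance) & ints$Ery >= 5, ]
  for (b in 1:3) {
    pirs <- unique(c(sig$oeID[sig$baitID == b],
                     sig$baitID[sig$oeID == b & b <= 3]))
    cnt <- 0L
    for (p in pirs) {
      f <- frag[S4Vectors::mcols(frag)$fragID == p]
      if (length(GenomicRanges::findOverlaps(f, peaks)) > 0) cnt <- cnt + 1L
    }
    expect_equal(ov$nPirsOverlapping[ov$baitID == b], cnt)
  }

  # adding peaks can only switch anyOverlap FALSE -> TRUE
  more <- c(peaks, GenomicRanges::GRanges("chrS1", IRanges::IRanges(20001, 20300)))
  ov2 <- baitPeakOverlap(x, "Ery", more)
  expect_true(all(ov2$anyOverlap >= ov$anyOverlap))

  # cell-type mismatch between labeled peaks and interactions is refused
  S4Vectors::metadata(peaks)$cellType <- "MK"
  expect_error(baitPeakOverlap(x, "Ery", peaks), "MK")
})

test_that("variant overlap honors the cell-type relevance filter", {
  x <- makeToyInteractome()
  # PLT variant inside fragment 7 (a PIR of bait 3 in MK, not in Ery)
  variants <- data.frame(chrom = "chrS1", position = 30100, rsid = "rs1",
                         phenotype = "PLT", pvalue = 1e-9,
                         independent = TRUE, source = "synthetic")
  mk <- baitVariantOverlap(x, "MK", variants)
  expect_true(mk$anyVariant[mk$baitID == 3])
  hits <- attr(mk, "hits")
  expect_equal(hits$rsid, "rs1")
  expect_equal(hits$oeID, 7)
  # same variant is irrelevant for erythrocytes
  ery <- baitVariantOverlap(x, "Ery", variants)
  expect_false(any(ery$anyVariant))
  # brute force: position-in-interval scan for the MK cell type
  frag <- fragments(x)
  f7 <- frag[S4Vectors::mcols(frag)$fragID == 7]
  expect_true(GenomicRanges::start(f7) <= 30100 &&
              GenomicRanges::end(f7) >= 30100)
})

test_that("logistic enrichment reduces to the 2x2 odds ratio at constant length", {
  set.seed(31)
  n <- 4000
  sip <- rbinom(n, 1, 0.3)
  p <- plogis(-1 + 0.9 * sip)
  y <- rbinom(n, 1, p)
  fit <- logisticEnrichment(y, sip, rep(5000, n))
  tab <- table(factor(sip, c(1, 0)), factor(y, c(1, 0)))
  or22 <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_equal(fit$coefficient, log(or22), tolerance = 1e-6)
  expect_equal(fit$method, "ml")
  expect_true(fit$ciLow <= fit$oddsRatio && fit$oddsRatio <= fit$ciHigh)
  expect_equal(fit$oddsRatio, exp(fit$coefficient))

  # complete separation triggers the penalized fallback, flagged
  ySep <- sip
  fitSep <- logisticEnrichment(ySep, sip, rep(5000, n))
  expect_equal(fitSep$method, "firth")
  expect_true(is.finite(fitSep$coefficient))
})

test_that("motif disruption rate is a deduplicated fraction", {
  hits <- data.frame(baitID = 1, oeID = 2,
                     rsid = sprintf("rs%d", c(1:10, 1)),  # one duplicate row
                     phenotype = "PLT", position = 1:11)
  motifs <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                       motifs = c("ESRRA;ESRRB;NR5A1;NR6A1", "GATA1", ""))
  res <- motifDisruptionRate(hits, motifs)
  expect_equal(res$nVariants, 10L)
  expect_equal(res$nDisrupting, 2L)
  expect_equal(res$fraction, 0.2)
  expect_equal(res$table$motifs[res$table$rsid == "rs1"],
               "ESRRA;ESRRB;NR5A1;NR6A1")
  # empty annotation: nothing disrupts
  res0 <- motifDisruptionRate(hits, motifs[0, ])
  expect_equal(res0$fraction, 0)
  # duplicate rows never change the rate
  res2 <- motifDisruptionRate(rbind(hits, hits), motifs)
  expect_equal(res2$fraction, res$fraction)
  expect_true(res$fraction >= 0 && res$fraction <= 1)
})

test_that("context features: boundary distance and gene density", {
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 5000), width = 50))
  bnd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(120, 9000), width = 10))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, 20000, by = 1000), width = 500))
  cf <- contextFeatures(iv, bnd, genes)
  expect_equal(cf$distanceToBoundary[1], 0)      # overlaps a boundary
  # brute-force nearest for the second interval
  gaps <- sapply(list(c(120, 129), c(9000, 9009)), function(bd) {
    if (bd[1] <= 5049 && bd[2] >= 5000) 0 else
      max(bd[1] - 5049, 5000 - bd[2])
  })
  expect_equal(cf$distanceToBoundary[2], min(gaps) - 1)
  expect_true(all(cf$geneDensity > 0))
  # chromosome without a boundary reports NA
  iv2 <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))
  cf2 <- contextFeatures(iv2, bnd, genes)
  expect_true(is.na(cf2$distanceToBoundary))
})
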