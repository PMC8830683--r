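test_that("cell-type merging averages source scores per record", {
  x <- makeToyInteractome()
  m <- mergeCellTypes(x, "EryMK", c("Ery", "MK"))
  ints <- interactions(m)
  expect_equal(ints$EryMK, (ints$Ery + ints$MK) / 2)
  expect_true("EryMK" %in% cellTypes(m))
  expect_true(all(c("Ery", "MK") %in% cellTypes(m)))  # sources retained
  expect_equal(mean(c(4, 4, 4, 4)), 4)
  expect_equal(mean(c(2, 4, 6, 8)), 5)
  expect_error(mergeCellTypes(x, "Z", c("Ery", "Mon")), "Mon")
  # merged column is usable downstream like a native cell type
  expect_s4_class(callSips(cumulativeScores(m, "EryMK"), "EryMK"), "SipCall")
})

test_that("cumulative scores sum significant cis records with bait-to-bait double entry", {
  x <- makeToyInteractome()
  prof <- cumulativeScores(x, "Ery", threshold = 5, maxDistance = 2e6)
  p <- function(id) prof[prof$baitID == id, ]
  # bait 1: 6 + 7 + 8 (bait-to-bait with bait 2); trans row excluded
  expect_equal(p(1)$cumScore, 21)
  expect_equal(p(1)$nSignificant, 3L)
  expect_equal(p(1)$medianScore, 7)
  # bait 2: own row 5 plus the bait-to-bait 8 credited to it too
  expect_equal(p(2)$cumScore, 13)
  # bait 3: 5.5 + 6.2 (row at 4.9 and row at 0.5 are sub-threshold)
  expect_equal(p(3)$cumScore, 11.7)

  # threshold boundary: scores strictly below never contribute
  y <- makeToyInteractome()
  ints <- interactions(y)
  ints$Ery <- ifelse(ints$Ery >= 5, 4.99, ints$Ery)
  y <- PromoterInteractome(fragments(y), ints, cellTypes(y))
  prof0 <- cumulativeScores(y, "Ery")
  expect_true(all(prof0$cumScore == 0))
  expect_true(all(prof0$nSignificant == 0L))
  expect_equal(nrow(prof0), 3L)            # zero-score baits retained

  # lowering the threshold never decreases any cumulative score
  lo <- cumulativeScores(x, "Ery", threshold = 3)
  expect_true(all(lo$cumScore >= prof$cumScore))

  # brute-force double-entry tally over the toy table
  ints <- interactions(x)
  isBait <- structure(S4Vectors::mcols(fragments(x))$isBait,
                      names = S4Vectors::mcols(fragments(x))$fragID)
  tally <- c(`1` = 0, `2` = 0, `3` = 0)
  for (i in seq_len(nrow(ints))) {
    if (is.na(ints$distance[i]) || ints$Ery[i] < 5) next
    tally[as.character(ints$baitID[i])] <-
      tally[as.character(ints$baitID[i])] + ints$Ery[i]
    if (isBait[as.character(ints$oeID[i])])
      tally[as.character(ints$oeID[i])] <-
        tally[as.character(ints$oeID[i])] + ints$Ery[i]
  }
  expect_equal(prof$cumScore, unname(tally[as.character(prof$baitID)]))
})

test_that("tangent cutoff matches the exhaustive oracle and handles degeneracy", {
  # flat curve: degenerate, no bait above the cutoff
  flat <- findCutoff(rep(7, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$cutoffValue, 7)

  # perfectly linear curve: no elbow, top rank, zero SIPs
  lin <- findCutoff(as.numeric(1:100))
  expect_true(lin$degenerate)
  expect_equal(lin$cutoffRank, 100L)

  # cubic curve: agrees exactly with the exhaustive O(n^2) search
  y <- as.numeric((1:100)^3)
  expect_equal(findCutoff(y)$cutoffRank, oracleCutoff(y)$cutoffRank)

  expect_error(findCutoff(c(1, 2)), "at least 3")

  # random curves of varied shape, n <= 500
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:500, 1)
    y <- sort(sample(c(
      rexp(n, 1 / 10),
      rlnorm(n, 1, 2),
      c(rep(0, n %/% 2), rexp(n - n %/% 2, 1 / 50)))[seq_len(n)]))
    got <- findCutoff(y)
    want <- oracleCutoff(y)
    expect_equal(got$cutoffRank, want$cutoffRank)
    expect_equal(got$degenerate, want$degenerate)
  }
})

test_that("SIP labels are strict, affine-invariant and order-invariant", {
  set.seed(11)
  n <- 300
  cum <- c(rexp(n * 0.92, 1 / 20), 500 + rexp(n * 0.08, 1 / 100))
  prof <- data.frame(baitID = seq_along(cum), cumScore = cum,
                     nSignificant = 1L, medianScore = 1)
  call <- callSips(prof, "Ery")
  tab <- sipTable(call)
  expect_true(all(tab$cumScore[tab$sip] > call@cutoffValue))
  expect_true(call@sipFraction > 0 && call@sipFraction < 1)

  # positive affine transform of every score leaves rank and labels alone
  prof2 <- prof
  prof2$cumScore <- 3.7 * prof2$cumScore + 11
  call2 <- callSips(prof2, "Ery")
  expect_equal(call2@cutoffRank, call@cutoffRank)
  expect_equal(sipLabels(call2), sipLabels(call))

  # permuting the input rows changes nothing
  perm <- sample(nrow(prof))
  call3 <- callSips(prof[perm, ], "Ery")
  expect_equal(sipLabels(call3)[names(sipLabels(call))], sipLabels(call))

  # all-equal scores: zero SIPs
  flatProf <- data.frame(baitID = 1:5, cumScore = 2)
  expect_equal(sum(sipTable(callSips(flatProf))$sip), 0L)
})

test_that("specific/shared classification matches set algebra", {
  mkCall <- function(ids, sip, ct) {
    prof <- data.frame(baitID = ids, cumScore = ifelse(sip, 100, 1))
    cl <- callSips(prof, ct)
    cl
  }
  set.seed(5)
  ids <- 1:1000
  cts <- c("Ery", "MacMon", "MK", "nCD4", "Neu")
  labs <- sapply(cts, function(ct) runif(1000) < 0.1)
  calls <- lapply(cts, function(ct) {
    prof <- data.frame(baitID = ids, cumScore = ifelse(labs[, ct], 100, 1))
    callSips(prof, ct)
  })
  names(calls) <- cts
  cls <- classifySips(calls)
  # the synthetic flat/high construction makes call labels equal planted labs
  expect_equal(unname(sapply(cts, function(ct) sum(cls[[paste0("SIP.", ct)]]))),
               unname(colSums(labs)))
  # brute-force category per bait
  for (i in sample(1000, 50)) {
    v <- labs[i, ]
    want <- if (sum(v) == 0) "never" else if (sum(v) == 5) "shared_all"
      else if (sum(v) == 1) paste0("specific:", cts[which(v)])
      else "intermediate"
    expect_equal(cls$category[cls$baitID == ids[i]], want)
  }
  cnt <- attr(cls, "counts")
  expect_equal(sum(cnt), 1000)

  calls2 <- calls
  calls2[[1]] <- mkCall(2:1001, rep(FALSE, 1000), "Ery")
  expect_error(classifySips(calls2), "universe")
})

test_that("gene-level SIP flags follow the capture rules", {
  # 4 baits x 6 genes; bait 1 is MK-specific SIP, bait 2 shared, bait 3
  # never, bait 4 intermediate (MK+Ery)
  frag <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 5000, length.out = 4), width = 4000))
  S4Vectors::mcols(frag)$fragID <- 1:4
  S4Vectors::mcols(frag)$fragNames <- IRanges::CharacterList(
    c("g1", "g2"), c("g3"), c("g2", "g4"), c("g5", "g6"))
  S4Vectors::mcols(frag)$isBait <- rep(TRUE, 4)
  cts <- c("Ery", "MK")
  labs <- cbind(Ery = c(FALSE, TRUE, FALSE, TRUE),
                MK = c(TRUE, TRUE, FALSE, TRUE))
  calls <- lapply(cts, function(ct) plantedCall(1:4, labs[, ct], ct))
  names(calls) <- cts
  cls <- classifySips(calls)
  flags <- mapSipGenes(cls, frag)
  g <- function(gene, ct) flags[flags$gene == gene & flags$cellType == ct, ]

  # g1 on the single MK-specific bait: MK-specific SIP gene
  expect_true(g("g1", "MK")$sipGene)
  expect_true(g("g1", "MK")$specificSipGene)
  # g2 on bait 1 (specific SIP) and bait 3 (never): excluded by capture rule
  expect_true(g("g2", "MK")$sipGene)
  expect_false(g("g2", "MK")$specificSipGene)
  # shared flag follows the shared_all bait
  expect_true(all(flags$sharedSipGene[flags$gene == "g3"]))
  expect_false(any(flags$sharedSipGene[flags$gene == "g1"]))
  # g5/g6 on the intermediate bait: SIP genes in both, specific in none
  expect_true(g("g5", "Ery")$sipGene)
  expect_false(g("g5", "Ery")$specificSipGene)

  # brute-force check of every flag under the unique-capture rule
  geneBaits <- list(g1 = 1, g2 = c(1, 3), g3 = 2, g4 = 3, g5 = 4, g6 = 4)
  for (gene in names(geneBaits)) for (ct in cts) {
    baits <- geneBaits[[gene]]
    wantSip <- any(labs[baits, ct])
    specHere <- cls$category[match(baits, cls$baitID)] == paste0("specific:", ct)
    wantSpec <- length(baits) == 1 && all(specHere)
    expect_equal(g(gene, ct)$sipGene, wantSip)
    expect_equal(g(gene, ct)$specificSipGene, wantSpec)
  }

  # relaxed rule: every capturing bait specific (still excludes g2)
  flagsRelax <- mapSipGenes(cls, frag, uniqueCaptureOnly = FALSE)
  expect_false(flagsRelax[flagsRelax$gene == "g2" &
                          flagsRelax$cellType == "MK", ]$specificSipGene)
})
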