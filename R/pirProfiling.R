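#' Promoter degree of each promoter-interacting region
#'
#' For one cell type, counts for every other end (PIR) the number of
#' distinct promoter (bait) fragments it significantly interacts with, and
#' flags super PIRs — PIRs contacting at least \code{superThreshold}
#' (default 4) distinct promoter fragments.  When the other end of a record
#' is itself a bait, the record also counts the other end as a promoter
#' partner of the bait side (promoter-promoter contacts are symmetric).
#'
#' @inheritParams cumulativeScores
#' @param superThreshold minimum promoter degree of a super PIR.
#' @return data.frame with \code{oeID}, \code{degree}, \code{superPir};
#'   attribute \code{"superThreshold"}.
#' @export
pirPromoterDegree <- function(x, cellType, threshold = 5, maxDistance = 2e6,
                              superThreshold = 4) {
  sig <- significantRecords(x, cellType, threshold, maxDistance)
  frag <- fragments(x)
  isBait <- structure(mcols(frag)$isBait,
                      names = as.character(mcols(frag)$fragID))
  ## incidence pairs (region, promoter partner)
  oeBait <- isBait[as.character(sig$oeID)]
  region <- c(sig$oeID, sig$baitID[oeBait])
  partner <- c(sig$baitID, sig$oeID[oeBait])
  if (!length(region)) {
    out <- data.frame(oeID = integer(), degree = integer(),
                      superPir = logical())
    attr(out, "superThreshold") <- superThreshold
    return(out)
  }
  key <- !duplicated(cbind(region, partner))
  region <- region[key]; partner <- partner[key]
  deg <- table(region)
  out <- data.frame(oeID = as.integer(names(deg)),
                    degree = as.integer(deg))
  out <- out[order(out$oeID), , drop = FALSE]
  rownames(out) <- NULL
  out$superPir <- out$degree >= superThreshold
  attr(out, "superThreshold") <- superThreshold
  out
}

#' Per-bait PIR summaries: PIR count, PIR score, super-PIR contact
#'
#' For every bait: the number of distinct significant PIRs, the PIR score
#' (the maximum promoter degree among the bait's PIRs) and whether any of
#' its PIRs is a super PIR.  When SIP labels are supplied, SIP vs non-SIP
#' group proportions of super-PIR contact are attached as attribute
#' \code{"groupStats"}.
#'
#' @inheritParams pirPromoterDegree
#' @param degreeMap data.frame from \code{\link{pirPromoterDegree}} for the
#'   same cell type and thresholds.
#' @param sipCall optional \code{\linkS4class{SipCall}} for the same cell
#'   type.
#' @return data.frame with \code{baitID}, \code{nPirs}, \code{pirScore}
#'   (0 when the bait has no significant PIR), \code{hasSuperPir} and,
#'   when labels are given, \code{sip}.
#' @export
baitPirSummary <- function(x, cellType, degreeMap, sipCall = NULL,
                           threshold = 5, maxDistance = 2e6) {
  sig <- significantRecords(x, cellType, threshold, maxDistance)
  frag <- fragments(x)
  isBait <- structure(mcols(frag)$isBait,
                      names = as.character(mcols(frag)$fragID))
  superThreshold <- attr(degreeMap, "superThreshold")
  if (is.null(superThreshold)) superThreshold <- 4
  ## partner sets: each record links bait -> oe; bait-typed other ends also
  ## act as promoters whose partner (the bait side) is one of their PIRs
  oeBait <- isBait[as.character(sig$oeID)]
  bait <- c(sig$baitID, sig$oeID[oeBait])
  pir <- c(sig$oeID, sig$baitID[oeBait])
  keep <- !duplicated(cbind(bait, pir))
  bait <- bait[keep]; pir <- pir[keep]
  deg <- structure(degreeMap$degree, names = as.character(degreeMap$oeID))

  allBaits <- sort(mcols(frag)$fragID[mcols(frag)$isBait])
  out <- data.frame(baitID = allBaits, nPirs = 0L, pirScore = 0L,
                    hasSuperPir = FALSE)
  if (length(bait)) {
    grp <- factor(as.character(bait), levels = as.character(allBaits))
    n <- tapply(pir, grp, length)
    pd <- deg[as.character(pir)]
    pd[is.na(pd)] <- 1L   # a partner absent from the map has at least this bait
    mx <- tapply(pd, grp, max)
    hit <- !is.na(n)
    out$nPirs[hit] <- as.integer(n[hit])
    out$pirScore[hit] <- as.integer(mx[hit])
    out$hasSuperPir <- out$pirScore >= superThreshold
  }
  if (!is.null(sipCall)) {
    lab <- sipLabels(sipCall)
    out$sip <- as.logical(lab[as.character(out$baitID)])
    grpStats <- vapply(c(`TRUE` = TRUE, `FALSE` = FALSE), function(s) {
      sel <- out$sip %in% s
      c(n = sum(sel), propSuperPir = mean(out$hasSuperPir[sel]),
        medianNPirs = stats::median(out$nPirs[sel]),
        medianPirScore = stats::median(as.numeric(out$pirScore[sel])))
    }, numeric(4))
    attr(out, "groupStats") <- t(grpStats)
  }
  out
}

#' Two-group comparison with a named effect size
#'
#' Two-sided comparison of two samples: Wilcoxon rank-sum (effect = ratio
#' of medians), Welch t-test (effect = difference of means), or a
#' two-proportion chi-square for (successes, totals) pairs (effect = ratio
#' of proportions).
#'
#' @param a,b numeric samples, or for \code{kind = "chi2_prop"} length-2
#'   vectors \code{c(successes, total)}.
#' @param kind one of \code{"wilcoxon"}, \code{"t"}, \code{"chi2_prop"}.
#' @param exact for Wilcoxon: force exact enumeration (default exact below
#'   51 per group, normal approximation with tie correction above).
#' @return one-row data.frame: \code{test}, \code{pValue}, \code{effect},
#'   \code{effectName}, \code{nA}, \code{nB}.
#' @export
compareGroups <- function(a, b, kind = c("wilcoxon", "t", "chi2_prop"),
                          exact = NULL) {
  kind <- match.arg(kind)
  if (kind == "chi2_prop") {
    stopifnot(length(a) == 2, length(b) == 2)
    ht <- suppressWarnings(
      stats::prop.test(c(a[1], b[1]), c(a[2], b[2]), correct = TRUE))
    return(data.frame(test = "two-proportion chi-square (continuity-corrected)",
                      pValue = ht$p.value,
                      effect = (a[1] / a[2]) / (b[1] / b[2]),
                      effectName = "proportion ratio",
                      nA = a[2], nB = b[2]))
  }
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  if (kind == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("zero-variance input for t-test; use kind = 'wilcoxon'",
           call. = FALSE)
    ht <- stats::t.test(a, b)
    return(data.frame(test = "Welch t", pValue = ht$p.value,
                      effect = mean(a) - mean(b),
                      effectName = "mean difference",
                      nA = length(a), nB = length(b)))
  }
  if (is.null(exact)) exact <- max(length(a), length(b)) <= 50
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  medB <- stats::median(b)
  data.frame(test = "Wilcoxon rank-sum", pValue = ht$p.value,
             effect = if (medB == 0) NA_real_ else stats::median(a) / medB,
             effectName = "median ratio",
             nA = length(a), nB = length(b))
}

#' Contingency tests on a 2x2 table
#'
#' Runs Fisher's exact test (two-sided, minimum-likelihood convention: the
#' p-value sums the probabilities of all tables no more likely than the
#' observed one) and the continuity-corrected two-proportion chi-square
#' test on the table
#' \preformatted{   a  b
#'    c  d}
#' where rows are groups and columns success/failure.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return two-row data.frame: \code{test}, \code{pValue}, \code{effect}
#'   (conditional MLE odds ratio for Fisher; proportion ratio for the
#'   chi-square), \code{propA}, \code{propB}.
#' @examples
#' twoByTwoTests(4, 25, 3, 227)   # p_Fisher ~ 0.00355
#' @export
twoByTwoTests <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0)
    stop("all-zero 2x2 table: tests undefined", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  fish <- stats::fisher.test(m)
  propA <- a / (a + b)
  propB <- c / (c + d)
  ## chi-square approximation caveats at small counts are expected here;
  ## Fisher's exact row is the small-sample answer
  pt <- suppressWarnings(
    stats::prop.test(c(a, c), c(a + b, c + d), correct = TRUE))
  data.frame(
    test = c("Fisher exact (two-sided)",
             "two-proportion chi-square (continuity-corrected)"),
    pValue = c(fish$p.value, pt$p.value),
    effect = c(unname(fish$estimate),
               if (propB == 0) NA_real_ else propA / propB),
    propA = propA, propB = propB)
}
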