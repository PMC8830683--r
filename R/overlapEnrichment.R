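#' Overlapping interval pairs between two sets
#'
#' All (query, subject) index pairs sharing at least \code{minBp} base
#' pairs, computed with the GenomicRanges overlap engine.  Mixed chromosome
#' dialects ("chr1" vs "1") are harmonized with a warning.
#'
#' @param query,subject \code{GRanges}.
#' @param minBp minimum overlap in bp (default 1).
#' @return data.frame with \code{queryIdx}, \code{subjectIdx},
#'   \code{overlapBp}.
#' @export
intervalOverlap <- function(query, subject, minBp = 1) {
  query <- harmonizeChromDialect(query, subject)
  hits <- findOverlaps(query, subject, minoverlap = minBp)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(end(query)[q], end(subject)[s]) -
    pmax(start(query)[q], start(subject)[s]) + 1L
  data.frame(queryIdx = q, subjectIdx = s, overlapBp = ov)
}

## PIR fragments (GRanges) of each bait in one cell type: returns
## data.frame(baitID, oeID) of distinct significant bait->PIR links plus
## the fragment index for coordinates.
baitPirLinks <- function(x, cellType, threshold, maxDistance) {
  sig <- significantRecords(x, cellType, threshold, maxDistance)
  frag <- fragments(x)
  isBait <- structure(mcols(frag)$isBait,
                      names = as.character(mcols(frag)$fragID))
  oeBait <- isBait[as.character(sig$oeID)]
  bait <- c(sig$baitID, sig$oeID[oeBait])
  pir <- c(sig$oeID, sig$baitID[oeBait])
  keep <- !duplicated(cbind(bait, pir))
  data.frame(baitID = bait[keep], oeID = pir[keep])
}

#' Per-bait ATAC-peak overlap of PIRs
#'
#' For every bait, counts its significant PIRs and how many of them overlap
#' (at least \code{minBp} base pairs) an open-chromatin peak of the cell
#' type.  With SIP labels supplied, attaches SIP vs non-SIP comparisons:
#' the continuity-corrected two-proportion test on "any PIR overlapping"
#' and the Welch t-test on per-bait overlap counts, plus per-PIR overlap
#' proportions by group.
#'
#' @inheritParams cumulativeScores
#' @param peaks \code{GRanges} of peaks for the matching cell type (a
#'   \code{cellType} entry in \code{metadata(peaks)}, when present, must
#'   match).
#' @param sipCall optional \code{\linkS4class{SipCall}}.
#' @param minBp minimum overlap in bp.
#' @return data.frame with \code{baitID}, \code{nPirs},
#'   \code{nPirsOverlapping}, \code{anyOverlap} and (with labels)
#'   \code{sip}; group statistics as attribute \code{"groupStats"}.
#' @export
baitPeakOverlap <- function(x, cellType, peaks, sipCall = NULL,
                            threshold = 5, maxDistance = 2e6, minBp = 1) {
  peakCt <- metadata(peaks)$cellType
  if (!is.null(peakCt) && !identical(peakCt, cellType))
    stop("peak set is labeled '", peakCt, "' but interactions are '",
         cellType, "'", call. = FALSE)
  links <- baitPirLinks(x, cellType, threshold, maxDistance)
  frag <- fragmentIndex(x)
  allBaits <- sort(mcols(fragments(x))$fragID[mcols(fragments(x))$isBait])
  out <- data.frame(baitID = allBaits, nPirs = 0L, nPirsOverlapping = 0L)
  if (nrow(links)) {
    pirGr <- frag[as.character(links$oeID)]
    olap <- if (length(peaks))
      countOverlaps(harmonizeChromDialect(pirGr, peaks), peaks,
                    minoverlap = minBp) > 0
    else rep(FALSE, length(pirGr))
    grp <- factor(as.character(links$baitID), levels = as.character(allBaits))
    n <- tapply(rep(1L, nrow(links)), grp, sum)
    no <- tapply(as.integer(olap), grp, sum)
    hit <- !is.na(n)
    out$nPirs[hit] <- as.integer(n[hit])
    out$nPirsOverlapping[hit] <- as.integer(no[hit])
  }
  out$anyOverlap <- out$nPirsOverlapping >= 1L
  if (!is.null(sipCall)) {
    lab <- sipLabels(sipCall)
    out$sip <- as.logical(lab[as.character(out$baitID)])
    sipIdx <- which(out$sip); nonIdx <- which(!out$sip)
    stats <- list(
      anyOverlapProp = c(sip = mean(out$anyOverlap[sipIdx]),
                         nonSip = mean(out$anyOverlap[nonIdx])),
      propTest = compareGroups(c(sum(out$anyOverlap[sipIdx]), length(sipIdx)),
                               c(sum(out$anyOverlap[nonIdx]), length(nonIdx)),
                               kind = "chi2_prop"),
      perPirOverlapProp = c(
        sip = with(out[sipIdx, ], sum(nPirsOverlapping) / max(1, sum(nPirs))),
        nonSip = with(out[nonIdx, ], sum(nPirsOverlapping) / max(1, sum(nPirs))))
    )
    if (stats::sd(out$nPirsOverlapping[sipIdx]) > 0 ||
        stats::sd(out$nPirsOverlapping[nonIdx]) > 0)
      stats$countTest <- compareGroups(out$nPirsOverlapping[sipIdx],
                                       out$nPirsOverlapping[nonIdx],
                                       kind = "t")
    attr(out, "groupStats") <- stats
  }
  out
}

#' Per-bait overlap of PIRs with relevant GWAS variants
#'
#' A variant counts toward a bait when its phenotype is relevant to the
#' cell type and its (1-based) position falls inside one of the bait's PIR
#' fragments.
#'
#' @inheritParams baitPeakOverlap
#' @param variants data.frame as from \code{\link{readVariantTable}}.
#' @param relevance named list, cell type -> relevant phenotype labels.
#' @param independentOnly restrict to conditionally independent signals.
#' @return data.frame with \code{baitID}, \code{nPirs},
#'   \code{nPirsWithVariant}, \code{anyVariant}; the per-hit detail table
#'   (\code{baitID}, \code{oeID}, \code{rsid}, \code{phenotype},
#'   \code{position}) is attached as attribute \code{"hits"}.
#' @export
baitVariantOverlap <- function(x, cellType, variants,
                               relevance = defaultRelevanceMap(),
                               threshold = 5, maxDistance = 2e6,
                               independentOnly = FALSE) {
  rel <- relevance[[cellType]]
  if (is.null(rel))
    stop("no relevant phenotypes declared for cell type '", cellType, "'",
         call. = FALSE)
  v <- variants[variants$phenotype %in% rel, , drop = FALSE]
  if (independentOnly) v <- v[v$independent, , drop = FALSE]
  links <- baitPirLinks(x, cellType, threshold, maxDistance)
  frag <- fragmentIndex(x)
  allBaits <- sort(mcols(fragments(x))$fragID[mcols(fragments(x))$isBait])
  out <- data.frame(baitID = allBaits, nPirs = 0L, nPirsWithVariant = 0L)
  hitsTab <- data.frame(baitID = integer(), oeID = integer(),
                        rsid = character(), phenotype = character(),
                        position = numeric())
  if (nrow(links)) {
    pirGr <- frag[as.character(links$oeID)]
    pirHasVar <- rep(FALSE, nrow(links))
    if (nrow(v)) {
      varGr <- GRanges(v$chrom, IRanges(v$position, width = 1L))
      ov <- intervalOverlap(varGr, pirGr)
      if (nrow(ov)) {
        hitsTab <- data.frame(baitID = links$baitID[ov$subjectIdx],
                              oeID = links$oeID[ov$subjectIdx],
                              rsid = v$rsid[ov$queryIdx],
                              phenotype = v$phenotype[ov$queryIdx],
                              position = v$position[ov$queryIdx],
                              stringsAsFactors = FALSE)
        pirHasVar[unique(ov$subjectIdx)] <- TRUE
      }
    }
    grp <- factor(as.character(links$baitID), levels = as.character(allBaits))
    n <- tapply(rep(1L, nrow(links)), grp, sum)
    nv <- tapply(as.integer(pirHasVar), grp, sum)
    hit <- !is.na(n)
    out$nPirs[hit] <- as.integer(n[hit])
    out$nPirsWithVariant[hit] <- as.integer(nv[hit])
  }
  out$anyVariant <- out$nPirsWithVariant >= 1L
  attr(out, "hits") <- hitsTab
  out
}

#' Bait-length-adjusted logistic enrichment model
#'
#' Fits \code{outcome ~ sipStatus + baitLength} by maximum likelihood and
#' reports the Wald test and 95\% confidence interval for the SIP-status
#' odds ratio.  Under complete or quasi-complete separation the fit falls
#' back to Firth's penalized likelihood (flagged in the result).
#'
#' @param outcome logical/0-1 per-bait outcome (e.g. "has at least one PIR
#'   overlapping a relevant GWAS variant").
#' @param sipStatus logical/0-1 SIP indicator per bait.
#' @param baitLength bait length in bp (positive).
#' @return one-row data.frame: \code{coefficient} (log-odds for SIP
#'   status), \code{oddsRatio}, \code{ciLow}, \code{ciHigh}, \code{pValue},
#'   \code{method} ("ml" or "firth").
#' @export
logisticEnrichment <- function(outcome, sipStatus, baitLength) {
  outcome <- as.integer(outcome)
  sipStatus <- as.integer(sipStatus)
  stopifnot(length(outcome) == length(sipStatus),
            length(outcome) == length(baitLength))
  if (length(unique(outcome)) < 2)
    stop("outcome must have both classes present", call. = FALSE)
  if (any(baitLength <= 0)) stop("bait lengths must be positive", call. = FALSE)
  ## scale length to kb so the optimizer is well-conditioned
  df <- data.frame(y = outcome, sip = sipStatus, len = baitLength / 1000)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ sip + len, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  if (sep || (!is.na(co["sip", 1]) && abs(co["sip", 1]) > 15)) {
    ## drop rank-deficient columns (e.g. a constant length) before Firth
    X <- cbind(intercept = 1, sip = df$sip, len = df$len)
    qrX <- qr(X)
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    X <- X[, keep, drop = FALSE]
    sipCol <- which(colnames(X) == "sip")
    ff <- firthLogistic(X, df$y)
    est <- ff$beta[sipCol]; se <- ff$se[sipCol]
    method <- "firth"
  } else {
    est <- co["sip", 1]; se <- co["sip", 2]
    method <- "ml"
  }
  z <- est / se
  data.frame(coefficient = est,
             oddsRatio = exp(est),
             ciLow = exp(est - stats::qnorm(0.975) * se),
             ciHigh = exp(est + stats::qnorm(0.975) * se),
             pValue = 2 * stats::pnorm(-abs(z)),
             method = method)
}

## Firth-penalized logistic regression (Jeffreys-prior score adjustment):
## Newton iteration on U*(beta) = X'(y - p) + X' h (1/2 - p) where h are
## the hat-matrix diagonals of the weighted design.
firthLogistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    I <- crossprod(XW)
    Iinv <- solve(I)
    h <- rowSums((XW %*% Iinv) * XW)
    U <- drop(crossprod(X, (y - p) + h * (0.5 - p)))
    step <- drop(Iinv %*% U)
    ## dampen large steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(Iinv)), iterations = it)
}

#' Fraction of SIP-PIR variants disrupting transcription-factor motifs
#'
#' Among the GWAS variants falling in SIP PIRs, the fraction annotated with
#' at least one disrupted transcription-factor binding motif.  Variants are
#' deduplicated by rsid before the rate is computed.
#'
#' @param variantHits data.frame of variant-in-PIR hits (as produced in the
#'   \code{"hits"} attribute of \code{\link{baitVariantOverlap}}), expected
#'   to carry \code{rsid}.
#' @param motifAnnotations data.frame with \code{rsid} and \code{motifs}
#'   (";"-joined motif gene names; empty or missing = no disruption).
#' @return list with \code{fraction}, \code{nVariants},
#'   \code{nDisrupting} and the annotated \code{table} (adds a
#'   \code{motifs} column to the deduplicated hits).
#' @export
motifDisruptionRate <- function(variantHits, motifAnnotations) {
  hits <- variantHits[!duplicated(variantHits$rsid), , drop = FALSE]
  if (!nrow(hits))
    return(list(fraction = NA_real_, nVariants = 0L, nDisrupting = 0L,
                table = cbind(hits, motifs = character(0))))
  motifs <- if (nrow(motifAnnotations))
    motifAnnotations$motifs[match(hits$rsid, motifAnnotations$rsid)]
  else rep(NA_character_, nrow(hits))
  motifs[is.na(motifs)] <- ""
  disrupting <- nzchar(motifs)
  hits$motifs <- motifs
  list(fraction = mean(disrupting),
       nVariants = nrow(hits),
       nDisrupting = sum(disrupting),
       table = hits)
}

#' Genomic context of intervals: TAD-boundary distance and gene density
#'
#' For each interval: the bp gap to the nearest domain boundary (0 when
#' overlapping; NA when the chromosome has no boundary) and the local gene
#' density as genes per Mb within a flanking window around the interval
#' midpoint.
#'
#' @param intervals \code{GRanges} to annotate.
#' @param boundaries \code{GRanges} of TAD boundaries.
#' @param genes \code{GRanges} of gene intervals.
#' @param flank half-width of the gene-density window in bp (default 500 kb).
#' @return data.frame with \code{distanceToBoundary} and \code{geneDensity}
#'   (genes per Mb).
#' @export
contextFeatures <- function(intervals, boundaries, genes, flank = 5e5) {
  boundaries <- harmonizeChromDialect(boundaries, intervals)
  genes <- harmonizeChromDialect(genes, intervals)
  dist <- rep(NA_real_, length(intervals))
  if (length(boundaries)) {
    dtn <- suppressWarnings(distanceToNearest(intervals, boundaries))
    dist[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  }
  mid <- floor((start(intervals) + end(intervals)) / 2)
  win <- GRanges(seqnames(intervals),
                 IRanges(pmax(1, mid - flank), mid + flank))
  dens <- suppressWarnings(countOverlaps(win, genes)) / (width(win) / 1e6)
  data.frame(distanceToBoundary = dist, geneDensity = dens)
}
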