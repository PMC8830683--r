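#' Average score columns into a merged cell type
#'
#' Forms a merged cell-type score (for example grouping monocytes with the
#' three macrophage states into one "MacMon" group) as the arithmetic mean
#' of the source score columns, per interaction record.  Averaging happens
#' before any significance thresholding, so the merged column behaves
#' downstream exactly like a native cell type.
#'
#' @param x a \code{\linkS4class{PromoterInteractome}}.
#' @param targetLabel name of the merged score column.
#' @param sourceLabels two or more existing score columns to average.
#' @return the interactome with the merged column appended to its cell types
#'   (sources retained).
#' @export
mergeCellTypes <- function(x, targetLabel, sourceLabels) {
  stopifnot(is(x, "PromoterInteractome"))
  if (length(sourceLabels) < 2)
    stop("need at least two source cell types to merge", call. = FALSE)
  missing <- setdiff(sourceLabels, cellTypes(x))
  if (length(missing))
    stop("source score column(s) not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ints <- interactions(x)
  ints[[targetLabel]] <- rowMeans(as.matrix(ints[, sourceLabels, drop = FALSE]))
  PromoterInteractome(fragments(x), ints,
                      unique(c(cellTypes(x), targetLabel)))
}

#' Cumulative significant-interaction scores per promoter bait
#'
#' For one cell type, sums the significance scores of a bait's significant
#' interactions (score at or above \code{threshold}), over both
#' bait-to-other-end and bait-to-bait records.  A bait-to-bait record
#' contributes its score to the profile of each member bait.  Only cis
#' records within \code{maxDistance} count; trans pairs are excluded.  Baits
#' with no significant interaction are retained with a cumulative score of
#' zero — they shape the low end of the ranked curve.
#'
#' @param x a \code{\linkS4class{PromoterInteractome}}.
#' @param cellType score column to profile.
#' @param threshold significance threshold (5 for CHiCAGO-style scores; use
#'   2 for -log10 q-value scores at FDR < 0.01).
#' @param maxDistance maximum 1-D genomic distance in bp (default 2 Mb).
#' @return data.frame with one row per bait: \code{baitID},
#'   \code{cumScore}, \code{nSignificant}, \code{medianScore} (NA when no
#'   significant interaction).
#' @export
cumulativeScores <- function(x, cellType, threshold = 5, maxDistance = 2e6) {
  sig <- significantRecords(x, cellType, threshold, maxDistance)
  frag <- fragments(x)
  isBait <- structure(mcols(frag)$isBait,
                      names = as.character(mcols(frag)$fragID))
  allBaits <- sort(mcols(frag)$fragID[mcols(frag)$isBait])

  ## double-entry tally: every record credits its bait; records whose other
  ## end is itself a bait also credit that bait
  oeIsBait <- isBait[as.character(sig$oeID)]
  ids <- c(sig$baitID, sig$oeID[oeIsBait])
  vals <- c(sig[[cellType]], sig[[cellType]][oeIsBait])

  out <- data.frame(baitID = allBaits,
                    cumScore = 0, nSignificant = 0L,
                    medianScore = NA_real_)
  if (length(ids)) {
    grp <- factor(as.character(ids), levels = as.character(allBaits))
    keep <- !is.na(grp)   # scores credited to non-bait ids cannot occur
    sums <- tapply(vals[keep], grp[keep], sum)
    ns <- tapply(vals[keep], grp[keep], length)
    meds <- tapply(vals[keep], grp[keep], stats::median)
    hit <- !is.na(sums)
    out$cumScore[hit] <- sums[hit]
    out$nSignificant[hit] <- as.integer(ns[hit])
    out$medianScore[hit] <- meds[hit]
  }
  out
}

#' Tangent-slope inflection cutoff on a ranked score vector
#'
#' Locates the inflection point of an ascending-ranked cumulative-score
#' curve in the manner of the ROSE super-enhancer procedure: using the
#' global slope \code{s = (max - min) / n} (the slope that equals 1 after
#' rescaling both axes to the unit square), each data point anchors a
#' candidate line of slope \code{s}, and the cutoff is the anchor whose
#' line leaves the fewest points on or below it — the point where that line
#' is tangent to the convex ranked curve (ties broken toward the largest
#' rank).  Equivalently, writing \code{z_r = y_r - s * r}, the cutoff rank
#' is the last index attaining \code{min(z)}.
#'
#' Two degenerate shapes yield zero SIPs: a flat curve (all scores equal),
#' and a curve with no elbow — one that rises at least as fast as the
#' global slope from the very first rank (e.g. perfectly linear scores), so
#' the tangent construction has nothing to grip.  Both are flagged
#' \code{degenerate} and report the top rank, so no score lies strictly
#' above the cutoff.
#'
#' @param scores numeric vector of cumulative scores, assumed sorted
#'   ascending (use \code{\link{callSips}} for sorting with deterministic
#'   tie-breaks).
#' @return list with \code{cutoffValue} (score at the tangent point),
#'   \code{cutoffRank} (1-based index in the ascending order) and
#'   \code{degenerate} (see above; callers label zero SIPs).
#' @examples
#' findCutoff(sort((1:100)^3))   # elbow at rank ~ 100 / sqrt(3)
#' @export
findCutoff <- function(scores) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 scores to locate an inflection point",
                  call. = FALSE)
  if (is.unsorted(scores)) stop("scores must be sorted ascending", call. = FALSE)
  rng <- max(scores) - min(scores)
  if (rng == 0) {
    return(list(cutoffValue = scores[n], cutoffRank = n, degenerate = TRUE))
  }
  s <- rng / n
  z <- scores - s * seq_len(n)
  ## point j lies on or below the line through r iff z[j] <= z[r];
  ## minimizing that count = minimizing z, ties -> largest rank
  cutoffRank <- max(which(z == min(z)))
  if (cutoffRank == 1L) {
    ## no elbow: the curve outruns the global slope from the start
    return(list(cutoffValue = scores[n], cutoffRank = n, degenerate = TRUE))
  }
  list(cutoffValue = scores[cutoffRank], cutoffRank = as.integer(cutoffRank),
       degenerate = FALSE)
}

#' Call super-interactive promoters in one cell type
#'
#' Ranks baits by cumulative interaction score (ascending, ties broken by
#' bait id), locates the tangent cutoff with \code{\link{findCutoff}} and
#' labels as SIP every bait whose cumulative score lies strictly above the
#' cutoff value.  On a degenerate flat curve no bait is a SIP.
#'
#' @param profiles data.frame from \code{\link{cumulativeScores}}.
#' @param cellType label recorded in the result.
#' @return A \code{\linkS4class{SipCall}}.
#' @export
callSips <- function(profiles, cellType = "cellType") {
  stopifnot(all(c("baitID", "cumScore") %in% colnames(profiles)))
  ord <- order(profiles$cumScore, profiles$baitID)
  tab <- profiles[ord, , drop = FALSE]
  rownames(tab) <- NULL
  cut <- findCutoff(tab$cumScore)
  tab$rank <- seq_len(nrow(tab))
  tab$sip <- if (cut$degenerate) rep(FALSE, nrow(tab)) else
    tab$cumScore > cut$cutoffValue
  new("SipCall",
      cellType = cellType,
      cutoffValue = cut$cutoffValue,
      cutoffRank = cut$cutoffRank,
      table = tab,
      sipFraction = mean(tab$sip),
      degenerate = cut$degenerate)
}

#' Classify SIPs as cell-type-specific, shared or intermediate
#'
#' Combines per-cell-type SIP calls over a common bait universe.  A bait
#' that is SIP in exactly one cell type is specific to it; a bait that is
#' SIP in every declared cell type is shared; a bait that is SIP in more
#' than one but not all is intermediate; the rest are never-SIP.
#'
#' @param calls named list of \code{\linkS4class{SipCall}} objects (names =
#'   cell types), all over the same baits.
#' @return data.frame with \code{baitID}, \code{nSipCellTypes},
#'   \code{sipCellTypes} (comma-joined), \code{category} (one of
#'   \code{"specific:<cellType>"}, \code{"shared_all"},
#'   \code{"intermediate"}, \code{"never"}), plus one logical column
#'   \code{SIP.<cellType>} per cell type.  Per-category counts are attached
#'   as attribute \code{"counts"}.
#' @export
classifySips <- function(calls) {
  stopifnot(length(calls) >= 1, !is.null(names(calls)))
  cts <- names(calls)
  universe <- sort(sipTable(calls[[1]])$baitID)
  lab <- sapply(calls, function(cl) {
    tab <- sipTable(cl)
    if (!identical(sort(tab$baitID), universe))
      stop("SIP calls must share one bait universe across cell types",
           call. = FALSE)
    structure(tab$sip, names = as.character(tab$baitID))[as.character(universe)]
  })
  lab <- matrix(lab, nrow = length(universe), dimnames = list(NULL, cts))
  nSip <- rowSums(lab)
  category <- ifelse(nSip == 0, "never",
              ifelse(nSip == length(cts), "shared_all",
              ifelse(nSip == 1, paste0("specific:", cts[apply(lab, 1, which.max)]),
                     "intermediate")))
  out <- data.frame(baitID = universe,
                    nSipCellTypes = as.integer(nSip),
                    sipCellTypes = apply(lab, 1, function(v)
                      paste(cts[v], collapse = ",")),
                    category = category,
                    stringsAsFactors = FALSE)
  for (ct in cts) out[[paste0("SIP.", ct)]] <- lab[, ct]
  attr(out, "counts") <- table(out$category)
  out
}

#' Map SIP calls to gene-level flags
#'
#' Projects bait-level SIP labels onto gene symbols.  For each cell type a
#' gene is a SIP gene when it is named on at least one SIP bait.  A gene is
#' a cell-type-specific SIP gene when, under the default unique-capture
#' rule, it is captured by exactly one bait and that bait is a specific SIP
#' of the cell type; with \code{uniqueCaptureOnly = FALSE} the rule relaxes
#' to "every capturing bait is a specific SIP of that cell type".  A shared
#' SIP gene is any gene named on a bait that is SIP in all cell types.
#'
#' @param classification data.frame from \code{\link{classifySips}}.
#' @param fragments fragment \code{GRanges} carrying \code{fragID} and
#'   \code{fragNames}.
#' @param uniqueCaptureOnly logical; see above.
#' @return data.frame with one row per (gene, cellType):
#'   \code{gene}, \code{cellType}, \code{sipGene},
#'   \code{specificSipGene}, \code{sharedSipGene}.
#' @export
mapSipGenes <- function(classification, fragments, uniqueCaptureOnly = TRUE) {
  cts <- sub("^SIP\\.", "",
             grep("^SIP\\.", colnames(classification), value = TRUE))
  nm <- mcols(fragments)$fragNames
  ids <- mcols(fragments)$fragID
  geneTab <- data.frame(gene = unlist(nm),
                        fragID = rep(ids, lengths(nm)),
                        stringsAsFactors = FALSE)
  geneTab <- geneTab[geneTab$fragID %in% classification$baitID, , drop = FALSE]
  if (!nrow(geneTab))
    return(data.frame(gene = character(), cellType = character(),
                      sipGene = logical(), specificSipGene = logical(),
                      sharedSipGene = logical()))
  cls <- classification[match(geneTab$fragID, classification$baitID), ,
                        drop = FALSE]
  nCapture <- table(geneTab$gene)
  genes <- sort(unique(geneTab$gene))
  sharedByGene <- tapply(cls$category == "shared_all", geneTab$gene, any)[genes]

  out <- do.call(rbind, lapply(cts, function(ct) {
    sipHere <- cls[[paste0("SIP.", ct)]]
    specHere <- cls$category == paste0("specific:", ct)
    sipGene <- tapply(sipHere, geneTab$gene, any)[genes]
    if (uniqueCaptureOnly) {
      specGene <- (nCapture[genes] == 1) &
        tapply(specHere, geneTab$gene, all)[genes]
    } else {
      specGene <- tapply(specHere, geneTab$gene, all)[genes]
    }
    data.frame(gene = genes, cellType = ct,
               sipGene = as.logical(sipGene),
               specificSipGene = as.logical(specGene),
               sharedSipGene = as.logical(sharedByGene),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
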