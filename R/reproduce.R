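#' Run the full SIP-calling pipeline on an interactome
#'
#' End-to-end runner: optionally merges score columns into grouped cell
#' types, computes cumulative significant-interaction scores per bait,
#' calls SIPs with the tangent cutoff in every cell type, classifies baits
#' as specific/shared, and maps SIP labels to genes.  Point it at the
#' blood-cell peak matrix (read with \code{\link{readPeakMatrix}}) to
#' reproduce the atlas-scale SIP catalogue, or at
#' \code{\link{simulateInteractome}} output for a fully offline run.
#'
#' @param x a \code{\linkS4class{PromoterInteractome}} or path to a
#'   peak-matrix TSV.
#' @param cellTypes cell types to call; defaults to all declared ones
#'   (required when \code{x} is a path).
#' @param mergeSpec optional named list: merged label -> source columns to
#'   average before calling (e.g.
#'   \code{list(MacMon = c("Mon", "Mac0", "Mac1", "Mac2"))}).
#' @param threshold,maxDistance as in \code{\link{cumulativeScores}}.
#' @param uniqueCaptureOnly gene-mapping rule, see
#'   \code{\link{mapSipGenes}}.
#' @return list with \code{calls} (named \code{SipCall} list),
#'   \code{classification}, \code{geneFlags}, \code{sipCounts},
#'   \code{sipFractions}, \code{sharedCount} and \code{specificCounts}.
#' @export
runSipPipeline <- function(x, cellTypes = NULL, mergeSpec = NULL,
                           threshold = 5, maxDistance = 2e6,
                           uniqueCaptureOnly = TRUE) {
  if (is.character(x)) {
    if (is.null(cellTypes))
      stop("cellTypes must be given when reading from a file", call. = FALSE)
    readCts <- unique(c(setdiff(cellTypes, names(mergeSpec)),
                        unlist(mergeSpec)))
    x <- readPeakMatrix(x, readCts)
  }
  if (!is.null(mergeSpec))
    for (lab in names(mergeSpec))
      x <- mergeCellTypes(x, lab, mergeSpec[[lab]])
  if (is.null(cellTypes)) cellTypes <- cellTypes(x)
  calls <- lapply(cellTypes, function(ct) {
    prof <- cumulativeScores(x, ct, threshold, maxDistance)
    callSips(prof, ct)
  })
  names(calls) <- cellTypes
  classification <- classifySips(calls)
  geneFlags <- mapSipGenes(classification, fragments(x),
                           uniqueCaptureOnly = uniqueCaptureOnly)
  sipCounts <- vapply(calls, function(cl) sum(sipTable(cl)$sip), integer(1))
  sipFractions <- vapply(calls, function(cl) cl@sipFraction, numeric(1))
  specificCounts <- vapply(cellTypes, function(ct)
    sum(classification$category == paste0("specific:", ct)), integer(1))
  list(calls = calls,
       classification = classification,
       geneFlags = geneFlags,
       interactome = x,
       sipCounts = sipCounts,
       sipFractions = sipFractions,
       sharedCount = sum(classification$category == "shared_all"),
       specificCounts = specificCounts)
}
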