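#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps distanceToNearest reduce
NULL

#' PromoterInteractome: a promoter-capture interactome
#'
#' Container for a promoter-capture Hi-C (or HiChIP/Hi-C) interactome in the
#' "peak matrix" layout: a map of restriction fragments (promoter baits and
#' other ends) plus one row per bait/other-end pair carrying a significance
#' score per cell type (CHiCAGO scores for pcHi-C, -log10 q-values for
#' HiChIP/Hi-C).
#'
#' Fragment coordinates are held in a \code{GRanges} (1-based closed, the
#' Bioconductor convention); BED input/output converts to and from 0-based
#' half-open at the file boundary.  The fragment \code{GRanges} carries
#' metadata columns \code{fragID} (integer identifier), \code{fragNames}
#' (a \code{CharacterList} of gene symbols; empty for unnamed fragments) and
#' \code{isBait}.  Interactions are a data.frame with \code{baitID},
#' \code{oeID}, \code{distance} (signed bp, \code{NA} for trans pairs) and
#' one numeric score column per cell type.
#'
#' @slot fragments \code{GRanges} of capture fragments.
#' @slot interactions data.frame of bait/other-end records.
#' @slot cellTypes character vector of score column labels.
#'
#' @aliases PromoterInteractome
#' @exportClass PromoterInteractome
setClass("PromoterInteractome",
  representation(
    fragments    = "GRanges",
    interactions = "data.frame",
    cellTypes    = "character"
  )
)

setValidity("PromoterInteractome", function(object) {
  frag <- object@fragments
  ints <- object@interactions
  cts  <- object@cellTypes
  msg <- character()
  needed <- c("fragID", "fragNames", "isBait")
  if (!all(needed %in% colnames(mcols(frag))))
    msg <- c(msg, "fragments must carry fragID, fragNames and isBait")
  else {
    if (anyDuplicated(mcols(frag)$fragID))
      msg <- c(msg, "fragment identifiers must be unique")
  }
  if (length(frag) && any(width(frag) < 1L))
    msg <- c(msg, "fragment width must be >= 1")
  if (!all(c("baitID", "oeID", "distance") %in% colnames(ints)))
    msg <- c(msg, "interactions must carry baitID, oeID and distance")
  if (!all(cts %in% colnames(ints)))
    msg <- c(msg, "every cell-type label must name a score column")
  if (nrow(ints)) {
    if (any(ints$baitID == ints$oeID))
      msg <- c(msg, "baitID must differ from oeID")
    ids <- mcols(frag)$fragID
    if (!all(ints$baitID %in% ids) || !all(ints$oeID %in% ids))
      msg <- c(msg, "interaction fragment ids must exist in the fragment map")
    for (ct in cts) {
      s <- ints[[ct]]
      if (!is.numeric(s) || anyNA(s) || any(s < 0))
        msg <- c(msg, sprintf("scores in '%s' must be non-negative numbers", ct))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterInteractome
#'
#' @param fragments \code{GRanges} with metadata columns \code{fragID},
#'   \code{fragNames} (CharacterList) and \code{isBait}.
#' @param interactions data.frame with \code{baitID}, \code{oeID},
#'   \code{distance} and one numeric column per cell type.
#' @param cellTypes character labels of the score columns to expose.
#' @return A \code{\linkS4class{PromoterInteractome}} object.
#' @examples
#' frag <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5001), width = 4000))
#' S4Vectors::mcols(frag)$fragID <- 1:2
#' S4Vectors::mcols(frag)$fragNames <- IRanges::CharacterList("GENE1", character())
#' S4Vectors::mcols(frag)$isBait <- c(TRUE, FALSE)
#' ints <- data.frame(baitID = 1L, oeID = 2L, distance = 5000L, Ery = 6.2)
#' PromoterInteractome(frag, ints, "Ery")
#' @export
PromoterInteractome <- function(fragments, interactions, cellTypes) {
  new("PromoterInteractome",
      fragments = fragments,
      interactions = as.data.frame(interactions),
      cellTypes = as.character(cellTypes))
}

#' @describeIn PromoterInteractome-class fragment map accessor
#' @param x,object a \code{PromoterInteractome}
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname PromoterInteractome-class
#' @export
setMethod("fragments", "PromoterInteractome", function(x) x@fragments)

#' @describeIn PromoterInteractome-class interaction table accessor
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname PromoterInteractome-class
#' @export
setMethod("interactions", "PromoterInteractome", function(x) x@interactions)

#' @describeIn PromoterInteractome-class cell-type labels accessor
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname PromoterInteractome-class
#' @export
setMethod("cellTypes", "PromoterInteractome", function(x) x@cellTypes)

#' @rdname PromoterInteractome-class
#' @export
setMethod("show", "PromoterInteractome", function(object) {
  nb <- sum(mcols(object@fragments)$isBait)
  cat("PromoterInteractome with", length(object@fragments), "fragments (",
      nb, "baits ),", nrow(object@interactions), "interactions\n")
  cat("cell types:", paste(object@cellTypes, collapse = ", "), "\n")
})

#' SipCall: the result of calling SIPs in one cell type
#'
#' Holds the ranked cumulative-score table for one cell type together with
#' the tangent-derived inflection cutoff and the resulting
#' super-interactive-promoter (SIP) labels.
#'
#' @slot cellType cell-type label.
#' @slot cutoffValue cumulative score at the tangent point.
#' @slot cutoffRank index of the tangent point in the ascending ranking.
#' @slot table data.frame with \code{baitID}, \code{cumScore},
#'   \code{nSignificant}, \code{medianScore}, \code{rank} (ascending) and
#'   logical \code{sip}.
#' @slot sipFraction fraction of baits labeled SIP.
#' @slot degenerate \code{TRUE} when the ranked curve was flat (all scores
#'   equal), in which case no bait is a SIP.
#' @exportClass SipCall
setClass("SipCall",
  representation(
    cellType    = "character",
    cutoffValue = "numeric",
    cutoffRank  = "integer",
    table       = "data.frame",
    sipFraction = "numeric",
    degenerate  = "logical"
  )
)

setValidity("SipCall", function(object) {
  tab <- object@table
  msg <- character()
  if (!all(c("baitID", "cumScore", "sip") %in% colnames(tab)))
    msg <- c(msg, "table must carry baitID, cumScore and sip")
  else if (nrow(tab) && any(tab$sip & tab$cumScore <= object@cutoffValue))
    msg <- c(msg, "every SIP must have cumScore strictly above the cutoff")
  if (length(msg)) msg else TRUE
})

#' @rdname SipCall-class
#' @param object a \code{SipCall}
#' @export
setMethod("show", "SipCall", function(object) {
  cat(sprintf(
    "SipCall [%s]: %d baits, cutoff %.3f at rank %d, %d SIPs (%.2f%%)%s\n",
    object@cellType, nrow(object@table), object@cutoffValue,
    object@cutoffRank, sum(object@table$sip), 100 * object@sipFraction,
    if (object@degenerate) " [degenerate flat curve]" else ""))
})

#' @describeIn SipCall-class per-bait SIP label table
#' @param x a \code{SipCall}
#' @export
setGeneric("sipTable", function(x) standardGeneric("sipTable"))

#' @rdname SipCall-class
#' @export
setMethod("sipTable", "SipCall", function(x) x@table)

#' @describeIn SipCall-class logical vector of SIP labels named by bait id
#' @export
setGeneric("sipLabels", function(x) standardGeneric("sipLabels"))

#' @rdname SipCall-class
#' @export
setMethod("sipLabels", "SipCall", function(x) {
  structure(x@table$sip, names = as.character(x@table$baitID))
})
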