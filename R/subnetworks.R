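#' Build SIP subnetworks for a cell type and phenotype
#'
#' A SIP subnetwork is a SIP bait together with at least two distinct PIR
#' fragments that each (i) contain a statistically independent GWAS variant
#' of the phenotype and (ii) overlap an open-chromatin peak of the cell
#' type.  For cell types without a peak set (e.g. neutrophils in the blood
#' atlas), the peak condition is dropped.
#'
#' @inheritParams baitVariantOverlap
#' @param sipCall \code{\linkS4class{SipCall}} for the cell type.
#' @param peaks \code{GRanges} of cell-type peaks, or \code{NULL} when the
#'   cell type has none (drops the peak condition).
#' @param phenotype trait label; must be relevant to the cell type under
#'   \code{relevance}.
#' @param minPirs minimum number of qualifying PIRs (default 2).
#' @param minBp minimum peak overlap in bp.
#' @return data.frame with one row per subnetwork: \code{cellType},
#'   \code{phenotype}, \code{baitID}, \code{genes} (";"-joined),
#'   \code{nQualifyingPirs}, \code{nIndependentSnps}.  The member detail
#'   table (\code{baitID}, \code{oeID}, \code{chrom}, \code{start},
#'   \code{end}, \code{score}, \code{rsids}, \code{peakOverlap}) is
#'   attached as attribute \code{"members"}.
#' @export
buildSubnetworks <- function(x, cellType, phenotype, sipCall, variants,
                             peaks = NULL, relevance = defaultRelevanceMap(),
                             threshold = 5, maxDistance = 2e6,
                             minPirs = 2, minBp = 1) {
  rel <- relevance[[cellType]]
  if (is.null(rel) || !phenotype %in% rel)
    stop("phenotype '", phenotype, "' is not relevant to cell type '",
         cellType, "'", call. = FALSE)
  v <- variants[variants$phenotype == phenotype & variants$independent, ,
                drop = FALSE]
  sig <- significantRecords(x, cellType, threshold, maxDistance)
  links <- baitPirLinks(x, cellType, threshold, maxDistance)
  lab <- sipLabels(sipCall)
  links <- links[as.logical(lab[as.character(links$baitID)]), , drop = FALSE]

  emptyNet <- data.frame(cellType = character(), phenotype = character(),
                         baitID = integer(), genes = character(),
                         nQualifyingPirs = integer(),
                         nIndependentSnps = integer())
  emptyMembers <- data.frame(baitID = integer(), oeID = integer(),
                             chrom = character(), start = integer(),
                             end = integer(), score = numeric(),
                             rsids = character(), peakOverlap = logical())
  if (!nrow(links) || !nrow(v)) {
    attr(emptyNet, "members") <- emptyMembers
    return(emptyNet)
  }
  frag <- fragmentIndex(x)
  pirGr <- frag[as.character(links$oeID)]
  varGr <- GRanges(v$chrom, IRanges(v$position, width = 1L))
  ov <- intervalOverlap(varGr, pirGr)
  hitsByLink <- split(v$rsid[ov$queryIdx], ov$subjectIdx)
  rsids <- character(nrow(links))
  rsids[as.integer(names(hitsByLink))] <-
    vapply(hitsByLink, function(r) paste(sort(unique(r)), collapse = ";"),
           character(1))
  hasVar <- nzchar(rsids)
  hasPeak <- if (is.null(peaks)) rep(TRUE, nrow(links)) else
    countOverlaps(harmonizeChromDialect(pirGr, peaks), peaks,
                  minoverlap = minBp) > 0
  qual <- hasVar & hasPeak
  ## interaction score of each qualifying bait-PIR link (max over records,
  ## either orientation for bait-to-bait pairs)
  bestScore <- tapply(c(sig[[cellType]], sig[[cellType]]),
                      c(paste(sig$baitID, sig$oeID),
                        paste(sig$oeID, sig$baitID)), max)
  members <- data.frame(
    baitID = links$baitID[qual], oeID = links$oeID[qual],
    chrom = as.character(seqnames(pirGr))[qual],
    start = start(pirGr)[qual], end = end(pirGr)[qual],
    score = unname(bestScore[paste(links$baitID[qual], links$oeID[qual])]),
    rsids = rsids[qual],
    peakOverlap = if (is.null(peaks)) NA else hasPeak[qual],
    stringsAsFactors = FALSE)
  if (!nrow(members)) {
    attr(emptyNet, "members") <- emptyMembers
    return(emptyNet)
  }
  nQual <- table(members$baitID)
  keepBaits <- as.integer(names(nQual)[nQual >= minPirs])
  members <- members[members$baitID %in% keepBaits, , drop = FALSE]
  if (!nrow(members)) {
    attr(emptyNet, "members") <- emptyMembers
    return(emptyNet)
  }
  geneNames <- vapply(as.character(keepBaits), function(id)
    paste(unlist(mcols(frag[id])$fragNames), collapse = ";"), character(1))
  nSnps <- vapply(keepBaits, function(b) {
    rs <- unlist(strsplit(members$rsids[members$baitID == b], ";"))
    length(unique(rs))
  }, integer(1))
  nets <- data.frame(cellType = cellType, phenotype = phenotype,
                     baitID = keepBaits,
                     genes = geneNames,
                     nQualifyingPirs = as.integer(nQual[as.character(keepBaits)]),
                     nIndependentSnps = nSnps,
                     stringsAsFactors = FALSE)
  nets <- nets[order(nets$baitID), , drop = FALSE]
  rownames(nets) <- NULL
  members <- members[order(members$baitID, members$oeID), , drop = FALSE]
  rownames(members) <- NULL
  attr(nets, "members") <- members
  nets
}

#' Summarize subnetwork collections
#'
#' Tallies subnetworks per (cell type, phenotype) combination, mirroring a
#' per-sheet "CellType_Phenotype" layout.
#'
#' @param nets data.frame of subnetworks (rows from
#'   \code{\link{buildSubnetworks}}, possibly rbind-ed over combinations).
#' @return data.frame with \code{cellType}, \code{phenotype}, \code{n},
#'   \code{sheet} ("CellType_Phenotype").
#' @export
summarizeSubnetworks <- function(nets) {
  if (!nrow(nets))
    return(data.frame(cellType = character(), phenotype = character(),
                      n = integer(), sheet = character()))
  agg <- stats::aggregate(list(n = nets$baitID),
                          by = list(cellType = nets$cellType,
                                    phenotype = nets$phenotype),
                          FUN = length)
  agg <- agg[order(agg$cellType, agg$phenotype), , drop = FALSE]
  agg$sheet <- paste(agg$cellType, agg$phenotype, sep = "_")
  rownames(agg) <- NULL
  agg
}
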