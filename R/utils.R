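#' Blood cell trait vocabulary
#'
#' The 15 hematological trait abbreviations used to label GWAS variants:
#' HCT (hematocrit), HGB (hemoglobin), MCH (mean corpuscular hemoglobin),
#' MCHC (MCH concentration), MCV (mean corpuscular volume), RBC (red blood
#' cell count), RDW (RBC distribution width), BASO, EOS, LYM, MONO, NEU, WBC
#' (white-cell counts), PLT (platelet count) and MPV (mean platelet volume).
#'
#' @return character vector of trait labels.
#' @export
bloodTraitVocabulary <- function() {
  c("HCT", "HGB", "MCH", "MCHC", "MCV", "RBC", "RDW",
    "BASO", "EOS", "LYM", "MONO", "NEU", "WBC", "PLT", "MPV")
}

#' Default cell type to relevant trait map
#'
#' Which blood cell traits are considered biologically relevant when
#' intersecting GWAS variants with the PIRs of each hematopoietic cell type:
#' red-cell traits for erythrocytes, MONO/WBC for macrophages-monocytes,
#' PLT/MPV for megakaryocytes, LYM/WBC for naive CD4 T cells and NEU/WBC for
#' neutrophils.
#'
#' @return named list: cell type -> character vector of trait labels.
#' @export
defaultRelevanceMap <- function() {
  list(
    Ery    = c("HCT", "HGB", "MCH", "MCHC", "RBC", "RDW"),
    MacMon = c("MONO", "WBC"),
    MK     = c("PLT", "MPV"),
    nCD4   = c("LYM", "WBC"),
    Neu    = c("NEU", "WBC")
  )
}

## Harmonize "chr1" vs "1" chromosome dialects between two GRanges.
## Returns the query relabeled to the subject's dialect (warning once).
harmonizeChromDialect <- function(query, subject) {
  qs <- as.character(GenomeInfoDb::seqlevels(query))
  ss <- as.character(GenomeInfoDb::seqlevels(subject))
  if (!length(qs) || !length(ss)) return(query)
  qChr <- any(grepl("^chr", qs))
  sChr <- any(grepl("^chr", ss))
  if (qChr == sChr) return(query)
  warning("mixed chromosome dialects ('chr1' vs '1'); harmonizing query to ",
          if (sChr) "'chr' prefix" else "bare names", call. = FALSE)
  newLevels <- if (sChr) paste0("chr", sub("^chr", "", qs)) else sub("^chr", "", qs)
  GenomeInfoDb::seqlevels(query) <- newLevels
  query
}

## Significant cis records for one cell type: score >= threshold,
## cis (distance present) and |distance| <= maxDistance.
significantRecords <- function(x, cellType, threshold = 5, maxDistance = 2e6) {
  stopifnot(is(x, "PromoterInteractome"))
  if (!cellType %in% cellTypes(x))
    stop("unknown cell type '", cellType, "'; declared: ",
         paste(cellTypes(x), collapse = ", "), call. = FALSE)
  if (threshold <= 0) stop("significance threshold must be > 0", call. = FALSE)
  ints <- interactions(x)
  keep <- !is.na(ints$distance) & abs(ints$distance) <= maxDistance &
    ints[[cellType]] >= threshold
  ints[keep, , drop = FALSE]
}

## GRanges of fragments indexed by fragID (character names for lookup).
fragmentIndex <- function(x) {
  frag <- fragments(x)
  names(frag) <- as.character(mcols(frag)$fragID)
  frag
}

baitIDs <- function(x) {
  frag <- fragments(x)
  mcols(frag)$fragID[mcols(frag)$isBait]
}
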