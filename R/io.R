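#' Read a promoter-capture "peak matrix" interaction table
#'
#' Parses the wide interaction layout used for promoter-capture Hi-C
#' significance scores: one row per bait/other-end pair with bait columns
#' (\code{baitID}, \code{baitChr}, \code{baitStart}, \code{baitEnd},
#' \code{baitName}), other-end columns (\code{oeID}, \code{oeChr},
#' \code{oeStart}, \code{oeEnd}, \code{oeName}), a signed genomic
#' \code{dist} column (empty/NA for trans pairs) and one numeric score
#' column per cell type.
#'
#' Input coordinates are 1-based inclusive (the HindIII-fragment convention
#' of the source data), matching the \code{GRanges} convention used
#' internally, so a fragment's width is \code{end - start + 1}.  Gene-name
#' fields are split on
#' \code{";"}; \code{"."} or empty fields yield an empty name list.
#' Fragments are deduplicated by identifier; an other end whose id also
#' occurs as a bait id is flagged \code{isBait}.  Trans pairs (missing
#' distance) are retained at parse time and filtered downstream.
#'
#' @param path path to the tab-separated table.
#' @param cellTypes character vector naming the score columns to load.
#' @return A \code{\linkS4class{PromoterInteractome}}.
#' @export
readPeakMatrix <- function(path, cellTypes) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("baitID", "baitChr", "baitStart", "baitEnd", "baitName",
                "oeID", "oeChr", "oeStart", "oeEnd", "oeName", "dist",
                cellTypes)
  missing <- setdiff(required, colnames(tab))
  if (length(missing))
    stop("peak matrix is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L)
    return(PromoterInteractome(emptyFragments(), emptyInteractions(cellTypes),
                               cellTypes))
  scores <- lapply(cellTypes, function(ct) {
    s <- suppressWarnings(as.numeric(tab[[ct]]))
    bad <- which(is.na(s) & !(tab[[ct]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("non-numeric score in column '%s' at line %d: '%s'",
                   ct, bad[1] + 1L, tab[[ct]][bad[1]]), call. = FALSE)
    if (anyNA(s))
      stop(sprintf("missing score in column '%s' at line %d", ct,
                   which(is.na(s))[1] + 1L), call. = FALSE)
    s
  })
  names(scores) <- cellTypes

  baitTab <- data.frame(
    fragID = as.integer(tab$baitID), chrom = tab$baitChr,
    start = as.integer(tab$baitStart), end = as.integer(tab$baitEnd),
    name = tab$baitName, fromBait = TRUE, stringsAsFactors = FALSE)
  oeTab <- data.frame(
    fragID = as.integer(tab$oeID), chrom = tab$oeChr,
    start = as.integer(tab$oeStart), end = as.integer(tab$oeEnd),
    name = tab$oeName, fromBait = FALSE, stringsAsFactors = FALSE)
  allFrag <- rbind(baitTab, oeTab)
  ## dedup by id; any id that ever appears on the bait side is a bait
  isBaitById <- tapply(allFrag$fromBait, allFrag$fragID, any)
  firstRow <- allFrag[!duplicated(allFrag$fragID), , drop = FALSE]
  if (anyDuplicated(allFrag$fragID)) {
    key <- paste(allFrag$chrom, allFrag$start, allFrag$end)
    nKeys <- tapply(key, allFrag$fragID, function(k) length(unique(k)))
    if (any(nKeys > 1))
      stop("duplicate fragment id with conflicting coordinates: ",
           paste(names(nKeys)[nKeys > 1][seq_len(min(3, sum(nKeys > 1)))],
                 collapse = ", "), call. = FALSE)
  }
  ord <- order(firstRow$fragID)
  firstRow <- firstRow[ord, , drop = FALSE]
  frag <- GRanges(firstRow$chrom, IRanges(firstRow$start, firstRow$end))
  mcols(frag)$fragID <- firstRow$fragID
  mcols(frag)$fragNames <- splitGeneNames(firstRow$name)
  mcols(frag)$isBait <- as.logical(isBaitById[as.character(firstRow$fragID)])

  ints <- data.frame(baitID = as.integer(tab$baitID),
                     oeID = as.integer(tab$oeID),
                     distance = suppressWarnings(as.numeric(tab$dist)),
                     stringsAsFactors = FALSE)
  for (ct in cellTypes) ints[[ct]] <- scores[[ct]]
  PromoterInteractome(frag, ints, cellTypes)
}

## ";"-separated gene-name field -> CharacterList ("." / "" -> empty)
splitGeneNames <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  CharacterList(lapply(parts, function(p) {
    p <- p[nzchar(p) & p != "."]
    p
  }))
}

emptyFragments <- function() {
  frag <- GRanges()
  mcols(frag)$fragID <- integer()
  mcols(frag)$fragNames <- CharacterList()
  mcols(frag)$isBait <- logical()
  frag
}

emptyInteractions <- function(cellTypes) {
  ints <- data.frame(baitID = integer(), oeID = integer(),
                     distance = numeric())
  for (ct in cellTypes) ints[[ct]] <- numeric()
  ints
}

#' Read a BED file of peaks or other intervals
#'
#' Standard BED3+ ingestion (0-based half-open on disk) for ATAC-seq peaks,
#' TAD boundaries or gene intervals.  Track lines are skipped; intervals are
#' returned sorted by chromosome and start.
#'
#' @param path path to the BED file.
#' @param cellType optional cell-type label stored as metadata.
#' @return A sorted \code{GRanges}; metadata \code{cellType} when supplied.
#' @export
readBed <- function(path, cellType = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("failed to parse BED '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(gr) && any(width(gr) < 1L))
    stop("BED interval with end <= start in '", path, "'", call. = FALSE)
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  mcols(gr) <- NULL
  if (!is.null(cellType)) metadata(gr)$cellType <- cellType
  gr
}

#' Read a GWAS variant table
#'
#' Expects a TSV with columns \code{chrom}, \code{position} (1-based bp),
#' \code{rsid}, \code{phenotype}, \code{pvalue}; optional \code{independent}
#' (conditionally independent signal; default \code{FALSE}) and
#' \code{source}.  Phenotype labels are validated against the blood-trait
#' vocabulary, and duplicate (rsid, phenotype) rows are collapsed.
#'
#' @param path path to the TSV.
#' @param vocabulary allowed phenotype labels.
#' @return data.frame of validated variant records.
#' @export
readVariantTable <- function(path, vocabulary = bloodTraitVocabulary()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("chrom", "position", "rsid", "phenotype", "pvalue")
  missing <- setdiff(required, colnames(tab))
  if (length(missing))
    stop("variant table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) {
    tab$independent <- logical()
    tab$source <- character()
    return(tab[, c(required, "independent", "source")])
  }
  unknown <- setdiff(unique(tab$phenotype), vocabulary)
  if (length(unknown))
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(vocabulary, collapse = ", "), call. = FALSE)
  if (any(tab$position < 1))
    stop("variant positions must be >= 1 (1-based)", call. = FALSE)
  if (!"independent" %in% colnames(tab)) tab$independent <- FALSE
  tab$independent <- as.logical(tab$independent)
  if (!"source" %in% colnames(tab)) tab$source <- NA_character_
  tab <- tab[!duplicated(tab[, c("rsid", "phenotype")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c(required, "independent", "source")]
}

#' Read a gene-by-tissue expression table
#'
#' TSV with a \code{gene} column and one numeric column per cell type or
#' tissue (RPKM-like, already normalized upstream).  Missing cells are kept
#' as \code{NA} (absent), never coerced to zero.
#'
#' @param path path to the TSV.
#' @return data.frame with \code{gene} plus numeric expression columns.
#' @export
readExpressionTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"gene" %in% colnames(tab))
    stop("expression table must have a 'gene' column", call. = FALSE)
  if (anyDuplicated(tab$gene))
    stop("gene symbols must be unique in an expression table", call. = FALSE)
  for (col in setdiff(colnames(tab), "gene")) {
    v <- tab[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (any(v < 0, na.rm = TRUE))
      stop("negative expression value in column '", col, "'", call. = FALSE)
    if (any(is.infinite(v)))
      stop("non-finite expression value in column '", col, "'", call. = FALSE)
    tab[[col]] <- v
  }
  tab
}

#' Write intervals as a sorted annotation BED
#'
#' Exports intervals (for example the PIRs of cell-type-specific SIPs, as
#' input for partitioned-heritability annotation) as a 0-based half-open
#' BED3.  Output is sorted and byte-stable for identical input; overlapping
#' intervals are optionally merged.
#'
#' @param intervals \code{GRanges}.
#' @param path output path.
#' @param merge merge overlapping/adjacent intervals before writing.
#' @return invisibly, the path written.
#' @export
writeAnnotationBed <- function(intervals, path, merge = FALSE) {
  gr <- intervals
  if (merge) gr <- reduce(gr)
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,   # 1-based closed -> 0-based half-open
                   end = end(gr))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), con)
  invisible(path)
}
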