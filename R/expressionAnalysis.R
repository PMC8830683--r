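#' Assign expression quintiles within a cell type
#'
#' Ranks genes from highest (quintile 1) to lowest (quintile 5) expression
#' in the chosen column and splits them into five near-equal bins (bin
#' sizes differ by at most one; earlier bins take the remainder).  Ties are
#' broken deterministically by gene symbol.  Genes with missing expression
#' are excluded; zero expression is retained by default (populating the low
#' quintiles), with \code{dropZeros} to exclude it.
#'
#' @param expression data.frame with a \code{gene} column plus numeric
#'   expression columns (see \code{\link{readExpressionTable}}).
#' @param cellType expression column to rank on.
#' @param dropZeros exclude genes with zero expression.
#' @return data.frame with \code{gene}, \code{quintile} (1 = highest).
#' @export
assignQuintiles <- function(expression, cellType, dropZeros = FALSE) {
  if (!cellType %in% colnames(expression))
    stop("no expression column '", cellType, "'", call. = FALSE)
  v <- expression[[cellType]]
  keep <- !is.na(v)
  if (dropZeros) keep <- keep & v > 0
  genes <- expression$gene[keep]
  v <- v[keep]
  n <- length(v)
  if (n < 5)
    stop("need at least 5 genes with expression values to form quintiles",
         call. = FALSE)
  ord <- order(-v, genes)
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  data.frame(gene = genes[ord],
             quintile = rep(1:5, times = sizes),
             stringsAsFactors = FALSE)
}

## Cochran-Armitage trend test on proportions across ordered groups.
## scores default to the group indices.  alternative:
##   "decreasing" - proportions fall as the score increases (one-sided)
##   "increasing" - proportions rise with the score
##   "two.sided"  - chi-square on z^2 (matches stats::prop.trend.test)
caTrendTest <- function(successes, totals, scores = seq_along(successes),
                        alternative = c("decreasing", "increasing",
                                        "two.sided")) {
  alternative <- match.arg(alternative)
  N <- sum(totals)
  pbar <- sum(successes) / N
  num <- sum(scores * (successes - totals * pbar))
  den <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  z <- num / sqrt(den)
  p <- switch(alternative,
              decreasing = stats::pnorm(z),
              increasing = stats::pnorm(z, lower.tail = FALSE),
              two.sided = stats::pchisq(z^2, df = 1, lower.tail = FALSE))
  list(z = z, pValue = p, alternative = alternative)
}

#' SIP-gene fold enrichment across expression quintiles
#'
#' Computes, per quintile, the proportion of genes that are SIP genes, the
#' fold enrichment relative to the lowest-expression quintile (quintile 5,
#' fold 1 by construction), a chi-square test across the five proportions,
#' and the one-sided Cochran-Armitage trend test (alternative: higher
#' expression means more SIP genes).
#'
#' @param assignments data.frame from \code{\link{assignQuintiles}}.
#' @param sipGenes character vector of SIP gene symbols for the cell type;
#'   genes absent from the assignment universe are dropped with a warning.
#' @return data.frame with one row per quintile: \code{quintile},
#'   \code{nGenes}, \code{nSip}, \code{proportion}, \code{fold};
#'   attributes \code{"chisqP"} and \code{"trendP"}.
#' @export
foldEnrichment <- function(assignments, sipGenes) {
  sipGenes <- unique(sipGenes)
  outside <- setdiff(sipGenes, assignments$gene)
  if (length(outside)) {
    warning(length(outside),
            " SIP gene(s) absent from the expression universe were dropped",
            call. = FALSE)
    sipGenes <- setdiff(sipGenes, outside)
  }
  isSip <- assignments$gene %in% sipGenes
  q <- factor(assignments$quintile, levels = 1:5)
  nGenes <- as.integer(table(q))
  nSip <- as.integer(tapply(isSip, q, sum))
  nSip[is.na(nSip)] <- 0L
  prop <- nSip / nGenes
  fold <- if (prop[5] == 0) {
    warning("no SIP genes in the lowest quintile; folds undefined",
            call. = FALSE)
    rep(NA_real_, 5)
  } else prop / prop[5]
  out <- data.frame(quintile = 1:5, nGenes = nGenes, nSip = nSip,
                    proportion = prop, fold = fold)
  chisq <- suppressWarnings(
    stats::chisq.test(cbind(nSip, nGenes - nSip)))
  trend <- caTrendTest(nSip, nGenes, scores = 1:5,
                       alternative = "decreasing")
  attr(out, "chisqP") <- chisq$p.value
  attr(out, "trendP") <- trend$pValue
  attr(out, "trendZ") <- trend$z
  out
}

#' Compare expression between gene groups
#'
#' Two-sided Wilcoxon rank-sum comparison of expression between two gene
#' sets in one cell type (e.g. SIP vs non-SIP genes, or SIP genes whose
#' baits overlap ATAC peaks vs those that do not).
#'
#' @inheritParams assignQuintiles
#' @param genesA,genesB character vectors of gene symbols.
#' @return one-row data.frame from \code{\link{compareGroups}}.
#' @export
expressionGroupTest <- function(expression, cellType, genesA, genesB) {
  v <- structure(expression[[cellType]], names = expression$gene)
  a <- v[intersect(genesA, names(v))]
  b <- v[intersect(genesB, names(v))]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both gene groups must have expression values", call. = FALSE)
  compareGroups(as.numeric(a), as.numeric(b), kind = "wilcoxon")
}

#' Cross-tissue percentile partition of a gene set
#'
#' For each gene in a set (e.g. the shared SIP genes), computes its mean
#' expression over blood cell-type columns and over other-tissue columns
#' (missing values excluded), ranks the set on each mean, and partitions it
#' into decile bins (bin 1 = top 10 percent).
#'
#' @inheritParams assignQuintiles
#' @param geneSet character vector of gene symbols to partition.
#' @param bloodLabels,otherLabels disjoint sets of expression columns.
#' @return data.frame with \code{gene}, \code{bloodMean}, \code{otherMean},
#'   \code{bloodBin}, \code{otherBin} (NA for a gene with no values in the
#'   respective label set, with a warning).
#' @export
crosstissuePercentiles <- function(expression, geneSet, bloodLabels,
                                   otherLabels) {
  if (length(intersect(bloodLabels, otherLabels)))
    stop("blood and other tissue label sets must be disjoint", call. = FALSE)
  stopifnot(length(geneSet) >= 1)
  rows <- expression[match(geneSet, expression$gene), , drop = FALSE]
  meanOf <- function(labels) {
    m <- as.matrix(rows[, labels, drop = FALSE])
    rowMeans(m, na.rm = TRUE)
  }
  bloodMean <- meanOf(bloodLabels)
  otherMean <- meanOf(otherLabels)
  bloodMean[is.nan(bloodMean)] <- NA
  otherMean[is.nan(otherMean)] <- NA
  if (anyNA(bloodMean) || anyNA(otherMean))
    warning("gene(s) with no values in a label set excluded from that ranking",
            call. = FALSE)
  decileBin <- function(v, tie) {
    bin <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    n <- sum(ok)
    if (n) {
      ord <- order(-v[ok], tie[ok])
      sizes <- rep(n %/% 10L, 10L)
      rem <- n %% 10L
      if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      bins <- rep(1:10, times = sizes)
      bin[ok][ord] <- bins
    }
    bin
  }
  data.frame(gene = geneSet,
             bloodMean = bloodMean, otherMean = otherMean,
             bloodBin = decileBin(bloodMean, geneSet),
             otherBin = decileBin(otherMean, geneSet),
             stringsAsFactors = FALSE)
}
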