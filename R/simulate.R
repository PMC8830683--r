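#' Simulation configuration for a planted-SIP interactome
#'
#' Parameters of the synthetic promoter interactome.  Defaults emulate the
#' statistical structure of the blood-cell promoter-capture atlas: about
#' 7.5\% of baits carry inflated significant-interaction counts (the SIP
#' signal is a count effect — roughly an order of magnitude more
#' significant interactions — while per-interaction score medians differ
#' only modestly, ~8.4 vs ~6.4), open chromatin and GWAS variants
#' concentrate at SIP PIRs, and SIP genes express higher in the matching
#' cell type.
#'
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param nBaits,nOtherEnds fragment counts.
#' @param nChromosomes,chromLength synthetic genome geometry.
#' @param fragmentMeanWidth mean fragment width in bp (HindIII-scale).
#' @param cellTypes cell-type labels.
#' @param sipFraction fraction of baits planted as SIP per cell type.
#' @param sharedFraction fraction of a cell type's planted SIPs shared
#'   across all cell types (the rest are cell-type-specific).
#' @param countMean,countDispersion negative-binomial mean and size for the
#'   per-bait significant-interaction count (non-SIP).
#' @param sipCountMultiplier multiplicative count inflation for SIP baits.
#' @param scoreThreshold significance threshold of the score model.
#' @param scoreMedianSip,scoreMedianNonSip median of the above-threshold
#'   exponential score excess for interactions of SIP / non-SIP baits
#'   (total score medians threshold + these).
#' @param baitToBaitFraction share of partners drawn from baits.
#' @param peakProbSipPir,peakProbOther peak placement probabilities at
#'   SIP-PIR vs other fragments.
#' @param variantRateSipPir,variantRateOther Poisson rates of GWAS variants
#'   per fragment at SIP-PIR vs other fragments.
#' @param independentFraction probability a variant is flagged
#'   conditionally independent.
#' @param motifDisruptionProb probability a variant disrupts a motif.
#' @param exprMeanLog,exprSdLog log-normal expression baseline.
#' @param exprSipShift location shift (log scale) for SIP genes in the
#'   matching cell type.
#' @param otherTissues non-blood tissue labels for the expression table.
#' @param maxDistance maximum 1-D partner distance in bp.
#' @return validated config list of class \code{SipSimConfig}.
#' @export
sipSimConfig <- function(seed = 1L,
                         nBaits = 2000L, nOtherEnds = 8000L,
                         nChromosomes = 3L, chromLength = 5e7,
                         fragmentMeanWidth = 4000,
                         cellTypes = c("Ery", "MacMon", "MK", "nCD4", "Neu"),
                         sipFraction = 0.075, sharedFraction = 0.15,
                         countMean = 5, countDispersion = 2,
                         sipCountMultiplier = 10,
                         scoreThreshold = 5,
                         scoreMedianSip = 3.4, scoreMedianNonSip = 1.4,
                         baitToBaitFraction = 0.1,
                         peakProbSipPir = 0.8, peakProbOther = 0.3,
                         variantRateSipPir = 0.5, variantRateOther = 0.1,
                         independentFraction = 0.5,
                         motifDisruptionProb = 0.3,
                         exprMeanLog = 1, exprSdLog = 1, exprSipShift = 1,
                         otherTissues = c("Liver", "Lung", "Brain", "Skin"),
                         maxDistance = 2e6) {
  cfg <- as.list(environment())
  probs <- c(sipFraction, sharedFraction, baitToBaitFraction,
             peakProbSipPir, peakProbOther, independentFraction,
             motifDisruptionProb)
  stopifnot(all(probs >= 0), all(probs <= 1),
            sipFraction > 0, sipFraction < 1,
            sipCountMultiplier >= 1,
            countMean > 0, countDispersion > 0,
            scoreThreshold > 0, nBaits >= 5, nOtherEnds >= 1,
            length(cellTypes) >= 1)
  structure(cfg, class = "SipSimConfig")
}

#' Simulate a promoter interactome with planted SIPs
#'
#' Lays non-overlapping fragments along synthetic chromosomes, plants a
#' \code{sipFraction} of baits as SIPs per cell type (a shared subset
#' common to all cell types, the rest cell-type-specific), draws per-bait
#' significant-interaction counts from a negative binomial (SIPs inflated
#' by \code{sipCountMultiplier}), samples partners within
#' \code{maxDistance} (a share of them other baits, yielding bait-to-bait
#' records) and assigns scores: significant interactions score
#' \code{threshold + Exponential}, background pairs score below threshold.
#'
#' @param config a \code{\link{sipSimConfig}}.
#' @return list with \code{interactome}
#'   (\code{\linkS4class{PromoterInteractome}}) and \code{truth} (planted
#'   SIP label matrix, shared/specific bait sets, per-cell-type SIP-PIR
#'   sets, gene map and the config snapshot).
#' @export
simulateInteractome <- function(config) {
  stopifnot(inherits(config, "SipSimConfig"))
  set.seed(config$seed)
  nFrag <- config$nBaits + config$nOtherEnds
  perChrom <- diff(round(seq(0, nFrag, length.out = config$nChromosomes + 1)))
  widths <- pmax(500, round(stats::rexp(nFrag, 1 / config$fragmentMeanWidth)))
  chrom <- rep(sprintf("chrS%d", seq_len(config$nChromosomes)), perChrom)
  starts <- integer(nFrag)
  idx0 <- 0L
  for (ci in seq_len(config$nChromosomes)) {
    n <- perChrom[ci]
    w <- widths[idx0 + seq_len(n)]
    slack <- config$chromLength - sum(w)
    if (slack < n)
      stop("infeasible geometry: fragments exceed chromosome length",
           call. = FALSE)
    gaps <- round(stats::rexp(n, n / slack))
    pos <- cumsum(gaps + c(0, w[-n])) + 1L
    if (pos[n] + w[n] - 1 > config$chromLength) {
      ## squeeze gaps deterministically to fit
      gaps <- rep(floor(slack / (2 * n)), n)
      pos <- cumsum(gaps + c(0, w[-n])) + 1L
    }
    starts[idx0 + seq_len(n)] <- pos
    idx0 <- idx0 + n
  }
  frag <- GRanges(chrom, IRanges(starts, width = widths))
  fragID <- seq_len(nFrag)
  baitIdx <- sort(sample.int(nFrag, config$nBaits))
  isBait <- logical(nFrag); isBait[baitIdx] <- TRUE

  ## gene names: most baits 1 gene, a few 2, a few unnamed
  nm <- vector("list", nFrag)
  nm[] <- list(character())
  gCounter <- 0L
  for (i in seq_along(baitIdx)) {
    u <- stats::runif(1)
    k <- if (u < 0.02) 0L else if (u < 0.06) 2L else 1L
    if (k > 0) {
      nm[[baitIdx[i]]] <- sprintf("G%05d", gCounter + seq_len(k))
      gCounter <- gCounter + k
    }
  }
  mcols(frag)$fragID <- fragID
  mcols(frag)$fragNames <- CharacterList(nm)
  mcols(frag)$isBait <- isBait

  ## plant SIP labels
  cts <- config$cellTypes
  nSip <- max(1L, round(config$sipFraction * config$nBaits))
  nShared <- min(nSip, round(config$sharedFraction * nSip))
  baitIds <- fragID[baitIdx]
  sharedBaits <- sort(sample(baitIds, nShared))
  pool <- setdiff(baitIds, sharedBaits)
  sipLab <- matrix(FALSE, nrow = config$nBaits, ncol = length(cts),
                   dimnames = list(as.character(sort(baitIds)), cts))
  specific <- list()
  for (ct in cts) {
    sp <- if (nSip > nShared) sort(sample(pool, nSip - nShared)) else integer()
    pool <- setdiff(pool, sp)
    specific[[ct]] <- sp
    sipLab[as.character(c(sharedBaits, sp)), ct] <- TRUE
  }

  ## candidate partners within maxDistance per bait (midpoint distance)
  mid <- (start(frag) + end(frag)) / 2
  records <- list()
  midByChrom <- split(seq_len(nFrag), chrom)
  for (b in baitIdx) {
    cand <- midByChrom[[chrom[b]]]
    cand <- cand[abs(mid[cand] - mid[b]) <= config$maxDistance & cand != b]
    if (!length(cand)) next
    candBait <- cand[isBait[cand]]
    candOe <- cand[!isBait[cand]]
    for (ct in cts) {
      isSip <- sipLab[as.character(fragID[b]), ct]
      mult <- if (isSip) config$sipCountMultiplier else 1
      ## size scales with the mean so the variance-to-mean ratio (not the
      ## CV) is preserved under inflation: the count boost is systematic
      k <- stats::rnbinom(1, size = config$countDispersion * mult,
                          mu = config$countMean * mult)
      if (k == 0) next
      kb <- min(length(candBait), round(k * config$baitToBaitFraction))
      ko <- min(length(candOe), k - kb)
      partners <- c(if (kb > 0) sample(candBait, kb),
                    if (ko > 0) sample(candOe, ko))
      if (!length(partners)) next
      rate <- log(2) / if (isSip) config$scoreMedianSip else config$scoreMedianNonSip
      records[[length(records) + 1L]] <- data.frame(
        baitID = fragID[b], oeID = fragID[partners], cellType = ct,
        score = config$scoreThreshold + stats::rexp(length(partners), rate))
    }
  }
  sigLong <- if (length(records)) do.call(rbind, records) else
    data.frame(baitID = integer(), oeID = integer(),
               cellType = character(), score = numeric())
  ## normalize bait-to-bait pairs to (smaller id = bait side)
  swap <- isBait[sigLong$oeID] & sigLong$oeID < sigLong$baitID
  tmp <- sigLong$baitID[swap]
  sigLong$baitID[swap] <- sigLong$oeID[swap]
  sigLong$oeID[swap] <- tmp

  key <- paste(sigLong$baitID, sigLong$oeID)
  pairs <- unique(data.frame(baitID = sigLong$baitID, oeID = sigLong$oeID))
  pairs <- pairs[order(pairs$baitID, pairs$oeID), , drop = FALSE]
  pkey <- paste(pairs$baitID, pairs$oeID)
  ints <- data.frame(baitID = pairs$baitID, oeID = pairs$oeID,
                     distance = mid[pairs$oeID] - mid[pairs$baitID])
  for (ct in cts) {
    s <- stats::runif(nrow(pairs), 0, config$scoreThreshold * 0.9)
    here <- sigLong$cellType == ct
    m <- match(key[here], pkey)
    ## keep the max when the same pair was drawn twice in one cell type
    agg <- tapply(sigLong$score[here], m, max)
    s[as.integer(names(agg))] <- agg
    ints[[ct]] <- s
  }
  interactome <- PromoterInteractome(frag, ints, cts)

  ## planted-SIP PIR sets per cell type (from generated significant records)
  sipPirs <- lapply(cts, function(ct) {
    sig <- ints[ints[[ct]] >= config$scoreThreshold, , drop = FALSE]
    sipHere <- rownames(sipLab)[sipLab[, ct]]
    sort(unique(c(sig$oeID[as.character(sig$baitID) %in% sipHere],
                  sig$baitID[as.character(sig$oeID) %in% sipHere])))
  })
  names(sipPirs) <- cts

  geneMap <- data.frame(gene = unlist(nm[baitIdx]),
                        baitID = rep(fragID[baitIdx],
                                     lengths(nm[baitIdx])),
                        stringsAsFactors = FALSE)
  truth <- list(sipLabels = sipLab, sharedBaits = sharedBaits,
                specificBaits = specific, sipPirs = sipPirs,
                geneMap = geneMap, config = config)
  list(interactome = interactome, truth = truth)
}

#' Simulate open-chromatin peaks, GWAS variants and motif annotations
#'
#' Places peaks on fragments with probability \code{peakProbSipPir} at
#' planted-SIP PIRs of each cell type and \code{peakProbOther} elsewhere;
#' draws Poisson variant counts per fragment with the analogous rates,
#' assigning each variant a phenotype relevant to the cell type, an
#' independence flag and (with \code{motifDisruptionProb}) a disrupted
#' motif list.
#'
#' @param sim result of \code{\link{simulateInteractome}}.
#' @param relevance cell type -> relevant phenotypes map.
#' @return list with \code{peaks} (named list of \code{GRanges} per cell
#'   type), \code{variants} (data.frame) and \code{motifs} (data.frame
#'   \code{rsid}, \code{motifs}).
#' @export
simulateAnnotations <- function(sim, relevance = defaultRelevanceMap()) {
  config <- sim$truth$config
  set.seed(config$seed + 1L)
  frag <- fragments(sim$interactome)
  ids <- mcols(frag)$fragID
  isBait <- mcols(frag)$isBait
  tfPool <- c("GATA1", "TAL1", "KLF1", "RUNX1", "SPI1", "CEBPA", "ETS1",
              "FLI1", "NFE2", "MYB")
  peaks <- list()
  variants <- list()
  vCounter <- 0L
  for (ct in config$cellTypes) {
    rel <- relevance[[ct]]
    if (is.null(rel)) rel <- bloodTraitVocabulary()
    inSipPir <- ids %in% sim$truth$sipPirs[[ct]]
    pPeak <- ifelse(inSipPir, config$peakProbSipPir, config$peakProbOther)
    hasPeak <- stats::runif(length(ids)) < pPeak
    pk <- frag[hasPeak]
    ## peaks are narrower than the fragment: central 50%
    pkStart <- start(pk) + floor(width(pk) / 4)
    pkWidth <- pmax(50L, floor(width(pk) / 2))
    pkGr <- GRanges(seqnames(pk), IRanges(pkStart, width = pkWidth))
    metadata(pkGr)$cellType <- ct
    peaks[[ct]] <- pkGr
    rate <- ifelse(inSipPir, config$variantRateSipPir,
                   config$variantRateOther)
    nv <- stats::rpois(length(ids), rate)
    take <- which(nv > 0)
    if (length(take)) {
      fi <- rep(take, nv[take])
      pos <- start(frag)[fi] +
        floor(stats::runif(length(fi)) * width(frag)[fi])
      variants[[ct]] <- data.frame(
        chrom = as.character(seqnames(frag))[fi],
        position = pos,
        rsid = sprintf("rs%07d", vCounter + seq_along(fi)),
        phenotype = sample(rel, length(fi), replace = TRUE),
        pvalue = 10^-stats::runif(length(fi), 8, 30),
        independent = stats::runif(length(fi)) < config$independentFraction,
        source = "synthetic",
        stringsAsFactors = FALSE)
      vCounter <- vCounter + length(fi)
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(chrom = character(), position = numeric(),
               rsid = character(), phenotype = character(),
               pvalue = numeric(), independent = logical(),
               source = character())
  rownames(variants) <- NULL
  disrupt <- stats::runif(nrow(variants)) < config$motifDisruptionProb
  motifs <- vapply(disrupt, function(d) {
    if (!d) "" else
      paste(sort(sample(tfPool, 1 + stats::rpois(1, 1.5))), collapse = ";")
  }, character(1))
  list(peaks = peaks, variants = variants,
       motifs = data.frame(rsid = variants$rsid, motifs = motifs,
                           stringsAsFactors = FALSE))
}

#' Simulate a gene-by-tissue expression table
#'
#' Log-normal expression per gene: in each blood cell type, genes on a
#' planted-SIP bait of that cell type receive a positive location shift
#' (\code{exprSipShift} on the log scale); other tissues are drawn from the
#' unshifted baseline, which makes shared-SIP genes blood-elevated.
#'
#' @param sim result of \code{\link{simulateInteractome}}.
#' @return data.frame with \code{gene} plus one column per blood cell type
#'   and other tissue.
#' @export
simulateExpression <- function(sim) {
  config <- sim$truth$config
  set.seed(config$seed + 2L)
  gm <- sim$truth$geneMap
  genes <- sort(unique(gm$gene))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  sipLab <- sim$truth$sipLabels
  for (ct in config$cellTypes) {
    sipBaits <- rownames(sipLab)[sipLab[, ct]]
    sipGenes <- unique(gm$gene[as.character(gm$baitID) %in% sipBaits])
    shift <- ifelse(genes %in% sipGenes, config$exprSipShift, 0)
    out[[ct]] <- stats::rlnorm(length(genes),
                               meanlog = config$exprMeanLog + shift,
                               sdlog = config$exprSdLog)
  }
  for (tis in config$otherTissues)
    out[[tis]] <- stats::rlnorm(length(genes),
                                meanlog = config$exprMeanLog,
                                sdlog = config$exprSdLog)
  out
}

#' Write a simulated dataset in the formats the readers accept
#'
#' Writes the peak-matrix TSV (1-based inclusive coordinates), one BED per
#' cell-type peak set (0-based half-open), the variant, motif and
#' expression TSVs and a planted-truth TSV, such that reading the files
#' back reproduces the in-memory objects.
#'
#' @param sim result of \code{\link{simulateInteractome}}.
#' @param annotations optional result of \code{\link{simulateAnnotations}}.
#' @param expression optional result of \code{\link{simulateExpression}}.
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return invisibly, the directory.
#' @export
writeDataset <- function(sim, annotations = NULL, expression = NULL, dir,
                         force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("directory '", dir, "' is not empty; use force = TRUE", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- sim$interactome
  frag <- fragments(x)
  ints <- interactions(x)
  ## per-fragment lookup vectors, indexed by position via match on fragID
  ids <- mcols(frag)$fragID
  nameStr <- vapply(as.list(mcols(frag)$fragNames), function(nm) {
    if (length(nm)) paste(nm, collapse = ";") else "."
  }, character(1))
  chrStr <- as.character(seqnames(frag))
  bi <- match(ints$baitID, ids)
  oi <- match(ints$oeID, ids)
  tab <- data.frame(
    baitID = ints$baitID,
    baitChr = chrStr[bi],
    baitStart = start(frag)[bi],
    baitEnd = end(frag)[bi],
    baitName = nameStr[bi],
    oeID = ints$oeID,
    oeChr = chrStr[oi],
    oeStart = start(frag)[oi],
    oeEnd = end(frag)[oi],
    oeName = nameStr[oi],
    dist = ints$distance,
    stringsAsFactors = FALSE)
  for (ct in cellTypes(x)) tab[[ct]] <- ints[[ct]]
  utils::write.table(tab, file.path(dir, "peak_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(annotations)) {
    for (ct in names(annotations$peaks))
      writeAnnotationBed(annotations$peaks[[ct]],
                         file.path(dir, sprintf("peaks_%s.bed", ct)))
    utils::write.table(annotations$variants, file.path(dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(annotations$motifs, file.path(dir, "motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(expression))
    utils::write.table(expression, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truthTab <- data.frame(baitID = as.integer(rownames(sim$truth$sipLabels)),
                         sim$truth$sipLabels, check.names = FALSE)
  colnames(truthTab)[-1] <- paste0("SIP.", colnames(sim$truth$sipLabels))
  utils::write.table(truthTab, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
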