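# Small deterministic interactome built in code, used across unit tests.
# chrS1 carries baits 1-3 (bait 3 names two genes) and other ends 4-7;
# fragment 8 sits on chrS2; row 1-8 is trans (no distance).
makeToyInteractome <- function() {
  frag <- GenomicRanges::GRanges(
    c(rep("chrS1", 7), "chrS2"),
    IRanges::IRanges(c(1, 5001, 10001, 15001, 20001, 25001, 30001, 1),
                     width = 4000))
  S4Vectors::mcols(frag)$fragID <- 1:8
  S4Vectors::mcols(frag)$fragNames <- IRanges::CharacterList(
    "A", "B", c("C", "D"), character(), character(), character(),
    character(), character())
  S4Vectors::mcols(frag)$isBait <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  ints <- data.frame(
    baitID  = c(1, 1, 1, 2, 2, 3, 3, 3, 1),
    oeID    = c(4, 5, 2, 5, 6, 6, 7, 4, 8),
    distance = c(15000, 20000, 5000, 16000, 21000, 16000, 21000, -6000, NA),
    Ery = c(6, 7, 8, 5, 4.9, 5.5, 0.5, 6.2, 11),
    MK  = c(2, 5.5, 1, 9, 6, 3, 12, 5, 11))
  PromoterInteractome(frag, ints, c("Ery", "MK"))
}

# SipCall with directly planted labels, bypassing the cutoff geometry, for
# tests that target downstream logic only.
plantedCall <- function(ids, sip, ct) {
  new("SipCall", cellType = ct, cutoffValue = 50, cutoffRank = 1L,
      table = data.frame(baitID = ids, cumScore = ifelse(sip, 100, 1),
                         rank = seq_along(ids), sip = sip),
      sipFraction = mean(sip), degenerate = FALSE)
}

writeTempTsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

peakMatrixHeader <- function(cts = c("Ery", "MK")) {
  paste(c("baitID", "baitChr", "baitStart", "baitEnd", "baitName",
          "oeID", "oeChr", "oeStart", "oeEnd", "oeName", "dist", cts),
        collapse = "\t")
}
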