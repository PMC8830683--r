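# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# Exhaustive tangent search: for every candidate anchor r, count the points
# lying on or below the line of slope s = (max - min)/n through (r, y_r);
# the cutoff is the anchor minimizing that count (ties -> largest rank).
# An anchor at rank 1 means the curve has no elbow (degenerate, rank n).
oracleCutoff <- function(y) {
  n <- length(y)
  if (max(y) == min(y)) return(list(cutoffRank = n, degenerate = TRUE))
  s <- (max(y) - min(y)) / n
  counts <- integer(n)
  for (r in seq_len(n)) {
    b <- y[r] - s * r
    cnt <- 0L
    for (j in seq_len(n)) if (y[j] <= s * j + b + 1e-12) cnt <- cnt + 1L
    counts[r] <- cnt
  }
  best <- max(which(counts == min(counts)))
  if (best == 1L) list(cutoffRank = n, degenerate = TRUE)
  else list(cutoffRank = best, degenerate = FALSE)
}

# All-pairs interval overlap on two data.frames(chrom, start, end),
# 1-based closed coordinates, minimum 1 bp shared.
oracleOverlapPairs <- function(q, s) {
  out <- NULL
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(s))) {
    if (q$chrom[i] == s$chrom[j] &&
        min(q$end[i], s$end[j]) >= max(q$start[i], s$start[j]))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# Per-other-end promoter degree by explicit partner counting over the raw
# record table; symmetric handling of bait-typed other ends.
oracleDegrees <- function(ints, isBait, cellType, threshold, maxDistance) {
  partners <- list()
  add <- function(region, partner) {
    k <- as.character(region)
    partners[[k]] <<- union(partners[[k]], partner)
  }
  for (i in seq_len(nrow(ints))) {
    d <- ints$distance[i]
    if (is.na(d) || abs(d) > maxDistance) next
    if (ints[[cellType]][i] < threshold) next
    add(ints$oeID[i], ints$baitID[i])
    if (isBait[as.character(ints$oeID[i])]) add(ints$baitID[i], ints$oeID[i])
  }
  sapply(partners, length)
}

# Two-sided Fisher exact p by full hypergeometric tail sum (minimum
# likelihood convention) for the table (a, b / c, d).
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  pr <- dhyper(x, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all group-A assignments.
oracleRankSumP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
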