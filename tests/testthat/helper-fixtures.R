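# Shared fixture builders and independent oracles. Oracles are deliberately
# written as plain loops/enumeration, independent of the package internals
# they check.

tracGuide <- function(maxMismatch = 6L)
  GuideSpec("TRAC", "AGAGTCTCTCAGCTGGTACA", "cas9", maxMismatch = maxMismatch)

# Small planted-genome fixture: one chromosome, planted sites.
plantedFixture <- function(chromLen = 50000L, requests = NULL, seed = 3L,
                           guide = tracGuide()) {
  if (is.null(requests)) {
    requests <- data.frame(chrom = "chr1", position = c(10000L, 30000L),
                           strand = c("+", "-"), nMismatch = c(0L, 4L),
                           efficiency = c(1, 0.3), stringsAsFactors = FALSE)
  }
  g <- makeGenome(1, chromLen, seed = seed)
  pl <- plantSites(g, guide, requests, seed = seed + 1L)
  c(pl, list(guide = guide))
}

# Build an AlignmentSet directly from a pair table (for arithmetic tests).
pairSet <- function(pairs, seqlengths, label = "manual") {
  defaults <- list(strand1 = "+", strand2 = "-", rlen = 36L, mapq = 42L,
                   isSingleton = FALSE)
  for (col in names(defaults)) {
    if (is.null(pairs[[col]])) pairs[[col]] <- rep(defaults[[col]],
                                                   length.out = nrow(pairs))
  }
  if (is.null(pairs$qname)) pairs$qname <- sprintf("q%04d", seq_len(nrow(pairs)))
  pairs$strand2[pairs$isSingleton] <- NA_character_
  dsbscan:::.AlignmentSet(
    pairs[, c("qname", "chrom", "start1", "strand1", "start2", "strand2",
              "rlen", "mapq", "isSingleton",
              intersect("origin", names(pairs)))],
    seqlengths, label = label)
}

# --- enumeration oracles ----------------------------------------------------

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  allW <- as.vector(signs %*% r)
  min(1, 2 * min(mean(allW <= w), mean(allW >= w)))
}

# Exact two-sided rank-sum p by enumerating all rank assignments to x.
enumRankSumP <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(r), nx)
  allU <- apply(combs, 2, function(ix) sum(seq_len(length(r))[ix])) -
    nx * (nx + 1) / 2
  min(1, 2 * min(mean(allU <= u), mean(allU >= u)))
}

# Brute-force candidate scan: direct midpoint counting in every window,
# interval merging and weighted-median summits, written independently.
bruteCandidates <- function(mids, chromLen, binSize, window, cutoff) {
  nbins <- as.integer(ceiling(chromLen / binSize))
  qual <- list()
  for (b in 0:(nbins - 1)) {
    lo <- b * binSize
    hi <- min(chromLen, lo + window)
    if (sum(mids >= lo & mids < hi) >= cutoff)
      qual[[length(qual) + 1L]] <- c(lo, hi)
  }
  if (!length(qual)) {
    return(data.frame(start = integer(), end = integer(), summit = integer(),
                      support = integer()))
  }
  regions <- list(qual[[1]])
  for (iv in qual[-1]) {
    last <- regions[[length(regions)]]
    if (iv[1] < last[2]) {
      regions[[length(regions)]] <- c(last[1], max(last[2], iv[2]))
    } else regions[[length(regions) + 1L]] <- iv
  }
  out <- lapply(regions, function(rg) {
    inReg <- mids[mids >= rg[1] & mids < rg[2]]
    support <- length(inReg)
    bins <- seq(rg[1] %/% binSize, (rg[2] - 1) %/% binSize)
    cnt <- vapply(bins, function(b)
      sum(inReg >= b * binSize & inReg < (b + 1) * binSize), integer(1))
    centers <- bins * binSize + binSize %/% 2
    keepCum <- cumsum(cnt)
    summit <- centers[which(keepCum * 2 >= support)[1]]
    data.frame(start = rg[1], end = rg[2], summit = summit,
               support = support)
  })
  do.call(rbind, out)
}

# Weak-efficiency study conditions for the sensitivity-gain comparison:
# strong on-target, weak off-targets (the regime where prolonged MRE11
# residence rescues detection).
weakRunConfig <- function(masterSeed) {
  cfg <- defaultRunConfig(masterSeed)
  cfg$sites$efficiency <- c(1.0, 0.06, 0.05, 0.05, 0.04, 0.04,
                            0.03, 0.03, 0.02, 0.02, 0.01)
  cfg
}

# Midpoint fixture: place bare midpoints as zero-length fragments.
midpointBins <- function(mids, chromLen, binSize = 50L) {
  g <- makeGenome(1, chromLen, seed = 1)
  pairs <- data.frame(chrom = rep("chr1", length(mids)), start1 = mids,
                      start2 = mids, rlen = rep(0L, length(mids)),
                      isSingleton = rep(FALSE, length(mids)))
  # rlen 0 makes the fragment midpoint equal the placed coordinate
  bins <- binFragmentMidpoints(pairSet(pairs, chromLengths(g)), binSize)
  bins
}
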