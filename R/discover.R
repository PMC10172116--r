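# Candidate cleavage-site detection from fragment pileups, protospacer/PAM
# matching with mismatch counting, and no-nuclease control subtraction.

#' Bin fragment midpoints
#'
#' Each proper (non-singleton) pair contributes one count to the bin holding
#' its fragment midpoint; the sum over bins equals the proper pair count.
#'
#' @param aln A filtered \link{AlignmentSet}.
#' @param binSize Bin width in bases (default 50).
#' @return data.frame with columns \code{chrom}, \code{bin} (0-based index),
#'   \code{count}; attributes \code{binSize} and \code{seqlengths}.
#' @export
binFragmentMidpoints <- function(aln, binSize = 50L) {
  p <- pairRecords(aln)
  p <- p[!p$isSingleton, , drop = FALSE]
  if (nrow(p)) {
    fragStart <- pmin(p$start1, p$start2)
    fragEnd <- pmax(p$start1, p$start2) + p$rlen
    mid <- (fragStart + fragEnd) %/% 2L
    bin <- mid %/% as.integer(binSize)
    tab <- stats::aggregate(list(count = rep(1L, length(bin))),
                            by = list(chrom = p$chrom, bin = bin), FUN = sum)
    tab <- tab[order(tab$chrom, tab$bin), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(chrom = character(), bin = integer(),
                      count = integer(), stringsAsFactors = FALSE)
  }
  attr(tab, "binSize") <- as.integer(binSize)
  attr(tab, "seqlengths") <- aln@seqlengths
  tab
}

#' Find candidate cleavage regions from binned midpoints
#'
#' A sliding window (width \code{window}, stride one bin) qualifies wherever
#' it holds at least \code{cutoffC} fragment midpoints; overlapping
#' qualifying windows are merged. A merged region's support is its total
#' midpoint count and its summit the (lower) weighted median of the bin
#' centers it covers. Candidates are sorted by support descending, ties by
#' chromosome then coordinate.
#'
#' @param bins Output of \link{binFragmentMidpoints}.
#' @param cutoffC Minimum fragment support (default 2, the sensitive cutoff;
#'   3 for deeply merged libraries).
#' @param window Window width in bases (default 500).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open merged region), \code{summit}, \code{support}.
#' @export
findCandidates <- function(bins, cutoffC = 2L, window = 500L) {
  if (cutoffC < 1L) stop("cutoffC must be >= 1")
  bs <- attr(bins, "binSize")
  sl <- attr(bins, "seqlengths")
  if (is.null(bs) || is.null(sl))
    stop("bins must come from binFragmentMidpoints()")
  w <- as.integer(ceiling(window / bs))
  out <- list()
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, , drop = FALSE]
    clen <- sl[[chrom]]
    nbins <- as.integer(ceiling(clen / bs))
    counts <- integer(nbins)
    counts[b$bin + 1L] <- b$count
    # rolling sum over w bins, anchored at each start bin (truncated at end)
    cs <- cumsum(c(0L, counts))
    starts <- seq_len(nbins)
    ends <- pmin(starts + w - 1L, nbins)
    winSum <- cs[ends + 1L] - cs[starts]
    qual <- which(winSum >= cutoffC)
    if (!length(qual)) next
    # merge overlapping qualifying windows (base-space intervals)
    lo <- (qual - 1L) * bs
    hi <- pmin(clen, (qual - 1L) * bs + as.integer(window))
    merged <- list()
    curLo <- lo[1]; curHi <- hi[1]
    for (i in seq_along(qual)[-1]) {
      if (lo[i] < curHi) curHi <- max(curHi, hi[i])
      else { merged[[length(merged) + 1L]] <- c(curLo, curHi)
             curLo <- lo[i]; curHi <- hi[i] }
    }
    merged[[length(merged) + 1L]] <- c(curLo, curHi)
    for (m in merged) {
      binIdx <- seq(m[1] %/% bs + 1L, min(nbins, (m[2] - 1L) %/% bs + 1L))
      cnt <- counts[binIdx]
      support <- sum(cnt)
      centers <- (binIdx - 1L) * bs + bs %/% 2L
      cum <- cumsum(cnt)
      summit <- centers[which(cum * 2L >= support)[1]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = m[1], end = m[2], summit = summit,
        support = support, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$support, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count mismatches between two equal-length DNA strings
#'
#' Hamming distance; gapped or bulged comparison is deliberately unsupported
#' (sites are annotated purely by substitution mismatch count).
#'
#' @param a,b A/C/G/T strings of equal length.
#' @return Integer mismatch count.
#' @examples
#' countMismatches("AGAGTCTCTCAGCTGGTACA", "AGAGTCTCTCAGCTGGTACA")
#' @export
countMismatches <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length (no gapped comparison)")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Scan one chromosome sequence (plain character) around a summit for the
# best protospacer placement. Vectorized over placements: one utf8 decode of
# the scanned region, then matrix mismatch counting and per-character IUPAC
# PAM checks. Returns NULL or a one-row data.frame.
.matchProtoInSeq <- function(chromSeq, clen, chrom, summit, guide,
                             searchRadius) {
  g <- guide@protospacer
  L <- nchar(g)
  pamLen <- nchar(guide@pam)
  pLo <- max(0L, summit - as.integer(searchRadius))
  pHi <- min(clen - L, summit + as.integer(searchRadius))
  if (pHi < pLo) return(NULL)
  # region generously padded so PAM footprints stay inside it when in-bounds
  rLo <- max(0L, pLo - pamLen)                 # 0-based
  rHi <- min(clen, pHi + L + pamLen)
  X <- utf8ToInt(substr(chromSeq, rLo + 1L, rHi))
  gCode <- utf8ToInt(g)
  rcgCode <- utf8ToInt(revcomp(g))
  ps <- seq(pLo, pHi)                          # candidate protospacer starts
  loc <- ps - rLo                              # 0-based offsets into X
  segIdx <- outer(seq_len(L), loc, `+`)        # 1-based rows of each segment
  segs <- matrix(X[segIdx], nrow = L)
  mmFwd <- colSums(segs != gCode)
  mmRev <- colSums(segs != rcgCode)
  patCodes <- function(pat) lapply(
    strsplit(pat, "")[[1]],
    function(ch) utf8ToInt(paste(.iupac[[ch]], collapse = "")))
  checkPam <- function(pamStart0, codes) {     # vector of 0-based PAM starts
    ok <- pamStart0 >= 0L & pamStart0 + pamLen <= clen
    off <- pamStart0 - rLo
    for (j in seq_len(pamLen)) {
      idx <- off + j
      code <- ifelse(idx >= 1L & idx <= length(X), X[pmax(1L, pmin(idx, length(X)))], -1L)
      ok <- ok & (code %in% codes[[j]])
    }
    ok
  }
  pamOK <- function(pamStart0) checkPam(pamStart0, patCodes(guide@pam))
  pamOKrev <- function(pamStart0)
    checkPam(pamStart0, patCodes(iupacRevcomp(guide@pam)))
  if (guide@nuclease == "cas9") {
    pamStartF <- ps + L
    pamStartR <- ps - pamLen
  } else {
    pamStartF <- ps - pamLen
    pamStartR <- ps + L
  }
  okF <- pamOK(pamStartF)
  okR <- pamOKrev(pamStartR)
  hits <- rbind(
    if (any(okF)) data.frame(p = ps[okF], strand = "+", mm = mmFwd[okF]),
    if (any(okR)) data.frame(p = ps[okR], strand = "-", mm = mmRev[okR]))
  if (is.null(hits) || !nrow(hits)) return(NULL)
  hits$cut <- cutPosition(hits$p, L, hits$strand, guide@nuclease)
  ord <- order(hits$mm, abs(hits$cut - summit), hits$strand == "-", hits$p)
  best <- hits[ord[1], ]
  if (best$mm > guide@maxMismatch) return(NULL)
  seg <- substr(chromSeq, best$p + 1L, best$p + L)
  pf <- pamFootprint(best$p, L, best$strand, guide@nuclease, pamLen)
  pamSeq <- substr(chromSeq, pf[1] + 1L, pf[2])
  data.frame(chrom = chrom, cut = best$cut, strand = best$strand,
             protospacer = if (best$strand == "+") seg else revcomp(seg),
             pam = if (best$strand == "+") pamSeq else revcomp(pamSeq),
             nMismatch = as.integer(best$mm), stringsAsFactors = FALSE)
}

#' Match a candidate region to the guide protospacer
#'
#' Scans both strands of the reference within \code{summit +/- searchRadius}
#' for every placement where the PAM rule holds and returns the placement
#' minimizing the mismatch count (ties broken by distance of the implied cut
#' from the summit, then + strand, then leftmost coordinate), or \code{NULL}
#' if no PAM-adjacent placement within \code{maxMismatch} exists.
#'
#' @param genome A \link{GenomeRef}.
#' @param region One candidate: a one-row data.frame or list with
#'   \code{chrom} and \code{summit} (e.g. a row of \link{findCandidates}).
#' @param guide A \link{GuideSpec}.
#' @param searchRadius Scan half-width in bases around the summit (default
#'   250, covering the maximum fragment half-length plus end jitter that
#'   separates a midpoint summit from the cut).
#' @return One-row data.frame (\code{chrom}, \code{cut}, \code{strand},
#'   \code{protospacer}, \code{pam}, \code{nMismatch}) or \code{NULL}.
#' @export
matchProtospacer <- function(genome, region, guide, searchRadius = 250L) {
  chrom <- as.character(region$chrom)[1]
  summit <- as.integer(region$summit)[1]
  chromSeq <- as.character(genomeSeqs(genome)[[chrom]])
  .matchProtoInSeq(chromSeq, nchar(chromSeq), chrom, summit, guide,
                   searchRadius)
}

#' Subtract no-nuclease control sites
#'
#' The final site set is the treated set minus any site whose cut position
#' lies within \code{tolerance} of a control-sample site on the same
#' chromosome; removed sites are presumed false positives.
#'
#' @param treatedSites,controlSites Site data.frames (column \code{cut},
#'   \code{chrom}).
#' @param tolerance Matching tolerance in bases (default 100).
#' @return List with \code{sites} (retained) and \code{removed}.
#' @export
subtractControl <- function(treatedSites, controlSites, tolerance = 100L) {
  if (is.null(controlSites) || nrow(controlSites) == 0L ||
      nrow(treatedSites) == 0L) {
    return(list(sites = treatedSites, removed = treatedSites[0, , drop = FALSE]))
  }
  hit <- vapply(seq_len(nrow(treatedSites)), function(i) {
    any(controlSites$chrom == treatedSites$chrom[i] &
          abs(controlSites$cut - treatedSites$cut[i]) <= tolerance)
  }, logical(1))
  list(sites = treatedSites[!hit, , drop = FALSE],
       removed = treatedSites[hit, , drop = FALSE])
}

.emptySiteTable <- function() {
  data.frame(chrom = character(), cut = integer(), strand = character(),
             protospacer = character(), pam = character(),
             nMismatch = integer(), support = integer(), rpm = numeric(),
             onTarget = logical(), stringsAsFactors = FALSE)
}

#' Discover cleavage sites from an alignment set
#'
#' Full discovery pipeline: fragment-midpoint binning, sliding-window
#' candidate detection at the support cutoff, protospacer/PAM matching around
#' each candidate summit, de-duplication of calls sharing a cut position
#' (maximum support kept), RPM annotation in a fixed window around the cut,
#' and subtraction of sites also discovered in a matched no-nuclease control.
#' Output is sorted with the on-target site (0 mismatches) first, then by
#' RPM descending.
#'
#' @param aln Filtered, depth-matched \link{AlignmentSet} (treated sample).
#' @param control Optional matched no-nuclease control: a filtered
#'   \link{AlignmentSet} (its sites are discovered with the same parameters)
#'   or an already-discovered control site table, or \code{NULL}.
#' @param genome A \link{GenomeRef}.
#' @param guide A \link{GuideSpec}.
#' @param cutoffC Minimum fragment support for a candidate (default 2).
#' @param binSize,window,searchRadius,controlTolerance,rpmWindowBp Tuning
#'   parameters; see \link{findCandidates}, \link{matchProtospacer},
#'   \link{subtractControl} and \link{rpmWindow}.
#' @return Site table data.frame (\code{chrom}, \code{cut}, \code{strand},
#'   \code{protospacer}, \code{pam}, \code{nMismatch}, \code{support},
#'   \code{rpm}, \code{onTarget}); attributes \code{removedByControl} and
#'   \code{candidates} expose the intermediate stages.
#' @export
discoverSites <- function(aln, control = NULL, genome, guide, cutoffC = 2L,
                          binSize = 50L, window = 500L, searchRadius = 250L,
                          controlTolerance = 100L, rpmWindowBp = 1500L) {
  stopifnot(is(aln, "AlignmentSet"), is(genome, "GenomeRef"),
            is(guide, "GuideSpec"))
  if (guide@nuclease == "cas9" && !grepl("G", guide@pam))
    stop("PAM rule inconsistent with a Cas9 guide")
  bins <- binFragmentMidpoints(aln, binSize)
  cands <- findCandidates(bins, cutoffC, window)
  seqCache <- as.character(genomeSeqs(genome))
  lens <- chromLengths(genome)
  calls <- list()
  for (i in seq_len(nrow(cands))) {
    hit <- .matchProtoInSeq(seqCache[[cands$chrom[i]]],
                            lens[[cands$chrom[i]]], cands$chrom[i],
                            cands$summit[i], guide, searchRadius)
    if (is.null(hit)) next
    hit$support <- cands$support[i]
    calls[[length(calls) + 1L]] <- hit
  }
  sites <- if (length(calls)) do.call(rbind, calls) else .emptySiteTable()
  if (nrow(sites)) {
    # de-duplicate calls sharing a cut position, keeping maximal support
    sites <- sites[order(sites$chrom, sites$cut, -sites$support), ,
                   drop = FALSE]
    sites <- sites[!duplicated(sites[, c("chrom", "cut")]), , drop = FALSE]
    sites$rpm <- vapply(seq_len(nrow(sites)), function(i) {
      rpmWindow(aln, sites$chrom[i], sites$cut[i], rpmWindowBp)
    }, numeric(1))
    sites$onTarget <- sites$nMismatch == 0L
  } else {
    sites <- .emptySiteTable()
  }
  removed <- .emptySiteTable()
  if (!is.null(control)) {
    controlSites <- if (is.data.frame(control)) control
      else discoverSites(control, NULL, genome, guide, cutoffC,
                         binSize, window, searchRadius,
                         controlTolerance, rpmWindowBp)
    sub <- subtractControl(sites, controlSites, controlTolerance)
    sites <- sub$sites
    removed <- sub$removed
  }
  sites <- sites[order(-sites$onTarget, -sites$rpm), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "removedByControl") <- removed
  attr(sites, "candidates") <- cands
  sites
}
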