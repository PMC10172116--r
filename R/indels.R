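# Flank-anchored amplicon indel calling: reads are classified by exact,
# unique matches to two 20-bp anchors located 20 bp outside the target
# sequence; after a mean-quality filter, an indel is a flank-to-flank
# segment whose length differs from the reference. Substitutions between the
# flanks never change the call (length-only definition).

#' Locate flank anchors for an amplicon reference
#'
#' The anchors are the 20-bp reference segments 20 bp outside each end of
#' the target sequence: left flank at \code{[targetStart-40, targetStart-20)}
#' and right flank at \code{[targetEnd+20, targetEnd+40)} (0-based
#' half-open). Each must occur exactly once in the reference.
#'
#' @param refSeq Amplicon reference sequence (A/C/G/T).
#' @param targetStart,targetEnd 0-based half-open span of the gRNA target
#'   sequence within \code{refSeq}.
#' @return An \link{AmpliconSpec}.
#' @export
locateFlanks <- function(refSeq, targetStart, targetEnd) {
  refSeq <- toupper(refSeq)
  targetStart <- as.integer(targetStart)
  targetEnd <- as.integer(targetEnd)
  if (targetStart < 40L || targetEnd + 40L > nchar(refSeq))
    stop("reference too short to host 20-bp flanks at 20-bp standoff")
  if (targetEnd <= targetStart) stop("targetEnd must exceed targetStart")
  left <- substr(refSeq, targetStart - 40L + 1L, targetStart - 20L)
  right <- substr(refSeq, targetEnd + 20L + 1L, targetEnd + 40L)
  for (side in list(c("left", left), c("right", right))) {
    m <- gregexpr(side[2], refSeq, fixed = TRUE)[[1]]
    if (length(m) != 1L || m[1] == -1L)
      stop("the ", side[1], " flank ('", side[2],
           "') does not occur exactly once in the reference")
  }
  new("AmpliconSpec", refSeq = refSeq, targetStart = targetStart,
      targetEnd = targetEnd, leftFlank = left, rightFlank = right,
      innerRefLen = targetEnd - targetStart + 40L)
}

# Exact-match starts (1-based) of a pattern in a subject string.
.exactHits <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Inner length between flank inner edges for one read orientation, or NA if
# the flanks are not each found exactly once in consistent order.
.innerLength <- function(seq, leftFlank, rightFlank) {
  l <- .exactHits(leftFlank, seq)
  r <- .exactHits(rightFlank, seq)
  if (length(l) != 1L || length(r) != 1L) return(NA_integer_)
  inner <- r - (l + 20L)
  if (inner < 0L) return(NA_integer_)
  inner
}

#' Classify one amplicon read
#'
#' The read is scanned for exact matches to both flank anchors, forward
#' first, then reverse-complemented; a read valid in both orientations is
#' excluded as ambiguous, as is one where either flank is absent or found
#' more than once (\code{no_flank}). Reads with mean quality less than or
#' equal to \code{minMeanQ} are then excluded (\code{quality}; the quality
#' filter is a strict "greater than"). Otherwise the call is the signed
#' difference between the observed and reference flank-to-flank lengths.
#'
#' @param readSeq Read sequence.
#' @param readQuals Numeric Phred qualities, same length as \code{readSeq}.
#' @param spec An \link{AmpliconSpec}.
#' @param minMeanQ Mean-quality threshold (default 20, strict).
#' @return A list: \code{size} (integer indel size, 0 = no mutation) and
#'   \code{excluded} (\code{NA}, \code{"no_flank"} or \code{"quality"}).
#' @export
callRead <- function(readSeq, readQuals, spec, minMeanQ = 20) {
  if (nchar(readSeq) != length(readQuals))
    stop("read sequence and qualities differ in length")
  fwd <- .innerLength(readSeq, spec@leftFlank, spec@rightFlank)
  rev <- .innerLength(revcomp(readSeq), spec@leftFlank, spec@rightFlank)
  if (is.na(fwd) == is.na(rev)) # neither or both orientations valid
    return(list(size = NA_integer_, excluded = "no_flank"))
  if (mean(readQuals) <= minMeanQ)
    return(list(size = NA_integer_, excluded = "quality"))
  inner <- if (!is.na(fwd)) fwd else rev
  list(size = inner - spec@innerRefLen, excluded = NA_character_)
}

# Vectorized classification of many reads; returns per-read sizes and
# exclusion reasons. Same rules as callRead (tested for equivalence).
.callReads <- function(seqs, qualStrings, spec, minMeanQ = 20) {
  n <- length(seqs)
  dna <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(dna)
  cntLF <- Biostrings::vcountPattern(spec@leftFlank, dna)
  cntRF <- Biostrings::vcountPattern(spec@rightFlank, dna)
  cntLR <- Biostrings::vcountPattern(spec@leftFlank, rc)
  cntRR <- Biostrings::vcountPattern(spec@rightFlank, rc)
  innerF <- rep(NA_integer_, n)
  innerR <- rep(NA_integer_, n)
  okF <- cntLF == 1L & cntRF == 1L
  okR <- cntLR == 1L & cntRR == 1L
  pos1 <- function(pattern, subset) {
    s <- Biostrings::vmatchPattern(pattern, subset)
    vapply(s, function(ir) IRanges::start(ir)[1], integer(1))
  }
  if (any(okF)) {
    l <- pos1(spec@leftFlank, dna[okF])
    r <- pos1(spec@rightFlank, dna[okF])
    v <- r - (l + 20L)
    v[v < 0L] <- NA_integer_
    innerF[okF] <- v
  }
  if (any(okR)) {
    l <- pos1(spec@leftFlank, rc[okR])
    r <- pos1(spec@rightFlank, rc[okR])
    v <- r - (l + 20L)
    v[v < 0L] <- NA_integer_
    innerR[okR] <- v
  }
  validF <- !is.na(innerF)
  validR <- !is.na(innerR)
  valid <- xor(validF, validR)
  inner <- ifelse(validF, innerF, innerR)
  excluded <- rep(NA_character_, n)
  excluded[!valid] <- "no_flank"
  meanQ <- vapply(qualStrings, function(q) mean(utf8ToInt(q) - 33),
                  numeric(1), USE.NAMES = FALSE)
  lowQ <- valid & meanQ <= minMeanQ
  excluded[lowQ] <- "quality"
  size <- rep(NA_integer_, n)
  analyzed <- valid & !lowQ
  size[analyzed] <- inner[analyzed] - spec@innerRefLen
  list(size = size, excluded = excluded)
}

#' Summarize indels over a set of amplicon reads
#'
#' Applies the per-read classification to every read and aggregates an
#' indel-size histogram (key "0" = no mutation) with exact bookkeeping:
#' excluded plus analyzed counts always sum to the input count. The summary
#' is invariant to read order.
#'
#' @param reads data.frame with columns \code{seq} and \code{qual}
#'   (Phred+33 strings), e.g. from \link{simulateAmpliconReads} or
#'   \link{readFastqReads}, or a FASTQ path.
#' @param spec An \link{AmpliconSpec}.
#' @param minMeanQ Mean-quality threshold (default 20).
#' @return An \link{IndelSummary}.
#' @export
summarizeIndels <- function(reads, spec, minMeanQ = 20) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- readFastqReads(reads)
  n <- nrow(reads)
  if (n == 0L) {
    return(new("IndelSummary", nInput = 0L, nExcludedNoFlank = 0L,
               nExcludedQuality = 0L, histogram = integer(0),
               indelFraction = NA_real_))
  }
  res <- .callReads(reads$seq, reads$qual, spec, minMeanQ)
  sizes <- res$size[is.na(res$excluded)]
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  hist <- setNames(as.integer(hist), names(hist))
  nAnalyzed <- length(sizes)
  new("IndelSummary", nInput = n,
      nExcludedNoFlank = sum(res$excluded == "no_flank", na.rm = TRUE),
      nExcludedQuality = sum(res$excluded == "quality", na.rm = TRUE),
      histogram = hist,
      indelFraction = if (nAnalyzed) sum(sizes != 0L) / nAnalyzed
                      else NA_real_)
}

#' Write an IndelSummary as TSV
#'
#' Writes a two-part export: summary metrics and the per-size histogram.
#'
#' @param summary An \link{IndelSummary}.
#' @param summaryPath,histogramPath Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
writeIndelSummary <- function(summary, summaryPath, histogramPath) {
  s <- data.frame(
    metric = c("n_input", "n_excluded_no_flank", "n_excluded_quality",
               "n_analyzed", "indel_fraction"),
    value = c(summary@nInput, summary@nExcludedNoFlank,
              summary@nExcludedQuality, sum(summary@histogram),
              summary@indelFraction))
  write.table(s, summaryPath, sep = "\t", quote = FALSE, row.names = FALSE)
  h <- data.frame(indel_size = names(summary@histogram),
                  count = as.integer(summary@histogram))
  write.table(h, histogramPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(summaryPath, histogramPath))
}
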