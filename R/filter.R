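# Read filtering and equal-depth subsetting, the preprocessing contract
# applied before any site discovery or RPM comparison.

#' Filter paired-end alignments
#'
#' Applies, in order: mapping-quality filter (pair MAPQ = min over mates,
#' removed when below \code{minMapq}), singleton removal, and PCR-duplicate
#' removal. A duplicate is a pair with an identical (chrom, start1, strand1,
#' start2, strand2) signature to an earlier pair; the first-seen pair is
#' kept. The removal report is attached to the result's metadata and the
#' operation is idempotent.
#'
#' @param aln An \link{AlignmentSet}.
#' @param minMapq Minimum retained mapping quality (default 25; a pair with
#'   MAPQ 24 is removed, 25 retained).
#' @return A filtered \link{AlignmentSet}; \code{alnMeta(x)$filterReport}
#'   holds counts removed per reason.
#' @export
filterAlignments <- function(aln, minMapq = 25L) {
  p <- pairRecords(aln)
  nInput <- nrow(p)
  lowMapq <- p$mapq < minMapq
  p <- p[!lowMapq, , drop = FALSE]
  singleton <- p$isSingleton
  p <- p[!singleton, , drop = FALSE]
  sig <- paste(p$chrom, p$start1, p$strand1, p$start2, p$strand2, sep = ":")
  dup <- duplicated(sig)
  p <- p[!dup, , drop = FALSE]
  report <- list(nInput = nInput, nLowMapq = sum(lowMapq),
                 nSingleton = sum(singleton), nDuplicate = sum(dup),
                 nRetained = nrow(p), minMapq = as.integer(minMapq))
  meta <- alnMeta(aln)
  meta$filterReport <- report
  .AlignmentSet(p, aln@seqlengths, label = aln@label, meta = meta)
}

#' Write a filter report as TSV
#'
#' @param aln A filtered \link{AlignmentSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFilterReport <- function(aln, path) {
  rep <- alnMeta(aln)$filterReport
  if (is.null(rep)) stop("AlignmentSet carries no filter report")
  df <- data.frame(metric = names(rep), value = unlist(rep, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset samples to equal sequencing depth
#'
#' Ensures fair comparison between samples by uniform random pair subsetting
#' (without replacement) down to the smallest retained pair count across the
#' inputs, mirroring the equal-read normalization applied before comparing
#' inhibited and uninhibited libraries. Samples already at the minimum are
#' returned unchanged.
#'
#' @param samples List of filtered \link{AlignmentSet}s (at least 2, all
#'   non-empty).
#' @param seed RNG seed; subsetting is deterministic under it.
#' @return List of \link{AlignmentSet}s, all with equal \code{totalReads}.
#' @export
subsampleEqualDepth <- function(samples, seed) {
  if (length(samples) < 2L) stop("need at least two samples")
  np <- vapply(samples, nPairs, integer(1))
  if (any(np == 0L)) stop("all samples must be non-empty")
  target <- min(np)
  withSeed(seed, {
    lapply(samples, function(s) {
      if (nPairs(s) == target) return(s)
      keep <- sort(sample.int(nPairs(s), target))
      meta <- alnMeta(s)
      meta$subsampledFrom <- nPairs(s)
      .AlignmentSet(pairRecords(s)[keep, , drop = FALSE], s@seqlengths,
                    label = s@label, meta = meta)
    })
  })
}
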