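# RPM enrichment in fixed windows around cut sites, offset background
# quantification, and coverage-track export.

# 0-based alignment starts of every retained mate on a chromosome.
.readStarts <- function(aln, chrom) {
  p <- pairRecords(aln)
  p <- p[p$chrom == chrom, , drop = FALSE]
  c(p$start1, p$start2[!is.na(p$start2)])
}

#' Reads per million in a window around a position
#'
#' Counts reads (each mate separately) whose alignment start lies in the
#' half-open window \code{[pos - window/2, pos + window/2)} and scales by
#' 1e6 over the sample's total retained reads. The window is clipped
#' silently at chromosome edges.
#'
#' @param aln A filtered \link{AlignmentSet} with \code{totalReads > 0}.
#' @param chrom Chromosome name.
#' @param pos 0-based center position (typically a cut site).
#' @param window Window width in bases (default 1500: the 1.5-kb enrichment
#'   window centered at the cut site).
#' @return RPM value (numeric).
#' @export
rpmWindow <- function(aln, chrom, pos, window = 1500L) {
  if (totalReads(aln) == 0L) stop("totalReads is 0; RPM undefined")
  if (!chrom %in% names(aln@seqlengths)) stop("unknown chromosome: ", chrom)
  half <- window / 2
  starts <- .readStarts(aln, chrom)
  count <- sum(starts >= pos - half & starts < pos + half)
  count * 1e6 / totalReads(aln)
}

#' Background RPM at an offset from a cut site
#'
#' Evaluates \link{rpmWindow} at \code{cut + offset} (downstream in reference
#' orientation) to measure background enrichment adjacent to a cut site. If
#' the offset window would fall off the chromosome, the upstream position
#' \code{cut - offset} is used instead and flagged.
#'
#' @param aln A filtered \link{AlignmentSet}.
#' @param chrom Chromosome of the site.
#' @param cut 0-based cut position.
#' @param offset Offset in bases (default 10000: background is measured 10 kb
#'   from the cut).
#' @param window Window width (default 1500).
#' @return RPM value with attributes \code{position} (the evaluated center)
#'   and \code{fallback} (TRUE if the upstream position was used); \code{NA}
#'   with attribute \code{reason} if both offsets are out of range.
#' @export
backgroundRpm <- function(aln, chrom, cut, offset = 10000L, window = 1500L) {
  clen <- aln@seqlengths[[chrom]]
  half <- window / 2
  inRange <- function(p) p - half >= 0 && p + half <= clen
  pos <- cut + offset
  fallback <- FALSE
  if (!inRange(pos)) {
    pos <- cut - offset
    fallback <- TRUE
    if (!inRange(pos)) {
      out <- NA_real_
      attr(out, "reason") <- "both offset positions out of chromosome range"
      return(out)
    }
  }
  out <- rpmWindow(aln, chrom, pos, window)
  attr(out, "position") <- pos
  attr(out, "fallback") <- fallback
  out
}

#' Per-base coverage track for a region
#'
#' Run-length-encoded per-base read coverage (each retained mate contributes
#' its aligned interval), as 0-based half-open bedGraph intervals. Zero
#' coverage runs are omitted; an empty region yields zero rows.
#'
#' @param aln An \link{AlignmentSet}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open region; \code{start < end} required.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{value}.
#' @export
coverageTrack <- function(aln, chrom, start, end) {
  if (start >= end) stop("inverted range: start must be < end")
  clen <- aln@seqlengths[[chrom]]
  p <- pairRecords(aln)
  p <- p[p$chrom == chrom, , drop = FALSE]
  starts <- c(p$start1, p$start2[!is.na(p$start2)])
  rlens <- c(p$rlen, p$rlen[!is.na(p$start2)])
  keep <- starts < end & (starts + rlens) > start
  starts <- starts[keep]; rlens <- rlens[keep]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = integer(),
                      stringsAsFactors = FALSE)
  if (!length(starts)) return(empty)
  cov <- IRanges::coverage(IRanges::IRanges(start = starts + 1L,
                                            width = rlens), width = clen)
  win <- S4Vectors::window(cov, start = start + 1L, end = min(end, clen))
  rl <- S4Vectors::runLength(win)
  rv <- S4Vectors::runValue(win)
  runStart <- start + c(0L, cumsum(rl[-length(rl)]))
  out <- data.frame(chrom = chrom, start = runStart,
                    end = runStart + rl, value = rv,
                    stringsAsFactors = FALSE)
  out <- out[out$value > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track data.frame from \link{coverageTrack}.
#' @param path Output path.
#' @param trackline Optional bedGraph track line (character) or \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path, trackline = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trackline)) writeLines(trackline, con)
  if (nrow(track))
    writeLines(sprintf("%s\t%d\t%d\t%d", track$chrom, track$start,
                       track$end, track$value), con)
  invisible(path)
}

#' Paired enrichment records for a site table
#'
#' For each site, RPM in the window around the cut in both samples plus
#' background RPM at the offset position, the quantities plotted as paired
#' inhibited-vs-no-drug enrichment and offset-background scatter data.
#'
#' @param sites Site table (columns \code{chrom}, \code{cut}).
#' @param alnInhibited,alnNoDrug Equal-depth filtered \link{AlignmentSet}s.
#' @param window RPM window (default 1500).
#' @param offset Background offset (default 10000).
#' @return data.frame with per-site \code{rpmInhibited}, \code{rpmNoDrug},
#'   \code{rpmBgInhibited}, \code{rpmBgNoDrug}.
#' @export
enrichmentRecords <- function(sites, alnInhibited, alnNoDrug,
                              window = 1500L, offset = 10000L) {
  if (totalReads(alnInhibited) != totalReads(alnNoDrug))
    warning("samples are not depth-matched; RPM comparison may be biased")
  n <- nrow(sites)
  siteRpm <- function(aln) vapply(seq_len(n), function(i)
    rpmWindow(aln, sites$chrom[i], sites$cut[i], window), numeric(1))
  bgRpm <- function(aln) vapply(seq_len(n), function(i)
    as.numeric(backgroundRpm(aln, sites$chrom[i], sites$cut[i],
                             offset = offset, window = window)), numeric(1))
  data.frame(chrom = sites$chrom, cut = sites$cut,
             nMismatch = if ("nMismatch" %in% names(sites)) sites$nMismatch
                         else NA_integer_,
             rpmInhibited = siteRpm(alnInhibited),
             rpmNoDrug = siteRpm(alnNoDrug),
             rpmBgInhibited = bgRpm(alnInhibited),
             rpmBgNoDrug = bgRpm(alnNoDrug),
             stringsAsFactors = FALSE)
}
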