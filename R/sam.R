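# SAM emission and ingestion. The simulator emits already-aligned records
# (alignment itself is upstream of this package); Rsamtools does the parsing
# on the way back in.

#' Write an AlignmentSet as SAM
#'
#' Emits SAM 1.6 with an @SQ header per chromosome; 1-based POS, proper-pair
#' flags for intact pairs, mate-unmapped flags for singletons, per-record
#' MAPQ, simple <readLen>M CIGARs and omitted SEQ/QUAL ("*"). Output is
#' byte-identical for identical inputs.
#'
#' @param aln An \link{AlignmentSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(aln, path) {
  p <- pairRecords(aln)
  sl <- aln@seqlengths
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  lines <- character(0)
  if (nrow(p)) {
    cig <- paste0(p$rlen, "M")
    pairRows <- !p$isSingleton
    if (any(pairRows)) {
      pp <- p[pairRows, , drop = FALSE]
      c1 <- paste0(pp$rlen, "M")
      f1 <- 1L + 2L + 64L + ifelse(pp$strand1 == "-", 16L, 0L) +
        ifelse(pp$strand2 == "-", 32L, 0L)
      f2 <- 1L + 2L + 128L + ifelse(pp$strand2 == "-", 16L, 0L) +
        ifelse(pp$strand1 == "-", 32L, 0L)
      span <- pmax(pp$start1 + pp$rlen, pp$start2 + pp$rlen) -
        pmin(pp$start1, pp$start2)
      t1 <- ifelse(pp$start1 <= pp$start2, span, -span)
      l1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                    pp$qname, f1, pp$chrom, pp$start1 + 1L, pp$mapq, c1,
                    pp$start2 + 1L, t1)
      l2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                    pp$qname, f2, pp$chrom, pp$start2 + 1L, pp$mapq, c1,
                    pp$start1 + 1L, -t1)
      lines <- c(lines, as.vector(rbind(l1, l2)))
    }
    if (any(p$isSingleton)) {
      ps <- p[p$isSingleton, , drop = FALSE]
      fs <- 1L + 8L + 64L + ifelse(ps$strand1 == "-", 16L, 0L)
      ls <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                    ps$qname, fs, ps$chrom, ps$start1 + 1L, ps$mapq,
                    paste0(ps$rlen, "M"))
      lines <- c(lines, ls)
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read paired-end alignments from SAM/BAM
#'
#' Parses via \pkg{Rsamtools} (SAM input is converted to BAM in a temporary
#' file first), pairs mates by query name, flags mate-less reads as
#' singletons, and converts coordinates to the package's internal 0-based
#' convention. A pair's MAPQ is the minimum over its mates. Records on
#' chromosomes absent from \code{genome} are a hard error naming the record;
#' malformed files are rejected outright by the parser (no per-record
#' skipping).
#'
#' @param path SAM or BAM file.
#' @param genome A \link{GenomeRef} providing the coordinate authority.
#' @param label Sample label (default: file base name).
#' @return An \link{AlignmentSet}.
#' @export
readAlignments <- function(path, genome, label = NULL) {
  stopifnot(is(genome, "GenomeRef"))
  if (is.null(label))
    label <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    dest <- tempfile(fileext = "")
    tryCatch(Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                              indexDestination = FALSE),
             error = function(e) stop("failed to parse SAM at ", path, ": ",
                                      conditionMessage(e)))
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "mapq",
               "cigar")))[[1]]
  lens <- chromLengths(genome)
  n <- length(res$qname)
  if (n == 0L) {
    empty <- data.frame(qname = character(), chrom = character(),
                        start1 = integer(), strand1 = character(),
                        start2 = integer(), strand2 = character(),
                        rlen = integer(), mapq = integer(),
                        isSingleton = logical(), stringsAsFactors = FALSE)
    return(.AlignmentSet(empty, lens, label = label))
  }
  chrom <- as.character(res$rname)
  bad <- which(!chrom %in% names(lens))
  if (length(bad))
    stop("record '", res$qname[bad[1]], "' on unknown chromosome '",
         chrom[bad[1]], "'")
  reads <- data.frame(
    qname = res$qname, flag = res$flag, chrom = chrom,
    strand = as.character(res$strand), start = res$pos - 1L,
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    rlen = cigarRefWidth(res$cigar), stringsAsFactors = FALSE)
  reads$isFirst <- bitwAnd(reads$flag, 64L) > 0L
  reads$mateUnmapped <- bitwAnd(reads$flag, 8L) > 0L

  firsts <- reads[reads$isFirst | bitwAnd(reads$flag, 192L) == 0L, ,
                  drop = FALSE]
  seconds <- reads[bitwAnd(reads$flag, 128L) > 0L, , drop = FALSE]
  idx2 <- match(firsts$qname, seconds$qname)
  hasMate <- !is.na(idx2) & !firsts$mateUnmapped
  mate <- seconds[idx2, , drop = FALSE]
  pairs <- data.frame(
    qname = firsts$qname, chrom = firsts$chrom, start1 = firsts$start,
    strand1 = firsts$strand,
    start2 = ifelse(hasMate, mate$start, NA_integer_),
    strand2 = ifelse(hasMate, mate$strand, NA_character_),
    rlen = firsts$rlen,
    mapq = ifelse(hasMate, pmin(firsts$mapq, mate$mapq), firsts$mapq),
    isSingleton = !hasMate, stringsAsFactors = FALSE)
  # second-of-pair reads whose first mate is absent become singletons too
  loneSecond <- seconds[!seconds$qname %in% firsts$qname, , drop = FALSE]
  if (nrow(loneSecond)) {
    pairs <- rbind(pairs, data.frame(
      qname = loneSecond$qname, chrom = loneSecond$chrom,
      start1 = loneSecond$start, strand1 = loneSecond$strand,
      start2 = NA_integer_, strand2 = NA_character_, rlen = loneSecond$rlen,
      mapq = loneSecond$mapq, isSingleton = TRUE, stringsAsFactors = FALSE))
  }
  .AlignmentSet(pairs, lens, label = label)
}
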