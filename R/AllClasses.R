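#' @import methods
#' @importFrom stats rnorm rpois runif setNames sd
#' @importFrom utils head write.table read.delim
NULL

#' GenomeRef: a reference genome for the toy workflow
#'
#' Thin wrapper around a named \link[Biostrings]{DNAStringSet} holding one
#' sequence per chromosome. All coordinates in the package are 0-based
#' half-open internally; SAM/TSV emission converts to 1-based.
#'
#' @slot seqs A named \code{DNAStringSet}; names are chromosome names.
#' @export
setClass("GenomeRef", representation(seqs = "DNAStringSet"))

setValidity("GenomeRef", function(object) {
  nm <- names(object@seqs)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("chromosome names must be unique and non-empty")
  freq <- Biostrings::alphabetFrequency(object@seqs, baseOnly = TRUE)
  if (length(object@seqs) && any(freq[, "other"] > 0))
    return("sequences may contain only A/C/G/T")
  TRUE
})

#' @describeIn GenomeRef-class Chromosome names.
#' @param x,object A \code{GenomeRef}.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeRef-class
#' @export
setMethod("chromNames", "GenomeRef", function(x) names(x@seqs))

#' @describeIn GenomeRef-class Named integer vector of chromosome lengths.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeRef-class
#' @export
setMethod("chromLengths", "GenomeRef",
          function(x) setNames(Biostrings::width(x@seqs), names(x@seqs)))

#' @describeIn GenomeRef-class Total genome length in bases.
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname GenomeRef-class
#' @export
setMethod("totalLength", "GenomeRef", function(x) sum(chromLengths(x)))

#' @describeIn GenomeRef-class Underlying \code{DNAStringSet}.
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))

#' @rdname GenomeRef-class
#' @export
setMethod("genomeSeqs", "GenomeRef", function(x) x@seqs)

setMethod("show", "GenomeRef", function(object) {
  cat("GenomeRef with", length(object@seqs), "chromosome(s),",
      totalLength(object), "bp total\n")
  for (nm in head(names(object@seqs), 5))
    cat("  ", nm, ": ", Biostrings::width(object@seqs[nm]), " bp\n", sep = "")
})

#' GuideSpec: a guide RNA / nuclease specification
#'
#' @slot name Guide name.
#' @slot protospacer Protospacer sequence, 5'->3' (20 nt for Cas9; 20-23 nt
#'   for Cas12a).
#' @slot nuclease "cas9" (3' NGG PAM) or "cas12a" (5' TTTV PAM).
#' @slot pam PAM rule string, "NGG", "NAG" (accept both NGG and NAG) or "TTTV".
#' @slot maxMismatch Maximum Hamming distance for a reported site.
#' @export
setClass("GuideSpec", representation(
  name = "character", protospacer = "character",
  nuclease = "character", pam = "character", maxMismatch = "integer"))

setValidity("GuideSpec", function(object) {
  p <- object@protospacer
  if (length(p) != 1L || !grepl("^[ACGT]+$", p))
    return("protospacer must be a single A/C/G/T string")
  if (!object@nuclease %in% c("cas9", "cas12a"))
    return("nuclease must be 'cas9' or 'cas12a'")
  if (object@maxMismatch >= nchar(p))
    return("maxMismatch must be < protospacer length")
  if (object@maxMismatch < 0L) return("maxMismatch must be >= 0")
  TRUE
})

#' Construct a GuideSpec
#'
#' @param name Guide name.
#' @param protospacer Protospacer sequence (5'->3').
#' @param nuclease "cas9" or "cas12a".
#' @param pam PAM rule; defaults to "NGG" for Cas9 and "TTTV" for Cas12a.
#' @param maxMismatch Maximum mismatches for site reporting (default 6).
#' @return A \code{GuideSpec}.
#' @export
GuideSpec <- function(name, protospacer, nuclease = c("cas9", "cas12a"),
                      pam = NULL, maxMismatch = 6L) {
  nuclease <- match.arg(nuclease)
  if (is.null(pam)) pam <- if (nuclease == "cas9") "NGG" else "TTTV"
  new("GuideSpec", name = name, protospacer = toupper(protospacer),
      nuclease = nuclease, pam = pam, maxMismatch = as.integer(maxMismatch))
}

setMethod("show", "GuideSpec", function(object) {
  cat("GuideSpec '", object@name, "': ", object@protospacer, " (",
      object@nuclease, ", PAM ", object@pam, ", <=", object@maxMismatch,
      " mismatches)\n", sep = "")
})

#' SimConfig: knobs for the MRE11 ChIP-seq-style read simulator
#'
#' @slot lambda0 Expected site-bound fragment pairs at efficiency 1 without
#'   DNA-PKcs inhibition.
#' @slot residenceMultiplier Multiplier (>= 1) on site-bound pair counts under
#'   DNA-PKcs inhibition (prolonged MRE11 residence).
#' @slot fragLenMin,fragLenMax Fragment length bounds (bp); must allow two
#'   non-overlapping reads (fragLenMin >= 2 * readLen).
#' @slot endSigma SD (bp) of the cut-proximal fragment end around the cut.
#' @slot readLen Read length (bp), default 36.
#' @slot bgPairs Number of uniform background fragment pairs.
#' @slot dupRate,lowmapqRate,orphanRate PCR-duplicate, low-MAPQ and singleton
#'   fractions, each in [0,1].
#' @slot seed RNG seed.
#' @export
setClass("SimConfig", representation(
  lambda0 = "numeric", residenceMultiplier = "numeric",
  fragLenMin = "integer", fragLenMax = "integer", endSigma = "numeric",
  readLen = "integer", bgPairs = "integer", dupRate = "numeric",
  lowmapqRate = "numeric", orphanRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  r <- c(object@dupRate, object@lowmapqRate, object@orphanRate)
  if (any(r < 0) || any(r > 1)) return("rates must be in [0,1]")
  if (object@residenceMultiplier < 1) return("residenceMultiplier must be >= 1")
  if (object@fragLenMin < 2L * object@readLen)
    return("fragLenMin must be >= 2 * readLen")
  if (object@fragLenMax < object@fragLenMin)
    return("fragLenMax must be >= fragLenMin")
  if (object@lambda0 <= 0) return("lambda0 must be positive")
  if (object@endSigma < 0) return("endSigma must be >= 0")
  if (object@bgPairs < 0L) return("bgPairs must be >= 0")
  TRUE
})

#' Construct a SimConfig
#'
#' Defaults give the package's desk-scale study conditions: fragment lengths
#' 150-400 bp with cut-proximal ends jittered by sd 25 bp, 2 x 36 bp reads,
#' site-bound pair mean \code{lambda0 = 50} per unit efficiency, a fivefold
#' residence multiplier under DNA-PKcs inhibition, and 400 uniform background
#' pairs on the default 2 Mb toy genome.
#'
#' @param lambda0,residenceMultiplier,fragLenMin,fragLenMax,endSigma,readLen,bgPairs,dupRate,lowmapqRate,orphanRate,seed
#'   See the class slots.
#' @return A \code{SimConfig}.
#' @export
SimConfig <- function(lambda0 = 50, residenceMultiplier = 5,
                      fragLenMin = 150L, fragLenMax = 400L, endSigma = 25,
                      readLen = 36L, bgPairs = 400L, dupRate = 0.05,
                      lowmapqRate = 0.05, orphanRate = 0.02, seed = 1L) {
  new("SimConfig", lambda0 = lambda0, residenceMultiplier = residenceMultiplier,
      fragLenMin = as.integer(fragLenMin), fragLenMax = as.integer(fragLenMax),
      endSigma = endSigma, readLen = as.integer(readLen),
      bgPairs = as.integer(bgPairs), dupRate = dupRate,
      lowmapqRate = lowmapqRate, orphanRate = orphanRate,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: lambda0=", object@lambda0, ", multiplier=",
      object@residenceMultiplier, ", frags [", object@fragLenMin, ",",
      object@fragLenMax, "] bp, endSigma=", object@endSigma, ", readLen=",
      object@readLen, ", bgPairs=", object@bgPairs, ", seed=", object@seed,
      "\n", sep = "")
})

#' AlignmentSet: a collection of paired-end alignment records
#'
#' Pair-level records: each row of \code{pairs} is one read pair (or a
#' singleton). Columns: \code{qname}, \code{chrom}, \code{start1},
#' \code{strand1}, \code{start2}, \code{strand2} (NA for singletons),
#' \code{rlen} (read length), \code{mapq} (min over mates),
#' \code{isSingleton}, and optionally \code{origin} (simulator provenance:
#' "bg", "site<i>", with ".dup" suffix for PCR-duplicate copies).
#'
#' @slot pairs data.frame of pair records (0-based starts).
#' @slot seqlengths Named integer vector of chromosome lengths.
#' @slot label Sample label.
#' @slot totalReads Retained read count (2 per proper pair, 1 per singleton);
#'   the RPM denominator basis.
#' @slot meta List: simulator ground-truth ledger, filter report, etc.
#' @export
setClass("AlignmentSet", representation(
  pairs = "data.frame", seqlengths = "integer", label = "character",
  totalReads = "integer", meta = "list"))

setValidity("AlignmentSet", function(object) {
  need <- c("qname", "chrom", "start1", "strand1", "start2", "strand2",
            "rlen", "mapq", "isSingleton")
  if (!all(need %in% names(object@pairs)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@pairs)) {
    if (!all(object@pairs$chrom %in% names(object@seqlengths)))
      return("pair records on chromosomes absent from seqlengths")
    if (any(object@pairs$mapq < 0, na.rm = TRUE)) return("mapq must be >= 0")
    expect <- 2L * sum(!object@pairs$isSingleton) + sum(object@pairs$isSingleton)
    if (object@totalReads != expect)
      return("totalReads inconsistent with pair records")
  } else if (object@totalReads != 0L) {
    return("totalReads must be 0 for an empty set")
  }
  TRUE
})

.AlignmentSet <- function(pairs, seqlengths, label = "sample", meta = list()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  total <- if (nrow(pairs)) {
    2L * sum(!pairs$isSingleton) + sum(pairs$isSingleton)
  } else 0L
  new("AlignmentSet", pairs = pairs,
      seqlengths = setNames(as.integer(seqlengths), names(seqlengths)),
      label = label, totalReads = as.integer(total), meta = meta)
}

#' @describeIn AlignmentSet-class Pair-level records as a data.frame.
#' @param x,object An \code{AlignmentSet}.
#' @export
setGeneric("pairRecords", function(x) standardGeneric("pairRecords"))

#' @rdname AlignmentSet-class
#' @export
setMethod("pairRecords", "AlignmentSet", function(x) x@pairs)

#' @describeIn AlignmentSet-class Retained read count (the RPM denominator basis).
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname AlignmentSet-class
#' @export
setMethod("totalReads", "AlignmentSet", function(x) x@totalReads)

#' @describeIn AlignmentSet-class Number of pair records.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname AlignmentSet-class
#' @export
setMethod("nPairs", "AlignmentSet", function(x) nrow(x@pairs))

#' @describeIn AlignmentSet-class Sample label.
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname AlignmentSet-class
#' @export
setMethod("sampleLabel", "AlignmentSet", function(x) x@label)

#' @describeIn AlignmentSet-class Metadata list (simulator ledger, filter report).
#' @export
setGeneric("alnMeta", function(x) standardGeneric("alnMeta"))

#' @rdname AlignmentSet-class
#' @export
setMethod("alnMeta", "AlignmentSet", function(x) x@meta)

setMethod("show", "AlignmentSet", function(object) {
  cat("AlignmentSet '", object@label, "': ", nrow(object@pairs),
      " pair record(s), ", object@totalReads, " reads, ",
      length(object@seqlengths), " chromosome(s)\n", sep = "")
  if (!is.null(object@meta$condition))
    cat("  simulated condition:", object@meta$condition, "\n")
  if (!is.null(object@meta$filterReport))
    cat("  filtered: ", object@meta$filterReport$nRetained, "/",
        object@meta$filterReport$nInput, " pairs retained\n", sep = "")
})

#' AmpliconSpec: flank-anchored amplicon reference for indel calling
#'
#' Reads are classified by exact matches to two 20-bp anchor sequences located
#' 20 bp outside the ends of the gRNA target sequence; an indel is a
#' flank-to-flank segment whose length differs from the reference.
#'
#' @slot refSeq Amplicon reference sequence.
#' @slot targetStart,targetEnd 0-based half-open span of the target sequence.
#' @slot leftFlank,rightFlank The two 20-bp anchors.
#' @slot innerRefLen Reference distance (bp) between the flank inner edges.
#' @export
setClass("AmpliconSpec", representation(
  refSeq = "character", targetStart = "integer", targetEnd = "integer",
  leftFlank = "character", rightFlank = "character", innerRefLen = "integer"))

setValidity("AmpliconSpec", function(object) {
  if (nchar(object@leftFlank) != 20L || nchar(object@rightFlank) != 20L)
    return("flanks must be 20 bp")
  for (fl in c(left = object@leftFlank, right = object@rightFlank)) {
    n <- length(gregexpr(fl, object@refSeq, fixed = TRUE)[[1]])
    if (n != 1L || gregexpr(fl, object@refSeq, fixed = TRUE)[[1]][1] == -1L)
      return("each flank must occur exactly once in refSeq")
  }
  if (object@innerRefLen != object@targetEnd - object@targetStart + 40L)
    return("innerRefLen inconsistent with target span")
  TRUE
})

setMethod("show", "AmpliconSpec", function(object) {
  cat("AmpliconSpec: ", nchar(object@refSeq), " bp reference, target [",
      object@targetStart, ",", object@targetEnd, "), inner length ",
      object@innerRefLen, " bp\n", sep = "")
})

#' IndelSummary: per-amplicon indel-size histogram
#'
#' @slot nInput Number of input reads.
#' @slot nExcludedNoFlank Reads without unique exact matches to both flanks.
#' @slot nExcludedQuality Reads failing the mean-quality > threshold filter.
#' @slot histogram Named integer vector, names are signed indel sizes
#'   ("0" = no mutation).
#' @slot indelFraction (reads with size != 0) / analyzed reads.
#' @export
setClass("IndelSummary", representation(
  nInput = "integer", nExcludedNoFlank = "integer",
  nExcludedQuality = "integer", histogram = "integer",
  indelFraction = "numeric"))

setValidity("IndelSummary", function(object) {
  if (object@nInput !=
      object@nExcludedNoFlank + object@nExcludedQuality + sum(object@histogram))
    return("exclusions + histogram counts must sum to nInput")
  if (!is.na(object@indelFraction) &&
      (object@indelFraction < 0 || object@indelFraction > 1))
    return("indelFraction must be in [0,1]")
  TRUE
})

setMethod("show", "IndelSummary", function(object) {
  n <- sum(object@histogram)
  cat("IndelSummary: ", object@nInput, " reads (",
      object@nExcludedNoFlank, " no-flank, ", object@nExcludedQuality,
      " low-quality excluded), ", n, " analyzed\n", sep = "")
  cat("  indel fraction: ",
      if (is.na(object@indelFraction)) "NA" else
        sprintf("%.4f", object@indelFraction), "\n", sep = "")
  if (length(object@histogram)) {
    cat("  sizes:\n")
    print(object@histogram)
  }
})

#' @describeIn IndelSummary-class Indel-size histogram (named by signed size).
#' @param x,object An \code{IndelSummary}.
#' @export
setGeneric("indelHistogram", function(x) standardGeneric("indelHistogram"))

#' @rdname IndelSummary-class
#' @export
setMethod("indelHistogram", "IndelSummary", function(x) x@histogram)

#' @describeIn IndelSummary-class Fraction of analyzed reads carrying an indel.
#' @export
setGeneric("indelFraction", function(x) standardGeneric("indelFraction"))

#' @rdname IndelSummary-class
#' @export
setMethod("indelFraction", "IndelSummary", function(x) x@indelFraction)
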