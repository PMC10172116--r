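# Toy genome construction and planting of on/off-target protospacers.

#' Generate a random reference genome
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T; the generator is a
#' synthetic stand-in for a real reference assembly so that discovery can be
#' scored against planted ground truth.
#'
#' @param nChroms Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths (bp); length must equal
#'   \code{nChroms}.
#' @param seed RNG seed; identical seeds give byte-identical genomes.
#' @return A \link{GenomeRef}.
#' @examples
#' g <- makeGenome(1, 1000, seed = 7)
#' totalLength(g)
#' @export
makeGenome <- function(nChroms, lengths, seed) {
  lengths <- as.integer(lengths)
  if (length(lengths) != nChroms)
    stop("lengths must have one entry per chromosome")
  if (any(lengths <= 0L)) stop("chromosome lengths must be positive")
  seqs <- withSeed(seed, {
    vapply(lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(nChroms))
  new("GenomeRef", seqs = Biostrings::DNAStringSet(seqs))
}

#' Write a GenomeRef as FASTA
#'
#' @param genome A \link{GenomeRef}.
#' @param path Output path; 60-column wrapped FASTA.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genomeSeqs(genome), path, width = 60L)
  invisible(path)
}

# --- nuclease geometry ------------------------------------------------------
# A cut is a single genomic coordinate. Cas9 cuts blunt 3 bp 5' of the PAM
# (between protospacer positions 17 and 18 of a 20-mer); Cas12a is summarized
# by one coordinate 18 bp from the PAM-proximal protospacer end (the staggered
# overhang is not modeled). `protoStart` is the 0-based leftmost genomic
# coordinate of the protospacer footprint.
cutPosition <- function(protoStart, protoLen, strand, nuclease) {
  if (nuclease == "cas9") {
    ifelse(strand == "+", protoStart + protoLen - 3L, protoStart + 3L)
  } else {
    ifelse(strand == "+", protoStart + 18L, protoStart + protoLen - 18L)
  }
}

# Genomic footprint [start, end) of the PAM for a protospacer placement.
pamFootprint <- function(protoStart, protoLen, strand, nuclease, pamLen) {
  if (nuclease == "cas9") {
    if (strand == "+") c(protoStart + protoLen, protoStart + protoLen + pamLen)
    else c(protoStart - pamLen, protoStart)
  } else {
    if (strand == "+") c(protoStart - pamLen, protoStart)
    else c(protoStart + protoLen, protoStart + protoLen + pamLen)
  }
}

.iupacComp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D")

iupacRevcomp <- function(pattern) {
  paste(rev(.iupacComp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# Draw one concrete PAM sequence satisfying an IUPAC rule.
samplePam <- function(pamRule) {
  paste(vapply(strsplit(pamRule, "")[[1]], function(ch) {
    opts <- .iupac[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Plant on/off-target protospacers into a genome
#'
#' Overwrites the genome sequence at each requested position with the guide
#' protospacer carrying the requested number of mismatches (substitutions at
#' randomly chosen positions, never equal to the guide base) plus a concrete
#' PAM satisfying the guide's PAM rule, and records full ground truth. The
#' returned mismatch counts are verified by recomputing the Hamming distance
#' from the modified genome.
#'
#' @param genome A \link{GenomeRef}.
#' @param guide A \link{GuideSpec}.
#' @param requests data.frame with columns \code{chrom}, \code{position}
#'   (0-based protospacer start), \code{strand} ("+"/"-"), \code{nMismatch},
#'   \code{efficiency} (relative MRE11 recruitment propensity in (0,1]).
#' @param seed RNG seed for mismatch placement and PAM sampling.
#' @return A list with \code{genome} (modified \code{GenomeRef}) and
#'   \code{sites}, a data.frame of planted sites: \code{chrom}, \code{cutPos},
#'   \code{strand}, \code{protospacer} (as planted, guide orientation),
#'   \code{pam}, \code{nMismatch}, \code{efficiency}, \code{protoStart}.
#' @export
plantSites <- function(genome, guide, requests, seed) {
  stopifnot(is(genome, "GenomeRef"), is(guide, "GuideSpec"))
  req <- as.data.frame(requests, stringsAsFactors = FALSE)
  need <- c("chrom", "position", "strand", "nMismatch", "efficiency")
  if (!all(need %in% names(req)))
    stop("requests must have columns: ", paste(need, collapse = ", "))
  g <- guide@protospacer
  L <- nchar(g)
  pamLen <- nchar(guide@pam)
  lens <- chromLengths(genome)
  if (any(!req$chrom %in% names(lens))) stop("unknown chromosome in requests")
  if (any(req$nMismatch > L)) stop("nMismatch cannot exceed protospacer length")
  if (any(req$efficiency <= 0 | req$efficiency > 1))
    stop("efficiency must be in (0, 1]")

  # footprints (protospacer plus PAM) must be in bounds and non-overlapping
  foot <- t(mapply(function(pos, strand) {
    pf <- pamFootprint(pos, L, strand, guide@nuclease, pamLen)
    c(min(pos, pf[1]), max(pos + L, pf[2]))
  }, req$position, req$strand))
  if (any(foot[, 1] < 0) || any(foot[, 2] > lens[req$chrom]))
    stop("requested site does not leave room for protospacer plus PAM")
  for (i in seq_len(nrow(req))) for (j in seq_len(nrow(req))) {
    if (i < j && req$chrom[i] == req$chrom[j] &&
        foot[i, 1] < foot[j, 2] && foot[j, 1] < foot[i, 2])
      stop("requested sites overlap")
  }

  seqs <- as.character(genomeSeqs(genome))
  out <- withSeed(seed, {
    sites <- vector("list", nrow(req))
    for (i in seq_len(nrow(req))) {
      nm <- req$nMismatch[i]
      proto <- strsplit(g, "")[[1]]
      if (nm > 0L) {
        at <- sample.int(L, nm)
        for (k in at) {
          proto[k] <- sample(setdiff(c("A", "C", "G", "T"), proto[k]), 1L)
        }
      }
      protoSeq <- paste(proto, collapse = "")
      pamSeq <- samplePam(guide@pam)
      pos <- req$position[i]
      strand <- req$strand[i]
      chrom <- req$chrom[i]
      # genomic characters for the protospacer footprint
      genoProto <- if (strand == "+") protoSeq else revcomp(protoSeq)
      substr(seqs[[chrom]], pos + 1L, pos + L) <- genoProto
      pf <- pamFootprint(pos, L, strand, guide@nuclease, pamLen)
      genoPam <- if (strand == "+") pamSeq else revcomp(pamSeq)
      substr(seqs[[chrom]], pf[1] + 1L, pf[2]) <- genoPam
      sites[[i]] <- data.frame(
        chrom = chrom,
        cutPos = cutPosition(pos, L, strand, guide@nuclease),
        strand = strand, protospacer = protoSeq, pam = pamSeq,
        nMismatch = nm, efficiency = req$efficiency[i], protoStart = pos,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, sites)
  })

  newGenome <- new("GenomeRef", seqs = Biostrings::DNAStringSet(seqs))
  # verify planted mismatch counts by recomputing Hamming distance
  for (i in seq_len(nrow(out))) {
    found <- substr(as.character(genomeSeqs(newGenome)[[out$chrom[i]]]),
                    out$protoStart[i] + 1L, out$protoStart[i] + L)
    if (out$strand[i] == "-") found <- revcomp(found)
    if (countMismatches(found, g) != out$nMismatch[i])
      stop("internal error: planted mismatch count failed verification")
  }
  list(genome = newGenome, sites = out)
}

#' Write planted ground-truth sites as BED
#'
#' BED6+ (0-based half-open, single-base cut intervals) with the planted
#' protospacer, PAM, mismatch count and efficiency in extra columns.
#'
#' @param sites Planted-site data.frame from \link{plantSites}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePlantedBed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$cutPos,
                    end = sites$cutPos + 1L,
                    name = paste0("site", seq_len(nrow(sites))),
                    score = sites$nMismatch, strand = sites$strand,
                    protospacer = sites$protospacer, pam = sites$pam,
                    efficiency = sites$efficiency)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
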