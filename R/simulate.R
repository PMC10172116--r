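# Synthetic MRE11 ChIP-seq-style paired-end read simulator and amplicon
# read generator, with full ground-truth provenance for acceptance testing.

# Apply PCR-duplicate / low-MAPQ / orphan artifacts to a fragment table,
# drawing from the current RNG stream. Input columns: chrom, fragStart,
# fragEnd, origin, qname. Returns pair records.
applyArtifacts <- function(frags, cfg) {
  n <- nrow(frags)
  if (n == 0L) {
    return(data.frame(qname = character(), chrom = character(),
                      start1 = integer(), strand1 = character(),
                      start2 = integer(), strand2 = character(),
                      rlen = integer(), mapq = integer(),
                      isSingleton = logical(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  dupSel <- runif(n) < cfg@dupRate
  dups <- frags[dupSel, , drop = FALSE]
  if (nrow(dups)) {
    dups$origin <- paste0(dups$origin, ".dup")
    dups$qname <- paste0(dups$qname, "d")
  }
  all <- rbind(frags, dups)
  n2 <- nrow(all)
  lowSel <- runif(n2) < cfg@lowmapqRate
  mapq <- ifelse(lowSel, as.integer(floor(runif(n2) * 25)), 42L)
  orphanSel <- runif(n2) < cfg@orphanRate
  rl <- cfg@readLen
  data.frame(
    qname = all$qname, chrom = all$chrom,
    start1 = all$fragStart, strand1 = "+",
    start2 = ifelse(orphanSel, NA_integer_, all$fragEnd - rl),
    strand2 = ifelse(orphanSel, NA_character_, "-"),
    rlen = rl, mapq = as.integer(mapq), isSingleton = orphanSel,
    origin = all$origin, stringsAsFactors = FALSE)
}

#' Simulate MRE11 ChIP-seq-like paired-end alignments
#'
#' Emulates the fragment-accumulation signal at nuclease cut sites: for each
#' planted site the number of site-bound fragment pairs is Poisson with mean
#' \code{lambda0 * efficiency * multiplier}, where the residence multiplier
#' applies only under DNA-PKcs inhibition (\code{treated_inhibited}). Each
#' site fragment lies entirely on one side of the cut (equiprobable), with its
#' cut-proximal end at \code{cutPos + |Normal(0, endSigma)|} on that side and
#' uniform length in \code{[fragLenMin, fragLenMax]} extending away from the
#' cut, so that paired-end reads of the fragment ends produce the
#' characteristic two flanking coverage peaks with a dip at the cut itself.
#' Background fragments are uniform genome-wide. PCR-duplicate, low-MAPQ and
#' orphan artifacts are applied last.
#'
#' Background fragments and their artifact flags are drawn from an RNG stream
#' that depends only on \code{cfg@seed}, so background reads are identical
#' across conditions under the same seed (the inhibitor affects only
#' site-bound signal, not background). With \code{residenceMultiplier = 1}
#' the \code{treated_inhibited} output is identical to
#' \code{treated_no_drug}; under \code{no_cas9} site-derived fragments are
#' suppressed entirely.
#'
#' @param genome A \link{GenomeRef}.
#' @param sites Planted-site data.frame from \link{plantSites} (may have zero
#'   rows).
#' @param cfg A \link{SimConfig}.
#' @param condition One of \code{"treated_inhibited"},
#'   \code{"treated_no_drug"}, \code{"no_cas9"}.
#' @param label Sample label; defaults to the condition.
#' @return An \link{AlignmentSet}; \code{alnMeta(x)$ledger} holds the
#'   ground-truth provenance counts.
#' @export
simulateChipReads <- function(genome, sites, cfg,
                              condition = c("treated_inhibited",
                                            "treated_no_drug", "no_cas9"),
                              label = NULL) {
  condition <- match.arg(condition)
  validObject(cfg)
  if (is.null(label)) label <- condition
  lens <- chromLengths(genome)
  if (min(lens) < cfg@fragLenMax)
    stop("all chromosomes must be at least fragLenMax long")
  mult <- if (condition == "treated_inhibited") cfg@residenceMultiplier else 1
  rl <- cfg@readLen

  bg <- withSeed(stageSeed(cfg@seed, "chip_background"), {
    n <- cfg@bgPairs
    chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    Lf <- sample(seq(cfg@fragLenMin, cfg@fragLenMax), n, replace = TRUE)
    start <- as.integer(floor(runif(n) * (lens[chrom] - Lf + 1)))
    frags <- data.frame(chrom = chrom, fragStart = start,
                        fragEnd = start + Lf,
                        origin = rep("bg", n),
                        qname = sprintf("bg%06d", seq_len(n)),
                        stringsAsFactors = FALSE)
    applyArtifacts(frags, cfg)
  })

  siteCounts <- integer(if (is.null(sites)) 0L else nrow(sites))
  sitePairs <- NULL
  if (condition != "no_cas9" && !is.null(sites) && nrow(sites)) {
    sitePairs <- withSeed(stageSeed(cfg@seed, "chip_sites"), {
      frs <- vector("list", nrow(sites))
      for (i in seq_len(nrow(sites))) {
        nI <- rpois(1L, cfg@lambda0 * sites$efficiency[i] * mult)
        siteCounts[i] <- nI
        if (nI == 0L) next
        cut <- sites$cutPos[i]
        chrom <- sites$chrom[i]
        clen <- lens[[chrom]]
        fragStart <- integer(nI)
        fragEnd <- integer(nI)
        todo <- seq_len(nI)
        attempts <- 0L
        while (length(todo)) {
          if (attempts >= 100L)
            stop("fragment resampling exceeded 100 attempts at a chromosome ",
                 "edge; move the site or shorten fragments")
          m <- length(todo)
          left <- runif(m) < 0.5
          z <- as.integer(floor(abs(rnorm(m, 0, cfg@endSigma))))
          Lf <- sample(seq(cfg@fragLenMin, cfg@fragLenMax), m, replace = TRUE)
          st <- ifelse(left, cut - z - Lf, cut + z)
          en <- st + Lf
          ok <- st >= 0L & en <= clen
          fragStart[todo[ok]] <- as.integer(st[ok])
          fragEnd[todo[ok]] <- as.integer(en[ok])
          todo <- todo[!ok]
          attempts <- attempts + 1L
        }
        frs[[i]] <- data.frame(chrom = chrom, fragStart = fragStart,
                               fragEnd = fragEnd, origin = paste0("site", i),
                               stringsAsFactors = FALSE)
      }
      frags <- do.call(rbind, frs)
      if (is.null(frags) || nrow(frags) == 0L) {
        NULL
      } else {
        frags$qname <- sprintf("st%06d", seq_len(nrow(frags)))
        applyArtifacts(frags, cfg)
      }
    })
  }

  pairs <- rbind(bg, sitePairs)
  ledger <- list(
    condition = condition, multiplier = mult,
    nBgPairs = cfg@bgPairs, nSitePairs = siteCounts,
    nDuplicates = sum(grepl("\\.dup$", pairs$origin)),
    nLowMapq = sum(pairs$mapq < 25L),
    nOrphans = sum(pairs$isSingleton),
    nEmittedPairs = nrow(pairs), seed = cfg@seed)
  .AlignmentSet(pairs, lens, label = label,
                meta = list(condition = condition, ledger = ledger))
}

#' Write a simulator provenance ledger as JSON
#'
#' @param aln An \link{AlignmentSet} produced by \link{simulateChipReads}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLedger <- function(aln, path) {
  ledger <- alnMeta(aln)$ledger
  if (is.null(ledger)) stop("AlignmentSet carries no simulator ledger")
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate amplicon sequencing reads with a planted indel spectrum
#'
#' Each read is drawn from the amplicon reference; with probability
#' \code{indelFraction} it carries one indel of a size sampled from
#' \code{sizeDist}, applied at the nuclease cut position (blunt Cas9 geometry,
#' 3 bp inside the 3' end of the target). Insertions add uniform random bases;
#' deletions remove bases centered on the cut. Per-base qualities are
#' Normal(\code{meanQ}, 3) rounded and clamped to [2, 40] (Phred). A fraction
#' \code{flankCorruptRate} of reads receives one substitution inside a flank
#' anchor, which the downstream caller must exclude.
#'
#' @param spec An \link{AmpliconSpec}.
#' @param indelFraction Probability that a read carries an indel, in [0,1].
#' @param sizeDist Named numeric vector of indel-size probabilities; names are
#'   nonzero signed integers (e.g. \code{c("1" = 0.8, "-3" = 0.2)});
#'   probabilities must sum to 1.
#' @param nReads Number of reads.
#' @param readLen Read length (default 151, the amplicon sequencing layout).
#' @param meanQ Mean Phred quality (default 30).
#' @param flankCorruptRate Fraction of reads with one substitution inside a
#'   flank anchor.
#' @param seed RNG seed.
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}
#'   (Phred+33 string), \code{trueSize} (ground truth; 0 = no indel) and
#'   \code{corrupted}.
#' @export
simulateAmpliconReads <- function(spec, indelFraction, sizeDist, nReads,
                                  readLen = 151L, meanQ = 30,
                                  flankCorruptRate = 0, seed = 1L) {
  stopifnot(is(spec, "AmpliconSpec"))
  sizes <- as.integer(names(sizeDist))
  if (any(is.na(sizes)) || any(sizes == 0L))
    stop("sizeDist names must be nonzero integers")
  if (abs(sum(sizeDist) - 1) > 1e-8) stop("sizeDist must sum to 1")
  if (indelFraction < 0 || indelFraction > 1)
    stop("indelFraction must be in [0,1]")
  leftStart <- spec@targetStart - 40L        # 0-based flank starts in ref
  rightStart <- spec@targetEnd + 20L
  leftInner <- spec@targetStart - 20L        # inner edges
  rightInner <- spec@targetEnd + 20L
  cut <- spec@targetEnd - 3L                 # blunt cut 3 bp from target 3' end
  del <- sizes[sizes < 0L]
  if (length(del)) {
    for (s in del) {
      a <- cut - (-s) %/% 2L
      if (-s > spec@innerRefLen || a < leftInner || a + (-s) > rightInner)
        stop("deletion size exceeds the inner segment")
    }
  }
  ref <- spec@refSeq
  so <- max(0L, leftStart - 10L)             # read start offset in the ref

  withSeed(seed, {
    hasIndel <- runif(nReads) < indelFraction
    sizeDraw <- integer(nReads)
    if (any(hasIndel))
      sizeDraw[hasIndel] <- sample(sizes, sum(hasIndel), replace = TRUE,
                                   prob = sizeDist)
    corrupt <- runif(nReads) < flankCorruptRate
    seqs <- character(nReads)
    for (i in seq_len(nReads)) {
      s <- sizeDraw[i]
      if (s > 0L) {
        ins <- paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                     collapse = "")
        mod <- paste0(substr(ref, 1L, cut), ins,
                      substr(ref, cut + 1L, nchar(ref)))
        rShift <- s
      } else if (s < 0L) {
        a <- cut - (-s) %/% 2L
        mod <- paste0(substr(ref, 1L, a), substr(ref, a - s + 1L, nchar(ref)))
        rShift <- s
      } else {
        mod <- ref
        rShift <- 0L
      }
      if (corrupt[i]) {
        # one substitution inside a flank anchor (left or right, equiprobable)
        useLeft <- runif(1) < 0.5
        fs <- if (useLeft) leftStart else rightStart + rShift
        at <- fs + sample.int(20L, 1L)       # 1-based position in mod
        old <- substr(mod, at, at)
        substr(mod, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      rd <- substr(mod, so + 1L, so + readLen)
      if (nchar(rd) < readLen) {             # adapter-free random fill
        rd <- paste0(rd, paste(sample(c("A", "C", "G", "T"),
                                      readLen - nchar(rd), replace = TRUE),
                               collapse = ""))
      }
      seqs[i] <- rd
    }
    q <- matrix(pmin(40L, pmax(2L, round(rnorm(nReads * readLen, meanQ, 3)))),
                nrow = nReads)
    quals <- apply(q, 1L, function(v) intToUtf8(v + 33L))
    data.frame(id = sprintf("amp%06d", seq_len(nReads)), seq = seqs,
               qual = quals, trueSize = sizeDraw, corrupted = corrupt,
               stringsAsFactors = FALSE)
  })
}

#' Write amplicon reads as FASTQ (Phred+33)
#'
#' @param reads data.frame from \link{simulateAmpliconReads}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFastqReads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file into the amplicon-read table format
#'
#' @param path FASTQ path (Phred+33).
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
readFastqReads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
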