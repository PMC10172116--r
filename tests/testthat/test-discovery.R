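test_that("fragment midpoints land in the expected bins", {
  g <- makeGenome(1, 10000, seed = 1)
  # fragments [0,20), [50,70), [70,90): midpoints 10, 60, 80
  pairs <- data.frame(chrom = "chr1", start1 = c(0L, 50L, 70L),
                      start2 = c(10L, 60L, 80L), rlen = 10L,
                      isSingleton = FALSE)
  bins <- binFragmentMidpoints(pairSet(pairs, chromLengths(g)), 50L)
  expect_identical(bins$bin, c(0L, 1L))
  expect_identical(bins$count, c(1L, 2L))
  expect_identical(sum(bins$count), 3L)
  empty <- pairSet(pairs[0, ], chromLengths(g))
  expect_identical(nrow(binFragmentMidpoints(empty)), 0L)
})

test_that("binning agrees with a direct per-bin recount", {
  g <- makeGenome(1, 20000, seed = 2)
  pairs <- withr::with_seed(3, data.frame(
    chrom = "chr1", start1 = sample(19000L, 300, replace = TRUE),
    start2 = NA_integer_, rlen = 36L, isSingleton = FALSE))
  pairs$start2 <- pairs$start1 + sample(100:400, 300, replace = TRUE)
  keep <- pairs$start2 + 36L <= 20000L
  pairs <- pairs[keep, ]
  bins <- binFragmentMidpoints(pairSet(pairs, chromLengths(g)), 50L)
  mids <- (pmin(pairs$start1, pairs$start2) +
             pmax(pairs$start1, pairs$start2) + 36L) %/% 2L
  for (i in seq_len(nrow(bins))) {
    expect_identical(bins$count[i],
                     sum(mids %/% 50L == bins$bin[i]))
  }
  expect_identical(sum(bins$count), nrow(pairs))
})


test_that("candidate detection honors cutoff, merging and summits", {
  bins <- midpointBins(c(5000L), 10000L)
  expect_identical(nrow(findCandidates(bins, cutoffC = 2L)), 0L)
  bins3 <- midpointBins(c(5000L, 5040L, 5090L), 10000L)
  cand <- findCandidates(bins3, cutoffC = 2L)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$support, 3L)
  expect_error(findCandidates(bins3, cutoffC = 0L), ">= 1")
})

test_that("candidate detection matches exhaustive window enumeration", {
  for (rep in 1:40) {
    n <- sample(c(0, 3, 8, 20, 60), 1)
    chromLen <- 12000L
    mids <- withr::with_seed(100 + rep,
                             sort(sample(chromLen - 1L, n, replace = TRUE)))
    got <- findCandidates(midpointBins(mids, chromLen), cutoffC = 2L,
                          window = 500L)
    want <- bruteCandidates(mids, chromLen, 50L, 500L, 2L)
    got <- got[order(got$start), c("start", "end", "summit", "support")]
    rownames(got) <- NULL
    if (nrow(want)) {
      want <- want[order(want$start), ]
      rownames(want) <- NULL
      expect_equal(got, want)
    } else {
      expect_identical(nrow(got), 0L)
    }
  }
})

test_that("mismatch counting is an exact Hamming distance", {
  trac <- "AGAGTCTCTCAGCTGGTACA"
  expect_identical(countMismatches(trac, trac), 0L)
  mutated <- trac
  substr(mutated, 3, 3) <- "T"
  substr(mutated, 17, 17) <- "C"
  expect_identical(countMismatches(trac, mutated), 2L)
  expect_identical(countMismatches(mutated, trac), 2L)  # symmetric
  # the two juxtaposed TRAC guides, counted by an independent loop first
  expect_identical(countMismatches(trac, "GAGTCTCTCAGCTGGTACAC"), 19L)
  expect_error(countMismatches(trac, "ACGT"), "equal length")
})

test_that("protospacer matching recovers planted sites exactly", {
  fx <- plantedFixture()
  hit <- matchProtospacer(fx$genome,
                          list(chrom = "chr1", summit = 10100L), fx$guide)
  expect_identical(hit$cut, fx$sites$cutPos[1])
  expect_identical(hit$nMismatch, 0L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$protospacer, "AGAGTCTCTCAGCTGGTACA")
  # a PAM-free background region yields no call
  flat <- new("GenomeRef",
              seqs = Biostrings::DNAStringSet(c(
                chr1 = paste(rep("AT", 2000), collapse = ""))))
  expect_null(matchProtospacer(flat, list(chrom = "chr1", summit = 2000L),
                               fx$guide))
})

test_that("planted off-target sites are matched with the right mismatches", {
  guide <- tracGuide()
  for (rep in 1:100) {
    nm <- (rep %% 6L) + 1L
    strand <- if (rep %% 2L) "+" else "-"
    g <- makeGenome(1, 4000, seed = 500 + rep)
    pl <- plantSites(g, guide, data.frame(
      chrom = "chr1", position = 2000L, strand = strand, nMismatch = nm,
      efficiency = 1, stringsAsFactors = FALSE), seed = 700 + rep)
    summit <- pl$sites$cutPos[1] + sample(-150:150, 1)
    hit <- matchProtospacer(pl$genome,
                            list(chrom = "chr1", summit = summit), guide)
    expect_false(is.null(hit))
    expect_identical(hit$cut, pl$sites$cutPos[1])
    expect_identical(hit$nMismatch, nm)
    expect_identical(hit$strand, strand)
  }
})

test_that("control subtraction removes matched sites within tolerance", {
  mkSites <- function(cuts) data.frame(chrom = "chr1", cut = cuts,
                                       stringsAsFactors = FALSE)
  treated <- mkSites(c(1000L, 5000L, 9000L))
  sub <- subtractControl(treated, mkSites(5000L))
  expect_identical(sub$sites$cut, c(1000L, 9000L))
  expect_identical(sub$removed$cut, 5000L)
  expect_identical(subtractControl(treated, treated[0, ])$sites, treated)
  # boundary: 80 bp away removed, 120 bp retained at tolerance 100
  expect_identical(nrow(subtractControl(mkSites(1000L),
                                        mkSites(1080L))$sites), 0L)
  expect_identical(nrow(subtractControl(mkSites(1000L),
                                        mkSites(1120L))$sites), 1L)
})

test_that("discovery is monotone in cutoff and control set size", {
  fx <- plantedFixture(chromLen = 200000L, requests = data.frame(
    chrom = "chr1", position = c(40000L, 100000L, 160000L),
    strand = c("+", "-", "+"), nMismatch = c(0L, 2L, 4L),
    efficiency = c(1, 0.4, 0.1), stringsAsFactors = FALSE))
  cfg <- SimConfig(bgPairs = 150L, seed = 8L)
  aln <- filterAlignments(simulateChipReads(fx$genome, fx$sites, cfg,
                                            "treated_inhibited"))
  s2 <- discoverSites(aln, NULL, fx$genome, fx$guide, cutoffC = 2L)
  s4 <- discoverSites(aln, NULL, fx$genome, fx$guide, cutoffC = 4L)
  s9 <- discoverSites(aln, NULL, fx$genome, fx$guide, cutoffC = 9999L)
  expect_lte(nrow(s4), nrow(s2))
  expect_identical(nrow(s9), 0L)
  expect_true(all(s4$cut %in% s2$cut))
  # growing the control set never grows the output
  ctlSmall <- s2[2, , drop = FALSE]
  ctlBig <- s2[2:3, , drop = FALSE]
  kSmall <- subtractControl(s2, ctlSmall)$sites
  kBig <- subtractControl(s2, ctlBig)$sites
  expect_lte(nrow(kBig), nrow(kSmall))
})

test_that("an unedited sample yields no sites; the on-target leads in RPM", {
  fx <- plantedFixture(chromLen = 200000L, requests = data.frame(
    chrom = "chr1", position = c(40000L, 120000L),
    strand = "+", nMismatch = c(0L, 3L), efficiency = c(1, 0.2),
    stringsAsFactors = FALSE))
  cfg <- SimConfig(bgPairs = 100L, seed = 12L)
  ctl <- filterAlignments(simulateChipReads(fx$genome, fx$sites, cfg,
                                            "no_cas9"))
  sCtl <- discoverSites(ctl, NULL, fx$genome, fx$guide)
  expect_identical(nrow(sCtl), 0L)
  trt <- filterAlignments(simulateChipReads(fx$genome, fx$sites, cfg,
                                            "treated_inhibited"))
  sTrt <- discoverSites(trt, ctl, fx$genome, fx$guide)
  expect_true(nrow(sTrt) >= 2L)
  expect_true(sTrt$onTarget[1])
  expect_identical(max(sTrt$rpm), sTrt$rpm[1])
})
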