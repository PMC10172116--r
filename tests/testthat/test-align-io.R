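test_that("SAM round-trip preserves coordinates, strands and flags", {
  fx <- plantedFixture()
  cfg <- SimConfig(bgPairs = 200L, orphanRate = 0.05, lowmapqRate = 0.1,
                   seed = 17L)
  aln <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_inhibited")
  sam <- tempfile(fileext = ".sam")
  writeSam(aln, sam)
  back <- readAlignments(sam, fx$genome)
  a <- pairRecords(aln)[, c("qname", "chrom", "start1", "strand1",
                            "start2", "strand2", "mapq", "isSingleton")]
  b <- pairRecords(back)[, names(a)]
  a <- a[order(a$qname), ]; b <- b[order(b$qname), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a)
  expect_identical(totalReads(back), totalReads(aln))
})

test_that("pairing and singleton bookkeeping follow the SAM flags", {
  g <- makeGenome(1, 10000, seed = 1)
  pairs <- data.frame(chrom = "chr1", start1 = c(100L, 500L, 900L),
                      start2 = c(300L, 700L, NA),
                      isSingleton = c(FALSE, FALSE, TRUE))
  aln <- pairSet(pairs, chromLengths(g))
  expect_identical(totalReads(aln), 5L)
  sam <- tempfile(fileext = ".sam")
  writeSam(aln, sam)
  back <- readAlignments(sam, g)
  expect_identical(nPairs(back), 3L)
  expect_identical(sum(pairRecords(back)$isSingleton), 1L)
  # two proper pairs alone: 2 records, 4 reads
  aln2 <- pairSet(pairs[1:2, ], chromLengths(g))
  writeSam(aln2, sam)
  expect_identical(totalReads(readAlignments(sam, g)), 4L)
})

test_that("records on unknown chromosomes are a named hard error", {
  g <- makeGenome(1, 10000, seed = 1)
  weird <- pairSet(data.frame(chrom = "chrZ", start1 = 10L, start2 = 200L,
                              isSingleton = FALSE),
                   c(chr1 = 10000L, chrZ = 5000L))
  sam <- tempfile(fileext = ".sam")
  writeSam(weird, sam)
  expect_error(readAlignments(sam, g), "chrZ")
})

test_that("filtering applies the MAPQ boundary, singleton and dup rules", {
  g <- makeGenome(1, 10000, seed = 1)
  pairs <- data.frame(
    chrom = "chr1",
    start1 = c(100L, 100L, 200L, 300L, 400L),
    start2 = c(400L, 400L, 500L, 600L, NA),
    mapq = c(42L, 42L, 24L, 25L, 42L),
    isSingleton = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  aln <- pairSet(pairs, chromLengths(g))
  filt <- filterAlignments(aln)
  rep <- alnMeta(filt)$filterReport
  expect_identical(rep$nLowMapq, 1L)     # mapq 24 removed, 25 retained
  expect_identical(rep$nSingleton, 1L)
  expect_identical(rep$nDuplicate, 1L)   # identical signature, first kept
  expect_identical(rep$nRetained, 2L)
  expect_identical(sort(pairRecords(filt)$start1), c(100L, 300L))
  # idempotence
  again <- filterAlignments(filt)
  expect_identical(pairRecords(again), pairRecords(filt))
  expect_identical(alnMeta(again)$filterReport$nRetained, rep$nRetained)
})

test_that("filter removal counts match the simulator ground truth", {
  fx <- plantedFixture()
  # isolate each artifact so report counts equal ledger counts exactly
  cfgDup <- SimConfig(bgPairs = 400L, dupRate = 0.1, lowmapqRate = 0,
                      orphanRate = 0, seed = 19L)
  # background-only library: every duplicate signature is a planted PCR copy
  alnD <- simulateChipReads(fx$genome, fx$sites, cfgDup, "no_cas9")
  repD <- alnMeta(filterAlignments(alnD))$filterReport
  expect_identical(repD$nDuplicate, alnMeta(alnD)$ledger$nDuplicates)
  # with dense site pileups the signature rule may additionally catch
  # coincidentally identical fragments, never fewer than the planted copies
  alnT <- simulateChipReads(fx$genome, fx$sites, cfgDup, "treated_inhibited")
  expect_gte(alnMeta(filterAlignments(alnT))$filterReport$nDuplicate,
             alnMeta(alnT)$ledger$nDuplicates)
  cfgQ <- SimConfig(bgPairs = 400L, dupRate = 0, lowmapqRate = 0.05,
                    orphanRate = 0.03, seed = 23L)
  alnQ <- simulateChipReads(fx$genome, fx$sites, cfgQ, "treated_inhibited")
  repQ <- alnMeta(filterAlignments(alnQ))$filterReport
  led <- alnMeta(alnQ)$ledger
  expect_identical(repQ$nLowMapq, led$nLowMapq)
  p <- pairRecords(alnQ)
  expect_identical(repQ$nSingleton, sum(p$isSingleton & p$mapq >= 25L))
})

test_that("equal-depth subsetting enforces the minimum and stays a subset", {
  g <- makeGenome(1, 100000, seed = 1)
  mk <- function(n, seed) {
    withr::with_seed(seed, pairSet(data.frame(
      chrom = "chr1", start1 = sample(90000L, n), start2 = NA_integer_,
      isSingleton = FALSE), chromLengths(g)))
  }
  big <- mk(1000, 1); small <- mk(400, 2)
  big@pairs$start2 <- big@pairs$start1 + 200L
  small@pairs$start2 <- small@pairs$start1 + 200L
  out <- subsampleEqualDepth(list(big, small), seed = 5)
  expect_identical(vapply(out, nPairs, integer(1)), c(400L, 400L))
  expect_true(all(pairRecords(out[[1]])$qname %in% pairRecords(big)$qname))
  expect_identical(pairRecords(out[[2]]), pairRecords(small))  # identity
  expect_identical(unique(vapply(out, totalReads, integer(1))), 800L)
  expect_error(subsampleEqualDepth(list(big), seed = 1), "at least two")
})

test_that("subsetting leaves window RPM unbiased", {
  g <- makeGenome(1, 100000, seed = 1)
  full <- withr::with_seed(11, pairSet(data.frame(
    chrom = "chr1", start1 = sample(90000L, 2000, replace = TRUE),
    start2 = NA_integer_, isSingleton = FALSE), chromLengths(g)))
  full@pairs$start2 <- full@pairs$start1 + 200L
  small <- pairSet(data.frame(chrom = "chr1",
                              start1 = seq(100L, by = 70L, length.out = 1200),
                              start2 = NA_integer_, isSingleton = FALSE),
                   chromLengths(g))
  small@pairs$start2 <- small@pairs$start1 + 200L
  before <- rpmWindow(full, "chr1", 50000L, 3000L)
  rel <- vapply(1:200, function(s) {
    sub <- subsampleEqualDepth(list(full, small), seed = s)[[1]]
    rpmWindow(sub, "chr1", 50000L, 3000L)
  }, numeric(1))
  expect_lt(abs(mean(rel) - before) / before, 0.02)
})
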