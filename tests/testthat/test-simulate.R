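fixtureOneSite <- function(eff = 1, chromLen = 100000L, seed = 5L) {
  plantedFixture(chromLen = chromLen,
                 requests = data.frame(chrom = "chr1", position = 50000L,
                                       strand = "+", nMismatch = 0L,
                                       efficiency = eff,
                                       stringsAsFactors = FALSE),
                 seed = seed)
}

test_that("simulated output is deterministic and condition-consistent", {
  fx <- fixtureOneSite()
  cfg <- SimConfig(bgPairs = 300L, seed = 9L)
  a1 <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_inhibited")
  a2 <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_inhibited")
  expect_identical(pairRecords(a1), pairRecords(a2))
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  writeSam(a1, f1); writeSam(a2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # multiplier 1 reproduces the no-drug condition exactly under one seed
  cfg1 <- SimConfig(residenceMultiplier = 1, bgPairs = 300L, seed = 9L)
  inh <- simulateChipReads(fx$genome, fx$sites, cfg1, "treated_inhibited")
  nod <- simulateChipReads(fx$genome, fx$sites, cfg1, "treated_no_drug")
  expect_identical(pairRecords(inh), pairRecords(nod))

  # no-nuclease condition carries no site-derived fragments at all
  ctl <- simulateChipReads(fx$genome, fx$sites, cfg, "no_cas9")
  expect_true(all(grepl("^bg", pairRecords(ctl)$origin)))
})

test_that("background reads are identical across treated conditions", {
  fx <- fixtureOneSite()
  cfg <- SimConfig(bgPairs = 400L, seed = 21L)
  inh <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_inhibited")
  nod <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_no_drug")
  bg <- function(a) {
    p <- pairRecords(a)
    p <- p[grepl("^bg", p$origin), , drop = FALSE]
    rownames(p) <- NULL
    p
  }
  expect_identical(bg(inh), bg(nod))
})

test_that("residence multiplier scales site-bound pair counts fivefold", {
  fx <- fixtureOneSite()
  ratios <- vapply(1:10, function(s) {
    c5 <- SimConfig(residenceMultiplier = 5, lambda0 = 50, bgPairs = 0L,
                    seed = s)
    c1 <- SimConfig(residenceMultiplier = 1, lambda0 = 50, bgPairs = 0L,
                    seed = s)
    n5 <- alnMeta(simulateChipReads(fx$genome, fx$sites, c5,
                                    "treated_inhibited"))$ledger$nSitePairs
    n1 <- alnMeta(simulateChipReads(fx$genome, fx$sites, c1,
                                    "treated_inhibited"))$ledger$nSitePairs
    sum(n5) / sum(n1)
  }, numeric(1))
  # closed-form Poisson means 250 vs 50; the mean ratio over 10 seeds stays
  # well within sampling error of 5
  expect_gt(mean(ratios), 3.5)
  expect_lt(mean(ratios), 6.5)
})

test_that("the provenance ledger accounts for every emitted pair", {
  fx <- fixtureOneSite(eff = 0.8)
  cfg <- SimConfig(bgPairs = 500L, dupRate = 0.1, lowmapqRate = 0.08,
                   orphanRate = 0.05, seed = 13L)
  aln <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_inhibited")
  p <- pairRecords(aln)
  led <- alnMeta(aln)$ledger
  expect_identical(nrow(p), led$nEmittedPairs)
  expect_identical(led$nEmittedPairs,
                   led$nBgPairs + sum(led$nSitePairs) + led$nDuplicates)
  expect_identical(sum(grepl("\\.dup$", p$origin)), led$nDuplicates)
  expect_identical(sum(p$isSingleton), led$nOrphans)
  expect_identical(sum(p$mapq < 25L), led$nLowMapq)
  expect_identical(totalReads(aln),
                   2L * sum(!p$isSingleton) + sum(p$isSingleton))
})

test_that("coverage shows two flanking peaks with a dip at the cut", {
  fx <- fixtureOneSite()
  cut <- fx$sites$cutPos[1]
  # 4000 site pairs pooled at one cut: lambda0 = 4000, no artifacts
  cfg <- SimConfig(lambda0 = 4000, residenceMultiplier = 1, bgPairs = 0L,
                   dupRate = 0, lowmapqRate = 0, orphanRate = 0, seed = 7L)
  aln <- simulateChipReads(fx$genome, fx$sites, cfg, "treated_no_drug")
  tr <- coverageTrack(aln, "chr1", cut - 600L, cut + 600L)
  perBase <- rep(0L, 1200L)
  for (i in seq_len(nrow(tr))) {
    idx <- seq(tr$start[i] - (cut - 600L) + 1L, tr$end[i] - (cut - 600L))
    perBase[idx] <- tr$value[i]
  }
  atCut <- perBase[601L]
  leftMax <- max(perBase[1:600])
  rightMax <- max(perBase[602:1200])
  expect_lt(atCut, leftMax)
  expect_lt(atCut, rightMax)
  # mirror symmetry: empirical peak heights differ by < 10%
  expect_lt(abs(leftMax - rightMax) / max(leftMax, rightMax), 0.10)
})

test_that("amplicon simulation honors indel fraction, spectrum and flanks", {
  ref <- as.character(genomeSeqs(makeGenome(1, 240, seed = 31))[[1]])
  spec <- locateFlanks(ref, 100L, 120L)
  # indel-free reads reproduce the reference inner segment
  clean <- simulateAmpliconReads(spec, 0, c("1" = 1), 200, seed = 1)
  s <- summarizeIndels(clean, spec)
  expect_identical(indelHistogram(s), c("0" = 200L))
  # ground-truth +1:-3 mix within binomial error of 4:1
  mix <- simulateAmpliconReads(spec, 0.5, c("1" = 0.8, "-3" = 0.2), 10000,
                               seed = 2)
  n1 <- sum(mix$trueSize == 1L); n3 <- sum(mix$trueSize == -3L)
  phat <- n1 / (n1 + n3)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / (n1 + n3)))
  # fully corrupted flanks exclude every read downstream
  bad <- simulateAmpliconReads(spec, 0, c("1" = 1), 300,
                               flankCorruptRate = 1, seed = 3)
  sBad <- summarizeIndels(bad, spec)
  expect_identical(sBad@nExcludedNoFlank, 300L)
  expect_identical(sum(indelHistogram(sBad)), 0L)
  # a deletion that exceeds the inner segment is rejected up front
  expect_error(simulateAmpliconReads(spec, 0.5, c("-80" = 1), 10, seed = 1),
               "exceeds the inner segment")
})
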