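# End-to-end orchestration: one config, one master seed, full workflow from
# synthetic genome to discovered sites, paired RPM quantification and
# comparison statistics.

#' Default end-to-end run configuration
#'
#' Desk-scale study conditions: a 2 Mb two-chromosome toy genome, the TRAC
#' Cas9 guide, one on-target site (efficiency 1) plus ten off-target sites
#' spanning 1-6 mismatches with efficiencies 0.05-0.5, lambda0 = 50
#' site-bound pairs per unit efficiency, a fivefold residence multiplier
#' under DNA-PKcs inhibition, and discovery at support cutoff 2. Every
#' tunable surfaced by the underlying modules is reachable from this config.
#'
#' @param masterSeed Master seed; every stochastic stage derives its own
#'   seed from it via \link{stageSeed}.
#' @param outDir Optional output directory for reports (default NULL: no
#'   files written).
#' @return A named list (class \code{dsbRunConfig}).
#' @export
defaultRunConfig <- function(masterSeed = 1L, outDir = NULL) {
  cfg <- list(
    masterSeed = as.integer(masterSeed),
    genome = list(nChroms = 2L, lengths = c(1200000L, 800000L)),
    guide = list(name = "TRAC", protospacer = "AGAGTCTCTCAGCTGGTACA",
                 nuclease = "cas9", pam = "NGG", maxMismatch = 6L),
    sites = data.frame(
      chrom = c(rep("chr1", 6), rep("chr2", 5)),
      position = c(100000L, 300000L, 500000L, 700000L, 900000L, 1100000L,
                   100000L, 250000L, 400000L, 550000L, 700000L),
      strand = c("+", "-", "+", "-", "+", "-", "+", "-", "+", "-", "+"),
      nMismatch = c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 6L),
      efficiency = c(1.0, 0.5, 0.4, 0.3, 0.25, 0.2,
                     0.15, 0.12, 0.1, 0.08, 0.05),
      stringsAsFactors = FALSE),
    sim = list(lambda0 = 50, residenceMultiplier = 5, fragLenMin = 150L,
               fragLenMax = 400L, endSigma = 25, readLen = 36L,
               bgPairs = 400L, dupRate = 0.05, lowmapqRate = 0.05,
               orphanRate = 0.02),
    discovery = list(cutoffC = 2L, binSize = 50L, windowBp = 500L,
                     searchRadius = 250L, controlTolerance = 100L,
                     rpmWindowBp = 1500L, backgroundOffset = 10000L,
                     minMapq = 25L),
    outDir = outDir)
  class(cfg) <- "dsbRunConfig"
  cfg
}

.checkRunConfig <- function(cfg) {
  ref <- defaultRunConfig()
  for (sec in setdiff(names(ref), "outDir")) {
    if (is.null(cfg[[sec]])) stop("config is missing section '", sec, "'")
    if (is.list(ref[[sec]]) && !is.data.frame(ref[[sec]])) {
      miss <- setdiff(names(ref[[sec]]), names(cfg[[sec]]))
      if (length(miss))
        stop("config section '", sec, "' is missing: ",
             paste(miss, collapse = ", "))
    }
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips unchanged through serialization.
#'
#' @param path YAML path.
#' @return \code{readRunConfig}: a \code{dsbRunConfig} list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$sites <- as.data.frame(raw$sites, stringsAsFactors = FALSE)
  raw$masterSeed <- as.integer(raw$masterSeed)
  intify <- function(l, keys) {
    for (k in intersect(keys, names(l))) l[[k]] <- as.integer(l[[k]])
    l
  }
  raw$genome <- intify(raw$genome, c("nChroms", "lengths"))
  raw$sim <- intify(raw$sim, c("fragLenMin", "fragLenMax", "readLen",
                               "bgPairs"))
  raw$discovery <- intify(raw$discovery, names(raw$discovery))
  raw$guide <- intify(raw$guide, "maxMismatch")
  raw$sites$position <- as.integer(raw$sites$position)
  raw$sites$nMismatch <- as.integer(raw$sites$nMismatch)
  class(raw) <- "dsbRunConfig"
  .checkRunConfig(raw)
}

#' @rdname readRunConfig
#' @param cfg A \code{dsbRunConfig} list.
#' @return \code{writeRunConfig}: \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  out <- unclass(cfg)
  out$sites <- as.list(out$sites)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full workflow end to end
#'
#' Simulates inhibited, no-drug and no-nuclease samples from one planted
#' ground truth; filters and depth-matches them; discovers sites for both
#' treated arms against the no-nuclease control; quantifies paired RPM at
#' the inhibited-arm sites (and at 10-kb offset background positions); runs
#' two-sided signed-rank comparisons; and scores recovery against the
#' planted truth. Deterministic under \code{masterSeed}.
#'
#' @param cfg A \code{dsbRunConfig}, e.g. \link{defaultRunConfig}.
#' @return A list: site tables for both arms, enrichment records,
#'   comparisons, recovery statistics and the run's inputs (genome, planted
#'   sites, configs).
#' @export
runEndToEnd <- function(cfg = defaultRunConfig()) {
  .checkRunConfig(cfg)
  ms <- cfg$masterSeed
  guide <- GuideSpec(cfg$guide$name, cfg$guide$protospacer,
                     cfg$guide$nuclease, cfg$guide$pam,
                     cfg$guide$maxMismatch)
  genome0 <- makeGenome(cfg$genome$nChroms, cfg$genome$lengths,
                        seed = stageSeed(ms, "genome"))
  planted <- plantSites(genome0, guide, cfg$sites,
                        seed = stageSeed(ms, "plant"))
  genome <- planted$genome
  truth <- planted$sites

  simCfg <- do.call(SimConfig, c(cfg$sim, list(seed = stageSeed(ms, "sim"))))
  arms <- lapply(
    c(inhibited = "treated_inhibited", noDrug = "treated_no_drug",
      control = "no_cas9"),
    function(cond) simulateChipReads(genome, truth, simCfg, cond))
  filtered <- lapply(arms, filterAlignments, minMapq = cfg$discovery$minMapq)
  # equal-read subsetting applies to the compared treated arms; the
  # no-nuclease control enters only through site-list subtraction
  depth <- subsampleEqualDepth(filtered[c("inhibited", "noDrug")],
                               seed = stageSeed(ms, "subsample"))
  depth$control <- filtered$control

  disc <- cfg$discovery
  discover <- function(a, control) discoverSites(
    a, control = control, genome = genome, guide = guide,
    cutoffC = disc$cutoffC, binSize = disc$binSize, window = disc$windowBp,
    searchRadius = disc$searchRadius,
    controlTolerance = disc$controlTolerance,
    rpmWindowBp = disc$rpmWindowBp)
  controlSites <- discover(depth$control, NULL)
  sitesInhibited <- discover(depth$inhibited, controlSites)
  sitesNoDrug <- discover(depth$noDrug, controlSites)

  enr <- NULL
  comparisons <- list()
  if (nrow(sitesInhibited) >= 2L) {
    enr <- enrichmentRecords(sitesInhibited, depth$inhibited, depth$noDrug,
                             window = disc$rpmWindowBp,
                             offset = disc$backgroundOffset)
    comparisons$rpm_site <- comparePaired(enr$rpmInhibited, enr$rpmNoDrug,
                                          "signed_rank")
    okBg <- !is.na(enr$rpmBgInhibited) & !is.na(enr$rpmBgNoDrug)
    if (sum(okBg) >= 2L)
      comparisons$rpm_background <- comparePaired(enr$rpmBgInhibited[okBg],
                                                  enr$rpmBgNoDrug[okBg],
                                                  "signed_rank")
  }

  truthTable <- data.frame(chrom = truth$chrom, cut = truth$cutPos,
                           stringsAsFactors = FALSE)
  recI <- overlapSites(truthTable, sitesInhibited,
                       tolerance = disc$controlTolerance)
  recN <- overlapSites(truthTable, sitesNoDrug,
                       tolerance = disc$controlTolerance)
  armOverlap <- overlapSites(sitesInhibited, sitesNoDrug,
                             tolerance = disc$controlTolerance)

  summary <- list(
    nSitesInhibited = nrow(sitesInhibited),
    nSitesNoDrug = nrow(sitesNoDrug),
    nPlanted = nrow(truth),
    recoveryInhibited = recI$both / nrow(truth),
    recoveryNoDrug = recN$both / nrow(truth),
    backgroundCallsInhibited = recI$onlyB,
    backgroundCallsNoDrug = recN$onlyB,
    pRpmSite = if (!is.null(comparisons$rpm_site))
      comparisons$rpm_site$pValue else NA_real_,
    pRpmBackground = if (!is.null(comparisons$rpm_background))
      comparisons$rpm_background$pValue else NA_real_)

  if (!is.null(cfg$outDir)) {
    writeReports(sitesInhibited, enr, comparisons, armOverlap,
                 outDir = cfg$outDir,
                 runInfo = list(masterSeed = ms,
                                condition = "treated_inhibited",
                                cutoffC = disc$cutoffC))
  }
  list(summary = summary, sitesInhibited = sitesInhibited,
       sitesNoDrug = sitesNoDrug, enrichment = enr,
       comparisons = comparisons, armOverlap = armOverlap,
       genome = genome, planted = truth, simConfig = simCfg, config = cfg)
}
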