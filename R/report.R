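# Table and figure-data export: site tables (TSV + BED), paired-enrichment
# scatter data, overlap summaries and a run log.

#' Write a site table as TSV
#'
#' Columns: chrom, cut (1-based), strand, sequence, PAM, mismatches,
#' support, RPM, on/off flag. Round-trips through \link{readSiteTable}.
#'
#' @param sites Site table from \link{discoverSites}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  out <- data.frame(chrom = sites$chrom, cut = sites$cut + 1L,
                    strand = sites$strand, protospacer = sites$protospacer,
                    pam = sites$pam, mismatches = sites$nMismatch,
                    support = sites$support, rpm = sites$rpm,
                    on_target = sites$onTarget, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by writeSiteTable
#'
#' @param path TSV path.
#' @return Site table data.frame in the package's internal convention
#'   (0-based \code{cut}).
#' @export
readSiteTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(protospacer = "character",
                                 pam = "character"))
  data.frame(chrom = as.character(x$chrom), cut = as.integer(x$cut - 1L),
             strand = as.character(x$strand),
             protospacer = as.character(x$protospacer),
             pam = as.character(x$pam),
             nMismatch = as.integer(x$mismatches),
             support = as.integer(x$support), rpm = as.numeric(x$rpm),
             onTarget = as.logical(x$on_target), stringsAsFactors = FALSE)
}

#' Write a site table as BED6
#'
#' 0-based half-open single-base cut intervals; score = mismatch count.
#'
#' @param sites Site table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSiteBed <- function(sites, path) {
  lines <- if (nrow(sites)) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$cut,
            sites$cut + 1L,
            paste0(sites$protospacer, "|", sites$pam),
            sites$nMismatch, sites$strand)
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write run reports
#'
#' Emits the standard result files for one discovery run: site table (TSV +
#' BED), paired enrichment scatter data (x = no-drug RPM, y = inhibited
#' RPM, plus offset backgrounds), comparison results, overlap summary and a
#' run log echoing configuration and seeds. Outputs are byte-identical for
#' identical inputs (no timestamps).
#'
#' @param sites Site table from \link{discoverSites}.
#' @param enrichment data.frame from \link{enrichmentRecords} or \code{NULL}.
#' @param comparisons Named list of \code{dsbComparison} results or
#'   \code{NULL}.
#' @param overlap Result of \link{overlapSites} or \code{NULL}.
#' @param outDir Output directory (created if absent).
#' @param runInfo Named list echoed into the run log (config, seeds).
#' @return Invisibly, the vector of files written.
#' @export
writeReports <- function(sites, enrichment = NULL, comparisons = NULL,
                         overlap = NULL, outDir, runInfo = list()) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outDir)) stop("cannot create out dir: ", outDir)
  }
  files <- character(0)
  f <- file.path(outDir, "sites.tsv")
  writeSiteTable(sites, f); files <- c(files, f)
  f <- file.path(outDir, "sites.bed")
  writeSiteBed(sites, f); files <- c(files, f)
  if (!is.null(enrichment)) {
    f <- file.path(outDir, "enrichment.tsv")
    write.table(enrichment, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(comparisons)) {
    df <- do.call(rbind, lapply(names(comparisons), function(nm) {
      cm <- comparisons[[nm]]
      data.frame(comparison = nm, test = cm$test,
                 n = paste(cm$n, collapse = "/"),
                 statistic = cm$statistic, p_value = cm$pValue,
                 degenerate = cm$degenerate, stringsAsFactors = FALSE)
    }))
    f <- file.path(outDir, "comparisons.tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(overlap)) {
    f <- file.path(outDir, "overlap.json")
    jsonlite::write_json(overlap[c("onlyA", "onlyB", "both")], f,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  f <- file.path(outDir, "run_log.txt")
  log <- c("dsbscan run log",
           vapply(names(runInfo), function(k)
             paste0(k, ": ", paste(format(runInfo[[k]]), collapse = " ")),
             character(1)))
  writeLines(log, f)
  files <- c(files, f)
  invisible(files)
}
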