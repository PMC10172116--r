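# Paired and unpaired comparison statistics (all two-sided) and site-set
# overlap bookkeeping.

#' @importFrom stats wilcox.test t.test
NULL

.comparisonResult <- function(test, n, statistic, pValue, exact = NA,
                              nZeroDropped = 0L, degenerate = FALSE) {
  structure(list(test = test, n = n, statistic = unname(statistic),
                 pValue = min(1, pValue), sidedness = "two_sided",
                 exact = exact, nZeroDropped = nZeroDropped,
                 degenerate = degenerate),
            class = "dsbComparison")
}

#' @export
print.dsbComparison <- function(x, ...) {
  cat(x$test, " (two-sided), n = ", paste(x$n, collapse = "/"),
      if (x$nZeroDropped) paste0(", ", x$nZeroDropped, " zero diffs dropped"),
      ":\n  statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$pValue, 4),
      if (isTRUE(x$exact)) " (exact)" else "",
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Paired two-sample comparison
#'
#' Wilcoxon signed-rank (zero differences dropped, count reported; exact
#' null distribution for 25 or fewer nonzero differences without ties in
#' absolute value, normal approximation with continuity correction
#' otherwise) or paired t-test. Two-sided.
#'
#' @param x,y Equal-length numeric vectors of paired observations
#'   (length >= 2).
#' @param test \code{"signed_rank"} or \code{"t_paired"}.
#' @return A \code{dsbComparison} list: \code{test}, \code{n},
#'   \code{statistic}, \code{pValue}, \code{sidedness}, \code{exact},
#'   \code{nZeroDropped}, \code{degenerate}.
#' @export
comparePaired <- function(x, y, test = c("signed_rank", "t_paired")) {
  test <- match.arg(test)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two pairs")
  d <- x - y
  if (test == "signed_rank") {
    dnz <- d[d != 0]
    nZero <- sum(d == 0)
    if (!length(dnz)) {
      return(.comparisonResult("signed_rank", length(x), NA_real_, 1,
                               exact = TRUE, nZeroDropped = nZero,
                               degenerate = TRUE))
    }
    exact <- length(dnz) <= 25L && !any(duplicated(abs(dnz)))
    ht <- suppressWarnings(wilcox.test(dnz, mu = 0, exact = exact,
                                       correct = TRUE))
    .comparisonResult("signed_rank", length(x), ht$statistic, ht$p.value,
                      exact = exact, nZeroDropped = nZero)
  } else {
    if (sd(d) == 0) {
      return(.comparisonResult("t_paired", length(x), NA_real_,
                               if (all(d == 0)) 1 else NA_real_,
                               degenerate = TRUE))
    }
    ht <- t.test(x, y, paired = TRUE)
    .comparisonResult("t_paired", length(x), ht$statistic, ht$p.value)
  }
}

#' Unpaired two-sample comparison
#'
#' Wilcoxon rank-sum (midranks for ties; exact null when the smaller sample
#' has 10 or fewer observations and there are no ties, normal approximation
#' with tie correction and continuity correction otherwise) or Welch
#' t-test. Two-sided.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param test \code{"rank_sum"} or \code{"t_unpaired"}.
#' @return A \code{dsbComparison} list; see \link{comparePaired}.
#' @export
compareUnpaired <- function(x, y, test = c("rank_sum", "t_unpaired")) {
  test <- match.arg(test)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two observations")
  if (length(unique(c(x, y))) == 1L) {
    return(.comparisonResult(test, c(length(x), length(y)), NA_real_, 1,
                             degenerate = TRUE))
  }
  if (test == "rank_sum") {
    ties <- any(duplicated(c(x, y)))
    exact <- min(length(x), length(y)) <= 10L && !ties
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    .comparisonResult("rank_sum", c(length(x), length(y)), ht$statistic,
                      ht$p.value, exact = exact)
  } else {
    ht <- t.test(x, y) # Welch degrees of freedom
    .comparisonResult("t_unpaired", c(length(x), length(y)), ht$statistic,
                      ht$p.value)
  }
}

#' Overlap two site sets
#'
#' Greedy nearest-coordinate matching of cut positions within a tolerance on
#' the same chromosome, each site matched at most once; candidate matches
#' are processed in order of increasing distance (ties by coordinates), so
#' the result is deterministic and symmetric in the counts.
#'
#' @param a,b Site tables (columns \code{chrom}, \code{cut}).
#' @param tolerance Maximum matched distance in bases (default 100).
#' @return List with counts \code{onlyA}, \code{onlyB}, \code{both} and a
#'   \code{matches} data.frame (\code{idxA}, \code{idxB}, \code{distance}).
#' @export
overlapSites <- function(a, b, tolerance = 100L) {
  na <- nrow(a); nb <- nrow(b)
  cand <- NULL
  if (na && nb) {
    cand <- do.call(rbind, lapply(seq_len(na), function(i) {
      j <- which(b$chrom == a$chrom[i] & abs(b$cut - a$cut[i]) <= tolerance)
      if (!length(j)) return(NULL)
      data.frame(idxA = i, idxB = j, distance = abs(b$cut[j] - a$cut[i]))
    }))
  }
  matches <- data.frame(idxA = integer(), idxB = integer(),
                        distance = integer())
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$distance, cand$idxA, cand$idxB), , drop = FALSE]
    usedA <- logical(na); usedB <- logical(nb)
    for (k in seq_len(nrow(cand))) {
      i <- cand$idxA[k]; j <- cand$idxB[k]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE
        matches <- rbind(matches, cand[k, , drop = FALSE])
      }
    }
  }
  both <- nrow(matches)
  list(onlyA = na - both, onlyB = nb - both, both = both,
       matches = matches)
}
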