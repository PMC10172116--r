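# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically fans one master seed out to named pipeline stages, so
#' that stages draw from independent streams while the whole run stays
#' reproducible. Polynomial string hash combined with the master seed, reduced
#' modulo a Mersenne prime so the result is a valid 32-bit seed.
#'
#' @param masterSeed Integer master seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed in [1, 2^31 - 2].
#' @export
stageSeed <- function(masterSeed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(masterSeed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer(max(1, h))
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reference-space width of a simple CIGAR string (M/D/N/=/X consume).
cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# IUPAC-aware match of a single base against a pattern character.
.iupac <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"))
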