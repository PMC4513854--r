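# Internal helpers shared across modules.

# IUPAC nucleotide degeneracy map. N matches any base in a *pattern*; an N in
# the scanned sequence never matches anything (see scanConsensus).
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream. seed = NULL uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Encode an upper-case DNA string as integers 1..4 (A,C,G,T); anything else
# (including N) becomes NA.
encodeDNA <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1L]], DNA_BASES)
}

# Reverse-complement of a plain character string, IUPAC-aware.
revcompChar <- function(seq) {
  as.character(reverseComplement(DNAString(seq)))
}

checkIupac <- function(iupac, what = "motif") {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC code(s) in %s: %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  chars
}

# Significance stars used throughout reporting.
pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# stopifnot() with sprintf-style message.
stopf <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
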