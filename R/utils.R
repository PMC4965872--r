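# Internal helpers shared across modules.

# Fraction labels used throughout: 1 = free RNP, 2 = 40S/60S, 3 = 80S monosome,
# 4..7 = polysome fractions of increasing ribosome load.
FRACTION_IDS <- 1:7

`%||%` <- rlang::`%||%`

assert_counts7 <- function(counts, what = "counts") {
  if (!is.numeric(counts) || length(counts) != 7L) {
    abort(sprintf("`%s` must be a numeric vector of length 7 (one entry per gradient fraction).", what))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", what))
  }
  invisible(counts)
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# strand-aware most-5' choice between two genomic positions
most5 <- function(pos, strand) {
  if (strand == "+") min(pos) else max(pos)
}

# normalize nucleotide string to DNA alphabet uppercase (U -> T)
as_dna <- function(seq) {
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (any(grepl("[^ACGT]", s))) {
    abort("sequence contains non-nucleotide characters (expected A/C/G/T/U)")
  }
  s
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
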