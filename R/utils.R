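# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.BASES <- c("A", "C", "G", "T")

#' Round half up
#'
#' Decimal rounding with ties going away from zero, the dialect used for
#' megabase summaries in published centromere tables (e.g. 45.2 / 7 -> 6.5).
#' Base R's `round()` rounds half to even and would give 6.4 in such cases.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. ACGT background, the composition assumed by the seed-based
#' repeat detector (minimises spurious 30-mer matches).
#'
#' @param n sequence length in nucleotides.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x a character string over the DNA alphabet.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# 0-based half-open interval sanity check
check_interval <- function(x, name = "interval") {
  if (length(x) != 2 || !is.numeric(x) || x[2] < x[1]) {
    stop(name, " must be a numeric [start, end) pair with end >= start")
  }
  invisible(x)
}

# run `expr` under a fixed seed when one is given, otherwise in the current
# RNG stream
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# extract [start, end) (0-based) from a character sequence
subseq0 <- function(seq, start, end) substr(seq, start + 1, end)
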