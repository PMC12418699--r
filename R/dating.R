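# Molecular dating of LTR retrotransposon insertions. The two LTRs are
# identical at insertion and diverge independently, so the Kimura
# two-parameter distance K between them, divided by twice the substitution
# rate, estimates the insertion age: age = K / (2 r).

default_scoring <- function() list(match = 2, mismatch = -2, gap = -3)

#' Globally align a 5'/3' LTR pair
#'
#' Needleman-Wunsch global alignment under simple scores (defaults mirror
#' the detector: match +2, mismatch -2, linear gap -3).
#'
#' @param ltr5,ltr3 LTR sequences (non-empty character strings).
#' @param scoring list with `match`, `mismatch`, `gap`.
#' @return object of class `ltr_alignment`: list with aligned strings `a`,
#'   `b` (gap character `-`) and the alignment `score`.
#' @export
align_ltr_pair <- function(ltr5, ltr3, scoring = default_scoring()) {
  if (!nzchar(ltr5) || !nzchar(ltr3)) stop("cannot align an empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                  mismatch = scoring$mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(toupper(ltr5), toupper(ltr3),
                                      substitutionMatrix = mat,
                                      gapOpening = 0,
                                      gapExtension = -scoring$gap,
                                      type = "global")
  structure(list(a = as.character(Biostrings::alignedPattern(pa)),
                 b = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "ltr_alignment")
}

#' Count transitions and transversions in an alignment
#'
#' Columns containing a gap or an ambiguous base (anything outside ACGT) are
#' excluded. Transitions are A<->G and C<->T; every other mismatch is a
#' transversion. `P` and `Q` are the transition and transversion fractions
#' over the retained columns.
#'
#' @param alignment an [align_ltr_pair()] result (or a list with aligned
#'   strings `a` and `b`).
#' @return object of class `subst_counts`: `n_cols`, `ts`, `tv`, `P`, `Q`.
#' @export
count_substitutions <- function(alignment) {
  a <- seq_chars(alignment$a)
  b <- seq_chars(alignment$b)
  if (length(a) != length(b) || length(a) == 0) stop("malformed alignment")
  keep <- a %in% .BASES & b %in% .BASES
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) stop("no ungapped columns in alignment")
  mism <- a != b
  ts <- sum(mism & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  tv <- sum(mism) - ts
  structure(list(n_cols = n, ts = ts, tv = tv, P = ts / n, Q = tv / n),
            class = "subst_counts")
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' observed transition and transversion fractions. Outside the domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the divergence is saturated and
#' `NA_real_` is returned; callers flag such elements rather than reporting
#' a number.
#'
#' @param P transition fraction, or a [count_substitutions()] result (in
#'   which case `Q` is ignored).
#' @param Q transversion fraction.
#' @return substitutions per site, or `NA_real_` when saturated.
#' @export
kimura2p <- function(P, Q = NULL) {
  if (inherits(P, "subst_counts")) { Q <- P$Q; P <- P$P }
  stopifnot(is.numeric(P), is.numeric(Q), P >= 0, Q >= 0)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Convert a substitution distance to an insertion age
#'
#' `age = K / (2 r)`, reported in Ma. The factor 2 reflects that both LTRs
#' accumulate substitutions independently after insertion.
#'
#' @param K substitutions per site (>= 0).
#' @param r substitution rate per site per year (default 1.3e-8, the
#'   wheat/grass LTR clock).
#' @return age in Ma.
#' @export
age_from_distance <- function(K, r = 1.3e-8) {
  if (any(K < 0, na.rm = TRUE)) stop("K must be >= 0")
  if (r <= 0) stop("r must be > 0")
  K / (2 * r) / 1e6
}

#' Date a set of elements from their LTR divergence
#'
#' For each element the 5' and 3' LTR sequences are extracted from the
#' genome, globally aligned, transition/transversion fractions counted over
#' ungapped columns, the Kimura two-parameter distance computed and converted
#' to an age in Ma. Elements whose divergence is saturated are retained with
#' `valid = FALSE` and flag `"saturated"`; elements lacking a 3' LTR get
#' flag `"missing_ltr"`. An element is *incipient* when its LTRs are still
#' identical (K exactly 0 after exclusions).
#'
#' @param elements data frame with `ltr5_start`, `ltr5_end`, `ltr3_start`,
#'   `ltr3_end` (0-based half-open), e.g. from [detect_flltrs()] or a
#'   simulation truth table.
#' @param genome character string, named character vector, or
#'   `Biostrings::DNAStringSet`; elements with a `chrom` column are looked up
#'   by name when the genome is named.
#' @param r substitution rate per site per year.
#' @param scoring alignment scores, see [align_ltr_pair()].
#' @return the input data frame extended with `n_cols`, `P`, `Q`, `K`,
#'   `age_ma`, `incipient`, `valid`, `dating_flag`.
#' @export
date_elements <- function(elements, genome, r = 1.3e-8,
                          scoring = default_scoring()) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  get_seq <- function(chrom) {
    if (length(genome) == 1 && is.null(names(genome))) return(genome[[1]])
    if (!is.null(names(genome)) && chrom %in% names(genome)) return(genome[[chrom]])
    genome[[1]]
  }
  n <- nrow(elements)
  res <- data.frame(n_cols = rep(NA_integer_, n), P = NA_real_, Q = NA_real_,
                    K = NA_real_, age_ma = NA_real_, incipient = FALSE,
                    valid = FALSE, dating_flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(elements$ltr3_start[i]) || is.na(elements$ltr3_end[i])) {
      res$dating_flag[i] <- "missing_ltr"
      next
    }
    g <- get_seq(if ("chrom" %in% names(elements)) elements$chrom[i] else "")
    l5 <- subseq0(g, elements$ltr5_start[i], elements$ltr5_end[i])
    l3 <- subseq0(g, elements$ltr3_start[i], elements$ltr3_end[i])
    aln <- align_ltr_pair(l5, l3, scoring)
    cnt <- count_substitutions(aln)
    K <- kimura2p(cnt)
    res$n_cols[i] <- cnt$n_cols
    res$P[i] <- cnt$P; res$Q[i] <- cnt$Q
    if (is.na(K)) {
      res$dating_flag[i] <- "saturated"
    } else {
      res$K[i] <- K
      res$age_ma[i] <- age_from_distance(K, r)
      res$incipient[i] <- K == 0
      res$valid[i] <- TRUE
    }
  }
  cbind(elements, res)
}

#' Write a dating table to TSV
#'
#' K is reported to 4 decimals and ages to 2 decimals (Ma).
#'
#' @param dated result of [date_elements()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dating_tsv <- function(dated, path) {
  out <- dated
  if ("K" %in% names(out)) out$K <- round(out$K, 4)
  if ("age_ma" %in% names(out)) out$age_ma <- round(out$age_ma, 2)
  write_tsv_file(out, path)
  invisible(path)
}
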