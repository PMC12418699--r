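# Ab initio detection of full-length LTR retrotransspoons from a single
# chromosome sequence. The detector finds exact seed matches between the two
# prospective LTR copies, extends them by greedy x-drop alignment, refines
# element boundaries with target-site-duplication and TG...CA motif evidence,
# filters on structural bounds and resolves overlapping candidates.
# All coordinates are 0-based half-open.

#' Structural detector parameters
#'
#' Defaults follow the parameterisation commonly used for plant genomes:
#' 30 nt exact seeds, x-drop 5 with match +2 / mismatch -2 / indel -3,
#' LTR length 100-2000 nt, 5'-to-3' LTR start distance 3-25 kb, minimum LTR
#' identity 0.85, TSD length 4-20 nt, TG...CA termini with at most one
#' mismatch, and a 60 nt boundary-search vicinity.
#'
#' @param seed_len exact seed length (nt).
#' @param xdrop x-drop termination threshold (score units).
#' @param match,mismatch,indel alignment scores.
#' @param min_ltr,max_ltr allowed LTR length range (nt).
#' @param min_dist,max_dist allowed distance between the starts of the 5' and
#'   3' LTRs (nt).
#' @param min_similarity minimal LTR pair identity (fraction).
#' @param min_tsd,max_tsd TSD length range (nt).
#' @param motif_mismatch_max allowed mismatches over the four terminal motif
#'   bases.
#' @param vicinity boundary refinement window (nt on each side).
#' @param overlap_mode overlap resolution mode (only `"best"`).
#' @param require_evidence drop elements lacking both TSD and terminal motif.
#' @return validated list of class `detector_params`.
#' @export
detector_params <- function(seed_len = 30, xdrop = 5, match = 2, mismatch = -2,
                            indel = -3, min_ltr = 100, max_ltr = 2000,
                            min_dist = 3000, max_dist = 25000,
                            min_similarity = 0.85, min_tsd = 4, max_tsd = 20,
                            motif_mismatch_max = 1, vicinity = 60,
                            overlap_mode = "best", require_evidence = TRUE) {
  p <- list(seed_len = seed_len, xdrop = xdrop, match = match,
            mismatch = mismatch, indel = indel, min_ltr = min_ltr,
            max_ltr = max_ltr, min_dist = min_dist, max_dist = max_dist,
            min_similarity = min_similarity, min_tsd = min_tsd,
            max_tsd = max_tsd, motif_mismatch_max = motif_mismatch_max,
            vicinity = vicinity, overlap_mode = overlap_mode,
            require_evidence = isTRUE(require_evidence))
  if (p$min_ltr > p$max_ltr) stop("min_ltr must be <= max_ltr")
  if (p$min_dist > p$max_dist) stop("min_dist must be <= max_dist")
  if (p$min_similarity <= 0 || p$min_similarity > 1) {
    stop("min_similarity must be in (0, 1]")
  }
  if (p$min_tsd > p$max_tsd) stop("min_tsd must be <= max_tsd")
  structure(p, class = "detector_params")
}

empty_candidates <- function() {
  data.frame(ltr5_start = numeric(0), ltr5_end = numeric(0),
             ltr3_start = numeric(0), ltr3_end = numeric(0),
             similarity = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Find candidate LTR pairs by seeded x-drop extension
#'
#' Exact `seed_len`-mer matches at offsets `(i, j)` with
#' `min_dist <= j - i <= max_dist` are clustered per diagonal and extended in
#' both directions by greedy ungapped x-drop alignment (stop when the running
#' score drops more than `xdrop` below its maximum). An extended pair is kept
#' when both copies fall within the LTR length bounds and the identity over
#' the extension reaches `min_similarity`; extensions exceeding `max_ltr`
#' (e.g. across tandem satellite arrays or whole-element matches) are
#' rejected. Overlapping candidates from seeds of the same repeat pair are
#' coalesced to the maximal-scoring extension. Soft-masked input is treated
#' as uppercase; runs of N break seeds.
#'
#' @param seq chromosome sequence (character).
#' @param params a [detector_params()].
#' @return data frame of raw candidates with 0-based half-open LTR intervals,
#'   `similarity` and extension `score`; zero rows when nothing qualifies.
#' @export
find_ltr_pairs <- function(seq, params = detector_params()) {
  s <- toupper(seq)
  n <- nchar(s)
  k <- params$seed_len
  if (n < params$min_dist + params$min_ltr) return(empty_candidates())
  starts <- seq_len(n - k + 1)
  kmers <- substring(s, starts, starts + k - 1)
  ok <- !grepl("[^ACGT]", kmers)
  dup <- ok & (duplicated(kmers) | duplicated(kmers, fromLast = TRUE))
  if (!any(dup)) return(empty_candidates())
  groups <- split(starts[dup] - 1L, kmers[dup])  # 0-based positions
  # seed pairs within the distance window
  pi <- integer(0); pj <- integer(0)
  for (g in groups) {
    if (length(g) < 2) next
    cmb <- utils::combn(sort(g), 2)
    d <- cmb[2, ] - cmb[1, ]
    keep <- d >= params$min_dist & d <= params$max_dist
    pi <- c(pi, cmb[1, keep]); pj <- c(pj, cmb[2, keep])
  }
  if (!length(pi)) return(empty_candidates())
  diag <- pj - pi
  ord <- order(diag, pi)
  pi <- pi[ord]; diag <- diag[ord]
  # cluster seeds on the same diagonal separated by <= max_ltr
  new_cluster <- c(TRUE, diff(diag) != 0 | diff(pi) > params$max_ltr)
  cl <- cumsum(new_cluster)
  sc <- seq_chars(s)
  cands <- lapply(split(seq_along(pi), cl), function(ix) {
    d <- diag[ix[1]]
    a <- min(pi[ix])               # cluster core [a, b) on copy 1, 0-based
    b <- max(pi[ix]) + k
    ext <- xdrop_extend(sc, a, b, d, n, params)
    if (is.null(ext)) return(NULL)
    len <- ext$end - ext$start
    if (len < params$min_ltr || len > params$max_ltr) return(NULL)
    if (ext$identity < params$min_similarity) return(NULL)
    data.frame(ltr5_start = ext$start, ltr5_end = ext$end,
               ltr3_start = ext$start + d, ltr3_end = ext$end + d,
               similarity = ext$identity, score = ext$score,
               stringsAsFactors = FALSE)
  })
  cands <- do.call(rbind, cands)
  if (is.null(cands) || nrow(cands) == 0) return(empty_candidates())
  coalesce_candidates(cands)
}

# greedy ungapped x-drop extension of a seed cluster [a, b) against the copy
# at diagonal offset d; returns the best-scoring extension, or NULL when the
# extension overruns the maximal LTR length (over-long repeat)
xdrop_extend <- function(sc, a, b, d, n, params) {
  mat <- params$match; mis <- params$mismatch; xd <- params$xdrop
  cap <- params$max_ltr + 1L
  score_at <- function(t) if (sc[t + 1] == sc[t + d + 1]) mat else mis
  core <- sum(ifelse(sc[(a + 1):b] == sc[(a + d + 1):(b + d)], mat, mis))
  # right extension: t = b, b+1, ... while copy 2 stays in bounds
  best <- core; run <- core; right <- b
  t <- b
  tmax <- n - d - 1
  while (t <= tmax) {
    run <- run + score_at(t)
    if (run > best) { best <- run; right <- t + 1 }
    if (run < best - xd) break
    if (right - a > cap) return(NULL)
    t <- t + 1
  }
  # left extension: t = a-1, a-2, ...
  run <- best; left <- a
  t <- a - 1
  while (t >= 0) {
    run <- run + score_at(t)
    if (run > best) { best <- run; left <- t }
    if (run < best - xd) break
    if (right - left > cap) return(NULL)
    t <- t - 1
  }
  len <- right - left
  if (len > params$max_ltr) return(NULL)
  matches <- sum(sc[(left + 1):right] == sc[(left + d + 1):(right + d)])
  list(start = left, end = right, score = best, identity = matches / len)
}

# keep the maximal-scoring candidate among sets whose 5' intervals overlap
coalesce_candidates <- function(cands) {
  cands <- cands[order(cands$ltr5_start, cands$ltr5_end), , drop = FALSE]
  grp <- integer(nrow(cands)); g <- 0L; cur_end <- -Inf
  for (i in seq_len(nrow(cands))) {
    if (cands$ltr5_start[i] >= cur_end) { g <- g + 1L; cur_end <- cands$ltr5_end[i] }
    cur_end <- max(cur_end, cands$ltr5_end[i])
    grp[i] <- g
  }
  keep <- vapply(split(seq_len(nrow(cands)), grp), function(ix) {
    ix[order(-cands$score[ix], cands$ltr5_start[ix])[1]]
  }, 0L)
  out <- cands[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine element boundaries with TSD and motif evidence
#'
#' Within `vicinity` nt of each provisional element boundary, searches for
#' (a) an exact direct repeat of 4-20 nt immediately flanking both ends (the
#' target-site duplication) and (b) TG...CA termini with at most
#' `motif_mismatch_max` mismatches over the four motif bases. Boundaries are
#' shifted to the highest-evidence placement (TSD+motif > motif-only >
#' TSD-only > none, smallest shift among ties); the evidence found is
#' recorded in `quality_flags`. Missing evidence is recorded, never fatal.
#'
#' @param candidate one-row data frame from [find_ltr_pairs()].
#' @param seq chromosome sequence (character).
#' @param params a [detector_params()].
#' @return one-row data frame describing the refined element: LTR intervals,
#'   `strand`, `ltr_similarity`, `tsd` (or `NA`), `motif_ok`, `element_span`,
#'   `quality_flags`.
#' @export
refine_boundaries <- function(candidate, seq, params = detector_params()) {
  sc <- seq_chars(seq)
  refine_boundaries_chars(candidate, sc, length(sc), params)
}

refine_boundaries_chars <- function(candidate, sc, n, params) {
  vic <- params$vicinity
  S0 <- candidate$ltr5_start; E0 <- candidate$ltr3_end
  s_cand <- unique(pmax(0, pmin(n - 4, S0 + (-vic):vic)))
  e_cand <- unique(pmax(4, pmin(n, E0 + (-vic):vic)))
  # motif mismatches at each candidate start (vs TG) and end (vs CA)
  m_start <- (sc[s_cand + 1] != "T") + (sc[s_cand + 2] != "G")
  m_end <- (sc[e_cand - 1] != "C") + (sc[e_cand] != "A")
  motif_pair_ok <- outer(m_start, m_end, "+") <= params$motif_mismatch_max

  # evidence ranking: TSD+motif (3) > motif-only (2) > TSD-only (1) > none;
  # among equal evidence the longer TSD wins (the l loop descends), then the
  # placement closest to the provisional boundaries
  best <- list(s = S0, e = E0, tsd = NA_character_, motif = FALSE)
  best_rank <- 0L; best_shift <- Inf; best_l <- -1L
  sq <- paste(sc, collapse = "")
  for (l in seq(params$max_tsd, params$min_tsd)) {
    up_idx <- which(s_cand - l >= 0)
    dn_idx <- which(e_cand + l <= n)
    if (!length(up_idx) || !length(dn_idx)) next
    up <- substring(sq, s_cand[up_idx] - l + 1, s_cand[up_idx])
    dn <- substring(sq, e_cand[dn_idx] + 1, e_cand[dn_idx] + l)
    for (str in intersect(up, dn)) {
      for (si in up_idx[up == str]) {
        for (ei in dn_idx[dn == str]) {
          mot <- motif_pair_ok[si, ei]
          rk <- if (mot) 3L else 1L
          sh <- abs(s_cand[si] - S0) + abs(e_cand[ei] - E0)
          if (rk > best_rank ||
              (rk == best_rank && l == best_l && sh < best_shift)) {
            best_rank <- rk; best_shift <- sh; best_l <- l
            best <- list(s = s_cand[si], e = e_cand[ei], tsd = str, motif = mot)
          }
        }
      }
    }
  }
  if (best_rank < 2L) {
    # a motif-only placement outranks TSD-only; prefer exact termini over
    # one-mismatch ones, then the smallest shift
    mi <- which(motif_pair_ok, arr.ind = TRUE)
    if (nrow(mi)) {
      mm <- m_start[mi[, 1]] + m_end[mi[, 2]]
      sh <- abs(s_cand[mi[, 1]] - S0) + abs(e_cand[mi[, 2]] - E0)
      b <- order(mm, sh)[1]
      best_rank <- 2L; best_shift <- sh[b]
      best <- list(s = s_cand[mi[b, 1]], e = e_cand[mi[b, 2]],
                   tsd = NA_character_, motif = TRUE)
    }
  }
  # both copies are the same repeat: a shift of the element start moves the
  # 5' boundary of both LTR copies, a shift of the element end moves both 3'
  # boundaries, keeping the copies congruent and the pair distance invariant
  ds <- best$s - S0; de <- best$e - E0
  flags <- c(if (is.na(best$tsd)) "no_tsd" else "tsd",
             if (best$motif) "motif" else "no_motif")
  data.frame(ltr5_start = best$s, ltr5_end = candidate$ltr5_end + de,
             ltr3_start = candidate$ltr3_start + ds, ltr3_end = best$e,
             strand = "+",
             ltr_similarity = candidate$similarity,
             tsd = best$tsd, motif_ok = best$motif,
             element_span = best$e - best$s,
             quality_flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Resolve overlapping elements
#'
#' Among overlapping elements the one with the highest LTR similarity is
#' kept; ties go to the longer element span, then to the leftmost start.
#' Surviving elements are non-overlapping and sorted.
#'
#' @param elements data frame of refined elements (one chromosome).
#' @param mode only `"best"` is implemented.
#' @return filtered, sorted data frame.
#' @export
resolve_overlaps <- function(elements, mode = "best") {
  if (!identical(mode, "best")) stop("unknown overlap mode: ", mode)
  if (nrow(elements) <= 1) return(elements)
  pri <- order(-elements$ltr_similarity, -elements$element_span,
               elements$ltr5_start)
  accepted <- integer(0)
  for (i in pri) {
    s <- elements$ltr5_start[i]; e <- elements$ltr3_end[i]
    clash <- any(s < elements$ltr3_end[accepted] &
                 elements$ltr5_start[accepted] < e)
    if (!clash) accepted <- c(accepted, i)
  }
  out <- elements[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect full-length LTR retrotransposons
#'
#' Orchestrates [find_ltr_pairs()], [refine_boundaries()], the structural
#' evidence filter and [resolve_overlaps()]. With
#' `params$require_evidence = TRUE` (default), candidates lacking both a TSD
#' and the terminal motif are dropped -- the integration-style filter that
#' removes structural false positives.
#'
#' @param seq chromosome sequence (character, or a length-1
#'   `Biostrings::DNAStringSet` / `DNAString`).
#' @param params a [detector_params()].
#' @param chrom chromosome name recorded in the output.
#' @return data frame of elements: `id`, `chrom`, LTR intervals (0-based
#'   half-open), `strand`, `ltr_similarity`, `tsd`, `motif_ok`,
#'   `element_span`, `quality_flags`, plus `start`/`end` aliases of the
#'   element extent.
#' @export
detect_flltrs <- function(seq, params = detector_params(), chrom = "chr1") {
  if (inherits(seq, "DNAStringSet")) seq <- as.character(seq[[1]])
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  cands <- find_ltr_pairs(seq, params)
  if (nrow(cands) == 0) return(empty_flltrs(chrom))
  sc <- seq_chars(seq)
  n <- length(sc)
  refined <- do.call(rbind, lapply(seq_len(nrow(cands)), function(i) {
    refine_boundaries_chars(cands[i, , drop = FALSE], sc, n, params)
  }))
  if (params$require_evidence) {
    refined <- refined[!is.na(refined$tsd) | refined$motif_ok, , drop = FALSE]
  }
  # enforce structural bounds post refinement
  l5 <- refined$ltr5_end - refined$ltr5_start
  l3 <- refined$ltr3_end - refined$ltr3_start
  dd <- refined$ltr3_start - refined$ltr5_start
  keep <- l5 >= params$min_ltr & l5 <= params$max_ltr &
    l3 >= params$min_ltr & l3 <= params$max_ltr &
    dd >= params$min_dist & dd <= params$max_dist &
    refined$ltr_similarity >= params$min_similarity &
    refined$ltr5_end <= refined$ltr3_start
  refined <- refined[keep, , drop = FALSE]
  if (nrow(refined) == 0) return(empty_flltrs(chrom))
  out <- resolve_overlaps(refined, params$overlap_mode)
  out$chrom <- chrom
  out$start <- out$ltr5_start
  out$end <- out$ltr3_end
  out$id <- sprintf("flltr%03d", seq_len(nrow(out)))
  out[, c("id", "chrom", "start", "end", "ltr5_start", "ltr5_end",
          "ltr3_start", "ltr3_end", "strand", "ltr_similarity", "tsd",
          "motif_ok", "element_span", "quality_flags")]
}

empty_flltrs <- function(chrom = character(0)) {
  data.frame(id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), ltr5_start = numeric(0), ltr5_end = numeric(0),
             ltr3_start = numeric(0), ltr3_end = numeric(0),
             strand = character(0), ltr_similarity = numeric(0),
             tsd = character(0), motif_ok = logical(0),
             element_span = numeric(0), quality_flags = character(0),
             stringsAsFactors = FALSE)
}
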