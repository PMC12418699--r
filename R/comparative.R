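# Comparative analytics: window dot plots, satellite monomer identity
# matrices, insertion-age distributions, exact/approximate Mann-Whitney U,
# ancestral/derived region partitioning and family copy tables.

# ---------------------------------------------------------------------------
# dot plots

#' Window dot plot between two sequences
#'
#' Non-overlapping windows of `seq_a` are compared to non-overlapping windows
#' of `seq_b` in both orientations; window pairs whose global alignment
#' identity reaches `min_identity` are reported with their orientation. A
#' shared-word prefilter skips window pairs that cannot reach the identity
#' threshold.
#'
#' @param seq_a,seq_b sequences (character).
#' @param window window size in nt (common choices: 500 for centromere-scale
#'   comparisons, 300 for finer structure).
#' @param min_identity minimal reported identity (fraction).
#' @return object of class `dotplot`: data frame `matches` with `x_window`,
#'   `y_window` (0-based window indices), `orientation`
#'   (`forward`/`reverse`), `identity`; plus window metadata.
#' @export
dotplot <- function(seq_a, seq_b, window = 500, min_identity = 0.85) {
  if (window <= 0) stop("window must be positive")
  if (window > min(nchar(seq_a), nchar(seq_b))) {
    stop("window larger than the shorter sequence")
  }
  wa <- window_starts(nchar(seq_a), window)
  wb <- window_starts(nchar(seq_b), window)
  a_win <- substring(toupper(seq_a), wa + 1, wa + window)
  b_win <- substring(toupper(seq_b), wb + 1, wb + window)
  b_rc <- vapply(b_win, revcomp, "")
  k <- 12L
  idx_f <- kmer_index(b_win, k)
  idx_r <- kmer_index(b_rc, k)
  rows <- list()
  for (i in seq_along(a_win)) {
    km <- unique(window_kmers(a_win[i], k))
    for (ornt in c("forward", "reverse")) {
      idx <- if (ornt == "forward") idx_f else idx_r
      cand <- sort(unique(unlist(idx[km], use.names = FALSE)))
      for (j in cand) {
        other <- if (ornt == "forward") b_win[j] else b_rc[j]
        pid <- alignment_identity(a_win[i], other)
        if (pid >= min_identity) {
          rows[[length(rows) + 1]] <- data.frame(
            x_window = i - 1L, y_window = j - 1L, orientation = ornt,
            identity = pid, stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_window = integer(0), y_window = integer(0),
               orientation = character(0), identity = numeric(0))
  structure(list(window = window, min_identity = min_identity,
                 n_x = length(wa), n_y = length(wb), matches = matches),
            class = "dotplot")
}

window_starts <- function(n, window) seq(0, n - window, by = window)

window_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# map k-mer -> window indices containing it
kmer_index <- function(wins, k) {
  km <- lapply(wins, window_kmers, k = k)
  idx <- rep(seq_along(wins), lengths(km))
  split(idx, unlist(km, use.names = FALSE))
}

#' @export
print.dotplot <- function(x, ...) {
  cat(sprintf("Dot plot: %d x %d windows of %d nt, %d matches >= %.2f identity\n",
              x$n_x, x$n_y, x$window, nrow(x$matches), x$min_identity))
  invisible(x)
}

# ---------------------------------------------------------------------------
# satellite monomers

#' Chop a satellite array into monomers and compute their identity matrix
#'
#' Consecutive `unit_len` monomers are cut from the array (a trailing
#' remainder shorter than `unit_len` is dropped and its length recorded);
#' all monomer pairs are globally aligned and their identity collected into a
#' symmetric matrix with unit diagonal -- the satellite similarity heatmap.
#'
#' @param array_seq tandem array sequence.
#' @param unit_len monomer length in nt (e.g. 566 or 550 for the wheat
#'   centromeric satellites).
#' @return list with `monomers` (character vector), `identity` (matrix) and
#'   `remainder` (nt dropped).
#' @export
monomerize_and_heatmap <- function(array_seq, unit_len) {
  if (unit_len <= 0) stop("unit_len must be positive")
  n <- nchar(array_seq)
  if (n < unit_len) stop("array shorter than one unit")
  k <- n %/% unit_len
  starts <- (seq_len(k) - 1) * unit_len
  monomers <- substring(toupper(array_seq), starts + 1, starts + unit_len)
  m <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        m[i, j] <- m[j, i] <- alignment_identity(monomers[i], monomers[j])
      }
    }
  }
  list(monomers = monomers, identity = m, remainder = n - k * unit_len)
}

# ---------------------------------------------------------------------------
# age distributions

#' Summarise an insertion-age cohort
#'
#' Median and quartiles, count of incipient elements (age exactly 0, i.e.
#' identical LTRs) and a Gaussian kernel density estimate (Silverman's
#' rule-of-thumb bandwidth by default).
#'
#' @param ages insertion ages in Ma (n >= 1).
#' @param group cohort label.
#' @param bandwidth `"silverman"` or a numeric bandwidth in Ma.
#' @return object of class `age_summary` with `group`, `n`, `median`, `q1`,
#'   `q3`, `incipient_count`, `grid`, `density`, `bandwidth`.
#' @export
age_distribution <- function(ages, group = "all", bandwidth = "silverman") {
  if (length(ages) == 0) stop("empty age vector")
  if (any(ages < 0)) stop("ages must be >= 0")
  qs <- stats::quantile(ages, c(0.25, 0.5, 0.75), names = FALSE)
  bw <- if (identical(bandwidth, "silverman")) {
    if (length(ages) >= 2 && stats::sd(ages) > 0) stats::bw.nrd0(ages) else 0.05
  } else as.numeric(bandwidth)
  d <- stats::density(ages, bw = bw)
  structure(list(group = group, n = length(ages), median = qs[2],
                 q1 = qs[1], q3 = qs[3],
                 incipient_count = sum(ages == 0),
                 grid = d$x, density = d$y, bandwidth = bw),
            class = "age_summary")
}

#' @export
print.age_summary <- function(x, ...) {
  cat(sprintf("Age summary [%s]: n = %d, median = %.2f Ma (IQR %.2f-%.2f), incipient = %d\n",
              x$group, x$n, x$median, x$q1, x$q3, x$incipient_count))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mann-Whitney U

#' Mann-Whitney U test (exact enumeration or normal approximation)
#'
#' `U` is computed from rank sums with midranks for ties. In `exact` mode
#' (default for `n_x + n_y <= 12`) the p-value is obtained by full
#' enumeration of all group assignments of the observed rank multiset, which
#' remains valid under ties. Otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. When every value
#' in both groups is identical, `p = 1` with flag `"degenerate"`.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x` relative
#'   to `y`).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U` (for `x`), `U_y`, `p`, `method`, `flag`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  U_y <- nx * ny - U
  if (length(unique(c(x, y))) == 1) {
    return(list(U = U, U_y = U_y, p = 1, method = "degenerate", flag = "degenerate"))
  }
  if (mode == "auto") mode <- if (nx + ny <= 12) "exact" else "normal"
  if (mode == "exact") {
    combos <- utils::combn(nx + ny, nx)
    Ustar <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- switch(alternative,
      less = mean(Ustar <= U),
      greater = mean(Ustar >= U),
      two.sided = mean(abs(Ustar - mu) >= abs(U - mu) - 1e-12)
    )
    list(U = U, U_y = U_y, p = p, method = "exact", flag = "")
  } else {
    n <- nx + ny
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    mu <- nx * ny / 2
    sigma <- sqrt(sigma2)
    cc <- 0.5
    p <- switch(alternative,
      less = stats::pnorm((U - mu + cc) / sigma),
      greater = stats::pnorm((mu - U + cc) / sigma),
      two.sided = 2 * stats::pnorm((-abs(U - mu) + cc) / sigma)
    )
    list(U = U, U_y = U_y, p = min(1, p), method = "normal", flag = "")
  }
}

# ---------------------------------------------------------------------------
# region partitioning

REGION_CLASSES <- c(ancestral_one = 1L, derived_only = 2L, ancestral_some = 3L,
                    neither = 4L, ancestral_all = 5L)

#' Partition a domain by ancestral and derived centromere coverage
#'
#' Every base of the domain is labelled by how many ancestral accessions'
#' CENH3 interval sets cover it and whether the derived (e.g. hexaploid)
#' set covers it. Classes: covered by exactly one ancestral set
#' (`ancestral_one`, region 1), by some but not all (`ancestral_some`,
#' region 3), by all (`ancestral_all`, region 5); covered only by the derived
#' set (`derived_only`, region 2); covered by neither (`neither`, region 4).
#' Contiguous same-class runs are emitted as segments tiling the domain
#' exactly.
#'
#' @param ancestral_sets list of interval sets, one per accession; each a
#'   data frame / matrix with `start`, `end` columns (0-based half-open nt).
#' @param derived one interval set for the derived genome.
#' @param domain `[start, end)` domain interval.
#' @return object of class `region_partition`: data frame `segments` with
#'   `start`, `end`, `class`, `region`, plus `domain` and `n_ancestral`.
#' @export
partition_regions <- function(ancestral_sets, derived, domain) {
  check_interval(domain, "domain")
  as_mat <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
      return(matrix(numeric(0), 0, 2))
    }
    m <- as.matrix(as.data.frame(x)[, c("start", "end")])
    if (any(m[, 1] < domain[1] | m[, 2] > domain[2])) {
      stop("interval outside domain")
    }
    m
  }
  anc <- lapply(ancestral_sets, as_mat)
  der <- as_mat(derived)
  k <- length(anc)
  bps <- sort(unique(c(domain, unlist(lapply(anc, as.vector)), as.vector(der))))
  bps <- bps[bps >= domain[1] & bps <= domain[2]]
  seg_start <- bps[-length(bps)]
  seg_end <- bps[-1]
  covers <- function(m, p) if (nrow(m) == 0) FALSE else any(m[, 1] <= p & p < m[, 2])
  mids <- (seg_start + seg_end) / 2
  anc_count <- vapply(mids, function(p) sum(vapply(anc, covers, TRUE, p = p)), 0L)
  der_cov <- vapply(mids, function(p) covers(der, p), TRUE)
  cls <- ifelse(anc_count == 0 & der_cov, "derived_only",
         ifelse(anc_count == 0, "neither",
         ifelse(anc_count == k, "ancestral_all",
         ifelse(anc_count == 1, "ancestral_one", "ancestral_some"))))
  # merge adjacent equal-class segments
  run <- cumsum(c(TRUE, cls[-1] != cls[-length(cls)]))
  segments <- data.frame(
    start = vapply(split(seg_start, run), min, 0),
    end = vapply(split(seg_end, run), max, 0),
    class = vapply(split(cls, run), `[`, "", 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  segments$region <- unname(REGION_CLASSES[segments$class])
  structure(list(domain = domain, n_ancestral = k, segments = segments),
            class = "region_partition")
}

#' Summarise insertion ages per region class
#'
#' Elements are assigned to partition segments by element midpoint; each
#' class with at least one element receives an [age_distribution()] summary,
#' and all class pairs are compared with [mann_whitney_u()]. Classes with no
#' elements are omitted and listed in attribute `empty_classes`.
#'
#' @param dated data frame with `start`, `end`, `age_ma` (e.g. from
#'   [date_elements()]).
#' @param partition a [partition_regions()] result.
#' @return list with `summaries` (named list of `age_summary`) and `tests`
#'   (data frame of pairwise U tests).
#' @export
region_age_summary <- function(dated, partition) {
  segs <- partition$segments
  mid <- (dated$start + dated$end) / 2
  seg_of <- findInterval(mid, segs$start)
  seg_of[mid < partition$domain[1] | mid >= partition$domain[2]] <- NA
  cls <- segs$class[seg_of]
  keep <- !is.na(cls) & !is.na(dated$age_ma)
  ages_by <- split(dated$age_ma[keep], cls[keep])
  summaries <- lapply(names(ages_by), function(cl) {
    age_distribution(ages_by[[cl]], group = cl)
  })
  names(summaries) <- names(ages_by)
  pairs <- if (length(ages_by) >= 2) utils::combn(names(ages_by), 2) else NULL
  tests <- if (!is.null(pairs)) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      mw <- mann_whitney_u(ages_by[[a]], ages_by[[b]], "two.sided")
      data.frame(class_a = a, class_b = b, U = mw$U, p = mw$p,
                 median_a = stats::median(ages_by[[a]]),
                 median_b = stats::median(ages_by[[b]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(class_a = character(0), class_b = character(0), U = numeric(0),
               p = numeric(0), median_a = numeric(0), median_b = numeric(0))
  }
  out <- list(summaries = summaries, tests = tests)
  attr(out, "empty_classes") <- setdiff(unique(segs$class), names(ages_by))
  out
}

# ---------------------------------------------------------------------------
# copy tables

#' Family-by-centromere copy table with superfamily roll-up
#'
#' Elements are assigned to a centromere call when their midpoint falls in
#' its interval; counts are tabulated family x centromere, and superfamily
#' percentages over all counted elements are reported to one decimal
#' (half-up).
#'
#' @param assignments data frame with `chrom`, `start`, `end`, `family_id`,
#'   `superfamily`.
#' @param centromere_calls data frame with `chrom`, `start`, `end` (one row
#'   per centromere).
#' @return list with `counts` (family x centromere matrix),
#'   `superfamily_pct` (named numeric) and `total`.
#' @export
crw_copy_table <- function(assignments, centromere_calls) {
  fams <- sort(unique(assignments$family_id))
  cens <- centromere_calls$chrom
  counts <- matrix(0L, length(fams), length(cens),
                   dimnames = list(fams, cens))
  in_any <- rep(FALSE, nrow(assignments))
  if (nrow(assignments)) {
    mid <- (assignments$start + assignments$end) / 2
    for (ci in seq_along(cens)) {
      inside <- assignments$chrom == centromere_calls$chrom[ci] &
        mid >= centromere_calls$start[ci] & mid < centromere_calls$end[ci]
      in_any <- in_any | inside
      if (any(inside)) {
        tab <- table(assignments$family_id[inside])
        counts[names(tab), ci] <- counts[names(tab), ci] + as.integer(tab)
      }
    }
  }
  total <- sum(in_any)
  pct <- superfamily_percentages(table(assignments$superfamily[in_any]))
  list(counts = counts, superfamily_pct = pct, total = total)
}

#' Superfamily percentage roll-up
#'
#' @param counts named numeric vector of element counts per superfamily.
#' @return named percentages of the total, one decimal, half-up rounding.
#' @export
superfamily_percentages <- function(counts) {
  counts <- unlist(as.list(counts))
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(round_half_up(100 * counts / tot, 1), names(counts))
}
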