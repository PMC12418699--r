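# CENH3 ChIP/Input enrichment: log2 ratio tracks, centromere delimitation,
# Table-style size summaries and between-sample signal correlation.

#' Compute a binned log2(ChIP/Input) ratio track
#'
#' Both tracks are scaled to counts per million by default (their own library
#' sizes), then `value_i = log2((chip_i + eps) / (input_i + eps))` per bin.
#' The pseudocount keeps values finite in empty bins. With
#' `normalize = "none"` raw counts are compared directly, which preserves a
#' global fold change between libraries.
#'
#' @param chip,input [coverage_track()]s with identical chromosome, bin size
#'   and bin count.
#' @param epsilon pseudocount added to both scaled signals (default 0.5).
#' @param normalize `"cpm"` (default) or `"none"`.
#' @return an object of class `ratio_track`.
#' @export
compute_ratio_track <- function(chip, input, epsilon = 0.5,
                                normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$chrom != input$chrom || chip$bin_size != input$bin_size ||
      length(chip$counts) != length(input$counts)) {
    stop("mismatched binning between chip and input tracks")
  }
  if (any(chip$counts < 0) || any(input$counts < 0)) stop("negative counts")
  scale_cpm <- function(x) {
    tot <- sum(x)
    if (tot <= 0) stop("cannot CPM-scale a track with zero total counts")
    x / tot * 1e6
  }
  c_val <- if (normalize == "cpm") scale_cpm(chip$counts) else chip$counts
  i_val <- if (normalize == "cpm") scale_cpm(input$counts) else input$counts
  values <- log2((c_val + epsilon) / (i_val + epsilon))
  structure(list(chrom = chip$chrom, bin_size = chip$bin_size,
                 values = values, chrom_length = chip$chrom_length,
                 normalization = normalize, epsilon = epsilon),
            class = "ratio_track")
}

#' Delimit CENH3-enriched intervals from a ratio track
#'
#' Maximal runs of bins at or above `threshold` are taken as candidate
#' domains; runs separated by less than `merge_gap` are merged, merged runs
#' shorter than `min_len` are dropped, and the longest surviving interval per
#' chromosome is flagged as the primary centromere call. Raising the
#' threshold can only shrink calls.
#'
#' @param track a [compute_ratio_track()] result.
#' @param threshold log2 enrichment cutoff (default 1.0, i.e. 2-fold).
#' @param merge_gap maximal gap (nt) between runs that are merged.
#' @param min_len minimal surviving interval length (nt).
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open nt), `length_mb`, `mean_log2`, `primary`; zero rows when
#'   nothing is enriched.
#' @export
call_enriched_intervals <- function(track, threshold = 1.0,
                                    merge_gap = 500000, min_len = 500000) {
  stopifnot(inherits(track, "ratio_track"))
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      length_mb = numeric(0), mean_log2 = numeric(0),
                      primary = logical(0), stringsAsFactors = FALSE)
  above <- track$values >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_bin <- cumsum(r$lengths)
  starts_bin <- ends_bin - r$lengths + 1
  keep <- r$values
  iv <- cbind(start = (starts_bin[keep] - 1) * track$bin_size,
              end = pmin(ends_bin[keep] * track$bin_size, track$chrom_length))
  # merge runs separated by < merge_gap
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv[i, "start"] - merged[last, "end"] < merge_gap) {
        merged[last, "end"] <- iv[i, "end"]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
  }
  len <- merged[, "end"] - merged[, "start"]
  merged <- merged[len >= min_len, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  mean_log2 <- vapply(seq_len(nrow(merged)), function(i) {
    b0 <- floor(merged[i, "start"] / track$bin_size) + 1
    b1 <- ceiling(merged[i, "end"] / track$bin_size)
    mean(track$values[b0:b1])
  }, 0)
  len <- merged[, "end"] - merged[, "start"]
  primary <- seq_along(len) == which.max(len)
  out <- data.frame(chrom = track$chrom, start = merged[, "start"],
                    end = merged[, "end"],
                    length_mb = round_half_up(len / 1e6, 1),
                    mean_log2 = mean_log2, primary = primary,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Summarize centromere calls per chromosome and subgenome
#'
#' Reports each interval's length in Mb (one decimal, half-up rounding, the
#' dialect of published wheat centromere tables) and per-subgenome
#' minimum / maximum / mean of those rounded lengths.
#'
#' @param calls data frame with `chrom` plus either `start`,`end` in nt or
#'   `start_mb`,`end_mb` in Mb.
#' @param subgenome_map named character vector mapping chromosome to
#'   subgenome label; every chromosome in `calls` must be present.
#' @return list of class `centromere_summary` with `per_chromosome` and
#'   `per_subgenome` data frames.
#' @export
summarize_centromeres <- function(calls, subgenome_map) {
  stopifnot(is.data.frame(calls), nrow(calls) > 0)
  if (all(c("start_mb", "end_mb") %in% names(calls))) {
    len_mb <- calls$end_mb - calls$start_mb
    start_mb <- calls$start_mb; end_mb <- calls$end_mb
  } else {
    len_mb <- (calls$end - calls$start) / 1e6
    start_mb <- calls$start / 1e6; end_mb <- calls$end / 1e6
  }
  missing <- setdiff(calls$chrom, names(subgenome_map))
  if (length(missing)) {
    stop("chromosome(s) missing from subgenome map: ", paste(missing, collapse = ", "))
  }
  per_chrom <- data.frame(chrom = calls$chrom,
                          subgenome = unname(subgenome_map[calls$chrom]),
                          start_mb = start_mb, end_mb = end_mb,
                          length_mb = round_half_up(len_mb, 1),
                          stringsAsFactors = FALSE)
  sgs <- split(per_chrom$length_mb, per_chrom$subgenome)
  per_sub <- data.frame(
    subgenome = names(sgs),
    n = vapply(sgs, length, 0L),
    min_mb = round_half_up(vapply(sgs, min, 0), 1),
    max_mb = round_half_up(vapply(sgs, max, 0), 1),
    mean_mb = round_half_up(vapply(sgs, mean, 0), 1),
    stringsAsFactors = FALSE
  )
  rownames(per_sub) <- NULL
  structure(list(per_chromosome = per_chrom, per_subgenome = per_sub),
            class = "centromere_summary")
}

#' @export
print.centromere_summary <- function(x, ...) {
  cat("Centromere size summary (Mb, half-up to one decimal)\n")
  print(x$per_subgenome, row.names = FALSE)
  invisible(x)
}

#' Correlate two enrichment tracks
#'
#' Pearson correlation of per-bin log2 ratios over a region (or the whole
#' chromosome), as used to compare CENH3 placement between samples or
#' generations.
#'
#' @param a,b `ratio_track`s with identical binning.
#' @param region optional `[start, end)` interval in nt; bins are selected by
#'   midpoint.
#' @return list with `pearson_r`, `r_squared`, `n_bins`.
#' @export
signal_correlation <- function(a, b, region = NULL) {
  stopifnot(inherits(a, "ratio_track"), inherits(b, "ratio_track"))
  if (a$bin_size != b$bin_size || length(a$values) != length(b$values)) {
    stop("mismatched binning")
  }
  idx <- seq_along(a$values)
  if (!is.null(region)) {
    check_interval(region)
    mids <- (idx - 0.5) * a$bin_size
    idx <- idx[mids >= region[1] & mids < region[2]]
  }
  if (length(idx) < 3) stop("need at least 3 bins for correlation")
  x <- a$values[idx]; y <- b$values[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in region")
  r <- stats::cor(x, y)
  list(pearson_r = r, r_squared = r^2, n_bins = length(idx))
}
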