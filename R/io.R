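# File-format readers and writers. Internal coordinates are 0-based
# half-open everywhere; conversion to the 1-based inclusive GFF3 convention
# happens only at the format boundary. Parsing and serialisation of the
# standard formats is delegated to rtracklayer / Biostrings / ape, with
# package-level validation on top.

#' Read / write FASTA
#'
#' Sequences are returned as an uppercase named character vector.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), sub("[[:space:]].*$", "", names(ss)))
}

#' @param seqs named character vector (or `DNAStringSet`).
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' @param x data frame with `chrom`, `start`, `end` (+ optional `name`).
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1, x$end))
  if (!is.null(x$name)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' Intervals must be non-overlapping within each chromosome; overlapping
#' records are rejected.
#'
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end`, `score` (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   score = gr$score, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("bedGraph has overlapping intervals on ", ch)
    }
  }
  rownames(df) <- NULL
  df
}

#' Convert a uniform-bin bedGraph data frame to a coverage track
#'
#' @param df a [read_bedgraph()] result covering one chromosome with
#'   constant-width bins (last bin may be shorter).
#' @return a [coverage_track()].
#' @export
bedgraph_to_track <- function(df) {
  stopifnot(length(unique(df$chrom)) == 1)
  widths <- df$end - df$start
  bin <- widths[1]
  if (nrow(df) > 1 && any(widths[-nrow(df)] != bin)) {
    stop("bins are not of constant width")
  }
  coverage_track(df$chrom[1], bin, df$score, max(df$end))
}

#' @param track a [coverage_track()] (or a `ratio_track`).
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  vals <- track$counts %||% track$values
  nb <- length(vals)
  starts <- (seq_len(nb) - 1) * track$bin_size
  ends <- pmin(starts + track$bin_size, track$chrom_length)
  gr <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(starts + 1, ends),
                               score = vals)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write detected or simulated elements to GFF3
#'
#' Each element becomes one `LTR_retrotransposon` feature with two
#' `long_terminal_repeat` children; attributes carry `family_id`,
#' `true_age_Ma`, `tsd`, `ltr_similarity`, `motif_ok` when present.
#'
#' @param elements element data frame (0-based half-open coordinates).
#' @param path output file.
#' @param source GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path, source = "cenarch") {
  n <- nrow(elements)
  ids <- elements$id %||% sprintf("elem%03d", seq_len(n))
  rows <- character(0)
  fmt_attr <- function(...) {
    kv <- c(...)
    kv <- kv[!is.na(kv) & nzchar(kv)]
    paste(kv, collapse = ";")
  }
  opt <- function(key, val) {
    if (is.null(val) || is.na(val)) "" else paste0(key, "=", val)
  }
  for (i in seq_len(n)) {
    e <- elements[i, ]
    attrs <- fmt_attr(paste0("ID=", ids[i]),
                      opt("family_id", e$family_id),
                      opt("superfamily", e$superfamily),
                      opt("true_age_Ma", e$true_age_ma),
                      opt("tsd", e$tsd),
                      opt("ltr_similarity", e$ltr_similarity),
                      opt("motif", if (is.null(e$motif_ok)) NA else
                        if (isTRUE(e$motif_ok)) "TGCA" else "none"),
                      opt("truncated", if (is.null(e$truncated)) NA else
                        tolower(as.character(e$truncated))))
    rows <- c(rows, paste(e$chrom, source, "LTR_retrotransposon",
                          e$start + 1, e$end, ".", e$strand %||% "+", ".",
                          attrs, sep = "\t"))
    add_ltr <- function(s0, e0, which) {
      if (is.na(s0) || is.na(e0)) return()
      rows <<- c(rows, paste(e$chrom, source, "long_terminal_repeat",
                             s0 + 1, e0, ".", e$strand %||% "+", ".",
                             fmt_attr(paste0("ID=", ids[i], "_", which),
                                      paste0("Parent=", ids[i])),
                             sep = "\t"))
    }
    add_ltr(e$ltr5_start, e$ltr5_end, "ltr5")
    add_ltr(e$ltr3_start, e$ltr3_end, "ltr3")
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read an elements GFF3 back into a data frame
#'
#' Reconstructs 0-based half-open element and LTR intervals from the parent
#' `LTR_retrotransposon` features and their `long_terminal_repeat` children.
#'
#' @param path GFF3 file written by [write_elements_gff3()] (or compatible).
#' @return element data frame.
#' @export
read_elements_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_parent <- md$type == "LTR_retrotransposon"
  parents <- gr[is_parent]
  kids <- gr[md$type == "long_terminal_repeat"]
  pmd <- S4Vectors::mcols(parents)
  kmd <- S4Vectors::mcols(kids)
  pick <- function(col, default = NA) {
    if (col %in% names(pmd)) {
      v <- pmd[[col]]
      if (is.list(v)) v <- vapply(v, function(z) if (length(z)) z[[1]] else NA_character_, "")
      v
    } else rep(default, length(parents))
  }
  out <- data.frame(
    id = pmd$ID,
    chrom = as.character(GenomicRanges::seqnames(parents)),
    start = GenomicRanges::start(parents) - 1,
    end = GenomicRanges::end(parents),
    ltr5_start = NA_real_, ltr5_end = NA_real_,
    ltr3_start = NA_real_, ltr3_end = NA_real_,
    strand = as.character(GenomicRanges::strand(parents)),
    stringsAsFactors = FALSE
  )
  out$strand[out$strand == "*"] <- "+"
  fam <- pick("family_id"); if (!all(is.na(fam))) out$family_id <- fam
  sup <- pick("superfamily"); if (!all(is.na(sup))) out$superfamily <- sup
  age <- pick("true_age_Ma"); if (!all(is.na(age))) out$true_age_ma <- as.numeric(age)
  tsd <- pick("tsd"); if (!all(is.na(tsd))) out$tsd <- tsd
  sim <- pick("ltr_similarity"); if (!all(is.na(sim))) out$ltr_similarity <- as.numeric(sim)
  tru <- pick("truncated"); if (!all(is.na(tru))) out$truncated <- tru == "true"
  if (length(kids)) {
    par_of <- vapply(kmd$Parent, function(z) if (length(z)) z[[1]] else NA_character_, "")
    for (i in seq_len(nrow(out))) {
      mine <- which(par_of == out$id[i])
      if (length(mine)) {
        ks <- GenomicRanges::start(kids)[mine] - 1
        ke <- GenomicRanges::end(kids)[mine]
        o <- order(ks)
        out$ltr5_start[i] <- ks[o[1]]; out$ltr5_end[i] <- ke[o[1]]
        if (length(mine) > 1) {
          out$ltr3_start[i] <- ks[o[2]]; out$ltr3_end[i] <- ke[o[2]]
        }
      }
    }
  }
  out
}

#' Write / read a Newick tree
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `path` (write) or a `phylo` (read).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

# plain TSV helpers
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# ---------------------------------------------------------------------------
# bundled survey tables

#' Published wheat centromere intervals
#'
#' The CENH3-delimited centromere intervals of the 21 chromosomes of
#' hexaploid wheat (cv. Chinese Spring), as reported in the wheat centromere
#' survey literature: pseudomolecule positions in Mb per chromosome, with the
#' subgenome derived from the chromosome name.
#'
#' @return data frame with `chrom`, `start_mb`, `end_mb`, `subgenome`.
#' @export
wheat_centromere_intervals <- function() {
  df <- read_tsv_file(system.file("extdata", "taestivum_cenh3_intervals.tsv",
                                  package = "cenarch", mustWork = TRUE))
  df$subgenome <- paste0(sub("^[0-9]+", "", df$chrom), sub("^[0-9]+", "", df$chrom))
  df
}

#' Published wheat centromeric flLTR-RT counts
#'
#' Survey counts of full-length LTR retrotransposons in the functional
#' centromeres of hexaploid wheat: per superfamily (Gypsy / Copia / unknown)
#' or per subgenome (AA / BB / DD).
#'
#' @param type `"superfamily"` or `"subgenome"`.
#' @return named integer vector of counts.
#' @export
wheat_crw_counts <- function(type = c("superfamily", "subgenome")) {
  type <- match.arg(type)
  f <- system.file("extdata", paste0("taestivum_crw_", type, "_counts.tsv"),
                   package = "cenarch", mustWork = TRUE)
  df <- read_tsv_file(f)
  stats::setNames(as.integer(df$count), df[[1]])
}
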