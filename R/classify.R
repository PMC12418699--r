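# Family classification of detected elements against a labelled consensus
# library, K2P pairwise distances, an in-package neighbor-joining tree and
# nearest-reference clade assignment.

#' Build a family consensus library
#'
#' @param entries data frame with columns `family_id`, `superfamily`
#'   (`Gypsy` / `Copia` / `unknown`) and `consensus` (DNA string), or a list
#'   of [family_consensus()] objects.
#' @param min_identity minimal global alignment identity for an assignment
#'   (default 0.80).
#' @return object of class `family_library`.
#' @export
family_library <- function(entries, min_identity = 0.80) {
  if (is.list(entries) && !is.data.frame(entries) &&
      all(vapply(entries, inherits, TRUE, "family_consensus"))) {
    entries <- data.frame(
      family_id = vapply(entries, `[[`, "", "family_id"),
      superfamily = vapply(entries, `[[`, "", "superfamily"),
      consensus = vapply(entries, full_element_seq, ""),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(entries),
            all(c("family_id", "superfamily", "consensus") %in% names(entries)))
  if (anyDuplicated(entries$family_id)) stop("family_ids must be unique")
  if (any(nchar(entries$consensus) < 100)) stop("consensus sequences must be >= 100 nt")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]")
  structure(list(entries = entries, min_identity = min_identity),
            class = "family_library")
}

#' Read a family library from FASTA
#'
#' Headers carry `family=...;superfamily=...` attributes, e.g.
#' `>CRW3 family=CRW3;superfamily=Gypsy`.
#'
#' @param path FASTA file.
#' @param min_identity assignment threshold.
#' @return a [family_library()].
#' @export
read_family_library <- function(path, min_identity = 0.80) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  get_attr <- function(h, key, default) {
    m <- regmatches(h, regexec(paste0(key, "=([^;[:space:]]+)"), h))[[1]]
    if (length(m) == 2) m[2] else default
  }
  fam <- vapply(hdr, function(h) get_attr(h, "family", strsplit(h, "[[:space:]]")[[1]][1]), "")
  sup <- vapply(hdr, function(h) get_attr(h, "superfamily", "unknown"), "")
  family_library(data.frame(family_id = unname(fam), superfamily = unname(sup),
                            consensus = as.character(ss), stringsAsFactors = FALSE),
                 min_identity = min_identity)
}

# global alignment identity over aligned columns (gaps count as mismatches)
alignment_identity <- function(a, b, scoring = default_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                  mismatch = scoring$mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b),
                                      substitutionMatrix = mat,
                                      gapOpening = 0,
                                      gapExtension = -scoring$gap,
                                      type = "global")
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Assign an element to its best-matching family
#'
#' The element is aligned against every library consensus; the family with
#' the highest identity is assigned when that identity reaches the library's
#' `min_identity`, otherwise the element is reported as `"other"` with
#' superfamily `"unknown"`. Identity is computed over aligned columns of a
#' full-length global alignment (gaps count as mismatches), so short chance
#' word matches cannot drive an assignment.
#'
#' @param element_seq element sequence (non-empty character string).
#' @param library a [family_library()].
#' @return list with `family_id`, `superfamily`, `identity`.
#' @export
best_hit_assign <- function(element_seq, library) {
  stopifnot(inherits(library, "family_library"))
  if (!nzchar(element_seq)) stop("empty element sequence")
  if (nrow(library$entries) == 0) stop("empty family library")
  ids <- vapply(library$entries$consensus, alignment_identity, 0, a = element_seq)
  top <- which.max(ids)
  if (ids[top] >= library$min_identity) {
    list(family_id = library$entries$family_id[top],
         superfamily = library$entries$superfamily[top],
         identity = unname(ids[top]))
  } else {
    list(family_id = "other", superfamily = "unknown",
         identity = unname(ids[top]))
  }
}

#' Assign many elements against a library
#'
#' @param seqs character vector of element sequences (names kept as ids).
#' @param library a [family_library()].
#' @return data frame with `id`, `family_id`, `superfamily`, `identity`.
#' @export
assign_families <- function(seqs, library) {
  res <- lapply(seqs, best_hit_assign, library = library)
  data.frame(id = names(seqs) %||% sprintf("seq%03d", seq_along(seqs)),
             family_id = vapply(res, `[[`, "", "family_id"),
             superfamily = vapply(res, `[[`, "", "superfamily"),
             identity = vapply(res, `[[`, 0, "identity"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise Kimura two-parameter distance matrix
#'
#' Each pair is globally aligned and its K2P distance computed as in the
#' dating module. Saturated pairs are set to 1.1 times the largest finite
#' distance and flagged (attribute `saturated_pairs`). K2P distances need not
#' satisfy the triangle inequality.
#'
#' @param seqs named character vector of >= 3 sequences.
#' @param scoring alignment scores.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(seqs, scoring = default_scoring()) {
  n <- length(seqs)
  if (n < 3) stop("need at least 3 sequences")
  labs <- names(seqs) %||% sprintf("seq%03d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- align_ltr_pair(seqs[[i]], seqs[[j]], scoring)
      K <- kimura2p(count_substitutions(aln))
      if (is.na(K)) {
        sat <- c(sat, paste(labs[i], labs[j], sep = ":"))
        K <- NA_real_
      }
      D[i, j] <- D[j, i] <- K
    }
  }
  if (length(sat)) {
    mx <- max(D, na.rm = TRUE)
    D[is.na(D)] <- mx * 1.1
  }
  attr(D, "saturated_pairs") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the Studier-Keppler Q-criterion:
#' repeatedly join the pair minimising
#' `Q(i,j) = (m - 2) d(i,j) - r(i) - r(j)`, assign branch lengths
#' `b(i) = d(i,j)/2 + (r(i) - r(j)) / (2(m - 2))`, and reduce the matrix with
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. For an additive matrix the tree
#' reproduces every pairwise path length exactly. Ties in Q are broken by the
#' lexicographically smallest label pair; negative branch lengths are clamped
#' to zero and counted in attribute `negative_clamped`. A 2-taxon input gives
#' a single split with equal halves and attribute `degenerate = TRUE`.
#'
#' @param D symmetric distance matrix (rows/columns named).
#' @return an unrooted tree of class `phylo` (ape-compatible).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  if (n < 2) stop("need at least 2 taxa")
  n_clamped <- 0L
  if (n == 2) {
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = labs, Nnode = 1L),
                    class = "phylo")
    attr(tr, "degenerate") <- TRUE
    return(tr)
  }
  # active nodes carry (provisional id, display label for tie-breaks)
  node_id <- seq_len(n)           # tips 1..n; internals get n+1, n+2, ...
  node_lab <- labs
  next_internal <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  add_edge <- function(parent, child, len) {
    if (len < 0) { n_clamped <<- n_clamped + 1L; len <- 0 }
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    keys <- apply(hits, 1, function(h) {
      p <- sort(c(node_lab[h[1]], node_lab[h[2]]))
      paste(p, collapse = "\r")
    })
    pick <- hits[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    u <- next_internal; next_internal <- next_internal + 1L
    add_edge(u, node_id[i], bi)
    add_edge(u, node_id[j], bj)
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]), c(duk[keep], 0))
    ulab <- paste0("(", paste(sort(c(node_lab[i], node_lab[j])), collapse = ","), ")")
    node_id <- c(node_id[keep], u)
    node_lab <- c(node_lab[keep], ulab)
    rownames(D2) <- colnames(D2) <- node_lab
    D <- D2
  }
  # final 3-node star with closed-form branch lengths
  v <- next_internal
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(v, node_id[1], b1)
  add_edge(v, node_id[2], b2)
  add_edge(v, node_id[3], b3)
  # renumber internals so the hub is n+1 (ape root convention)
  internals <- unique(edges[, 1])
  internals <- c(v, setdiff(internals, v))
  remap <- stats::setNames(n + seq_along(internals), internals)
  e <- edges
  e[, 1] <- remap[as.character(edges[, 1])]
  big <- edges[, 2] > n
  e[big, 2] <- remap[as.character(edges[big, 2])]
  tr <- structure(list(edge = matrix(as.integer(e), ncol = 2),
                       edge.length = lens, tip.label = labs,
                       Nnode = length(internals)),
                  class = "phylo")
  attr(tr, "negative_clamped") <- n_clamped
  tr
}

#' Assign elements to families by nearest reference leaf
#'
#' Each non-reference leaf receives the family of the reference leaf with the
#' smallest tree path length (ties: lexicographically smallest reference id).
#' When best-hit assignments are supplied, their agreement rate with the
#' clade assignment is attached as attribute `agreement`.
#'
#' @param tree a `phylo` tree containing reference and element leaves.
#' @param reference_leaves named character vector: reference leaf id ->
#'   family.
#' @param assignments optional named character vector: element leaf id ->
#'   best-hit family, used for the agreement rate.
#' @return data frame with `element`, `family`, `nearest_ref`, `path_length`.
#' @export
clade_report <- function(tree, reference_leaves, assignments = NULL) {
  if (length(reference_leaves) == 0) stop("need at least one reference leaf")
  refs <- intersect(names(reference_leaves), tree$tip.label)
  if (!length(refs)) stop("no reference leaves present in the tree")
  dm <- ape::cophenetic.phylo(tree)
  elems <- setdiff(tree$tip.label, names(reference_leaves))
  out <- do.call(rbind, lapply(elems, function(e) {
    d <- dm[e, refs]
    best <- refs[order(d, refs)][1]
    data.frame(element = e, family = unname(reference_leaves[best]),
               nearest_ref = best, path_length = unname(d[best]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(element = character(0), family = character(0),
                      nearest_ref = character(0), path_length = numeric(0))
  }
  if (!is.null(assignments)) {
    common <- intersect(out$element, names(assignments))
    attr(out, "agreement") <- if (length(common)) {
      mean(out$family[match(common, out$element)] == assignments[common])
    } else NA_real_
  }
  out
}
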