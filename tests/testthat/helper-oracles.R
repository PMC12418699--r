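# Independent oracles and shared fixtures for the test suite.

# reciprocal overlap of two 0-based half-open intervals
reciprocal_overlap <- function(a1, a2, b1, b2) {
  o <- max(0, min(a2, b2) - max(a1, b1))
  if (a2 <= a1 || b2 <= b1) return(0)
  min(o / (a2 - a1), o / (b2 - b1))
}

# detection recall / precision against a truth table at a reciprocal-overlap
# threshold
detection_stats <- function(detected, truth, min_ro = 0.95) {
  hit <- function(i, j) {
    reciprocal_overlap(truth$start[i], truth$end[i],
                       detected$start[j], detected$end[j]) >= min_ro
  }
  recall_hits <- vapply(seq_len(nrow(truth)), function(i) {
    nrow(detected) > 0 &&
      any(vapply(seq_len(nrow(detected)), function(j) hit(i, j), TRUE))
  }, TRUE)
  precision_hits <- vapply(seq_len(nrow(detected)), function(j) {
    nrow(truth) > 0 &&
      any(vapply(seq_len(nrow(truth)), function(i) hit(i, j), TRUE))
  }, TRUE)
  list(recall = mean(recall_hits),
       precision = if (nrow(detected)) mean(precision_hits) else NA_real_)
}

# Brute-force all-diagonals LTR pair oracle for short sequences (<= ~20 kb).
# For every diagonal d in the allowed distance window it checks, from the
# per-position match vector, whether (a) an exact run of >= seed_len matches
# exists and (b) some window of min_ltr consecutive positions reaches the
# identity threshold. Returns the qualifying diagonals. Independent of the
# detector's seed-and-extend path.
oracle_ltr_diagonals <- function(seq, params = cenarch::detector_params()) {
  sc <- strsplit(toupper(seq), "")[[1]]
  n <- length(sc)
  k <- params$seed_len
  w <- params$min_ltr
  need <- ceiling(params$min_similarity * w)
  found <- integer(0)
  dmax <- min(params$max_dist, n - w)
  if (dmax < params$min_dist) return(found)
  for (d in params$min_dist:dmax) {
    m <- sc[1:(n - d)] == sc[(1 + d):n]
    cs <- c(0, cumsum(m))
    L <- length(m)
    if (L < w) next
    idx <- 1:(L - k + 1)
    seed_run <- any(cs[idx + k] - cs[idx] == k)
    if (!seed_run) next
    idw <- 1:(L - w + 1)
    ident_ok <- any(cs[idw + w] - cs[idw] >= need)
    if (ident_ok) found <- c(found, d)
  }
  found
}

# Least-squares topology oracle: enumerate all unrooted topologies for the
# taxa (via phangorn), fit branch lengths to the distance matrix by ordinary
# least squares on the edge-path indicator matrix, and return the topology
# with the smallest residual error.
ls_best_topology <- function(D) {
  labs <- rownames(D)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  pairs <- utils::combn(labs, 2)
  dvec <- apply(pairs, 2, function(p) D[p[1], p[2]])
  errs <- vapply(topos, function(tr) {
    ne <- nrow(tr$edge)
    A <- matrix(0, ncol(pairs), ne)
    for (pi in seq_len(ncol(pairs))) {
      i <- match(pairs[1, pi], tr$tip.label)
      j <- match(pairs[2, pi], tr$tip.label)
      np <- ape::nodepath(tr, i, j)
      for (s in seq_len(length(np) - 1)) {
        eidx <- which((tr$edge[, 1] == np[s] & tr$edge[, 2] == np[s + 1]) |
                      (tr$edge[, 2] == np[s] & tr$edge[, 1] == np[s + 1]))
        A[pi, eidx] <- 1
      }
    }
    fit <- stats::lm.fit(A, dvec)
    sum(fit$residuals^2)
  }, 0)
  topos[[which.min(errs)]]
}

# path-length matrix of a phylo tree restricted to the given labels
tree_path_matrix <- function(tree, labs) {
  ape::cophenetic.phylo(tree)[labs, labs]
}

# additive distance matrix generated from a known unrooted tree
additive_matrix_from_tree <- function(tree) {
  labs <- sort(tree$tip.label)
  tree_path_matrix(tree, labs)
}

# a cached default simulation shared by several test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_genome(simulation_spec(seed = 42L))
    cache
  }
})

# a cached detection fixture + detector run
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_detection_fixture(7L)
      fx$detected <- detect_flltrs(fx$seq, chrom = "fixture")
      cache <<- fx
    }
    cache
  }
})
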