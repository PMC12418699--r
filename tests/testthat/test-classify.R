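three_family_library <- function(seed = 61, min_identity = 0.80) {
  fams <- withr::with_seed(seed, list(
    random_family("CRWa", "Gypsy", 300, 2500),
    random_family("CRWb", "Gypsy", 300, 2500),
    random_family("CRWc", "Copia", 300, 2500)
  ))
  list(fams = fams, lib = family_library(fams, min_identity = min_identity))
}

test_that("an exact consensus copy is assigned to its family at identity 1", {
  tl <- three_family_library()
  hit <- best_hit_assign(full_element_seq(tl$fams[[3]]), tl$lib)
  expect_equal(hit$family_id, "CRWc")
  expect_equal(hit$superfamily, "Copia")
  expect_equal(hit$identity, 1.0)
})

test_that("a random sequence falls below threshold and becomes 'other'", {
  tl <- three_family_library()
  rnd <- withr::with_seed(62, random_dna(3100))
  hit <- best_hit_assign(rnd, tl$lib)
  expect_equal(hit$family_id, "other")
  expect_equal(hit$superfamily, "unknown")
  expect_lt(hit$identity, 0.80)
})

test_that("mutated family copies are recovered reliably", {
  tl <- three_family_library()
  mu <- 1.3e-8 * 5e5   # 0.5 Ma of divergence
  ok <- vapply(1:30, function(i) {
    fam <- tl$fams[[1 + (i %% 3)]]
    seq <- mutate_sequence(full_element_seq(fam), mu, seed = 900 + i)
    best_hit_assign(seq, tl$lib)$family_id == fam$family_id
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("assignment is threshold-monotone", {
  tl <- three_family_library()
  seq <- mutate_sequence(full_element_seq(tl$fams[[2]]), 0.05, seed = 63)
  lo <- best_hit_assign(seq, family_library(tl$fams, min_identity = 0.80))
  hi <- best_hit_assign(seq, family_library(tl$fams, min_identity = 0.995))
  expect_equal(lo$family_id, "CRWb")
  expect_equal(hi$family_id, "other")
  expect_equal(lo$identity, hi$identity)
})

test_that("identical triplets give a zero distance matrix", {
  s <- withr::with_seed(64, random_dna(500))
  D <- pairwise_distance_matrix(c(a = s, b = s, c = s))
  expect_true(all(D == 0))
  expect_error(pairwise_distance_matrix(c(a = s, b = s)), "at least 3")
})

test_that("matrix entries delegate to the K2P distance", {
  s1 <- strrep("ACGT", 100)
  s2 <- mutate_sequence(s1, 0.05, seed = 65)
  s3 <- withr::with_seed(66, random_dna(400))
  D <- pairwise_distance_matrix(c(a = s1, b = s2, c = s3))
  direct <- kimura2p(count_substitutions(align_ltr_pair(s1, s2)))
  expect_equal(D["a", "b"], direct)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("saturated pairs are flagged and capped at 1.1 x the matrix max", {
  a <- strrep("AC", 300)
  b <- strrep("GT", 300)          # disjoint alphabets: all-transition columns
  c <- mutate_sequence(a, 0.05, seed = 67)
  D <- pairwise_distance_matrix(c(a = a, b = b, c = c))
  sat <- attr(D, "saturated_pairs")
  expect_true(length(sat) >= 1)
  off <- D[upper.tri(D)]
  expect_equal(max(off), 1.1 * max(off[off < max(off)]), tolerance = 1e-9)
})

test_that("three-taxon NJ has the closed-form star branches", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  pl <- tree_path_matrix(tr, c("A", "B", "C"))
  expect_equal(unname(pl), unname(D))
  b <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(b[c("A", "B", "C")]), c(0.5, 1.5, 2.5))
})

test_that("NJ reproduces additive matrices exactly and matches the LS oracle", {
  tree4 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:1):0);")
  D4 <- additive_matrix_from_tree(tree4)
  nj4 <- neighbor_joining(D4)
  expect_lt(max(abs(tree_path_matrix(nj4, rownames(D4)) - D4)), 1e-9)
  best4 <- ls_best_topology(D4)
  expect_equal(ape::dist.topo(ape::unroot(nj4), ape::unroot(best4)), 0,
               ignore_attr = TRUE)

  tree5 <- ape::read.tree(text = "(((A:0.5,B:1.2):0.7,C:2):0.4,(D:1,E:0.8):0.6);")
  D5 <- additive_matrix_from_tree(tree5)
  nj5 <- neighbor_joining(D5)
  expect_lt(max(abs(tree_path_matrix(nj5, rownames(D5)) - D5)), 1e-9)
  best5 <- ls_best_topology(D5)
  expect_equal(ape::dist.topo(ape::unroot(nj5), ape::unroot(best5)), 0,
               ignore_attr = TRUE)
})

test_that("NJ agrees with the reference implementation on a noisy matrix", {
  set.seed(68)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  mine <- neighbor_joining(D)
  ref <- ape::nj(D)
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  expect_equal(unname(sort(mine$edge.length)),
               unname(sort(pmax(ref$edge.length, 0))), tolerance = 1e-9)
})

test_that("degenerate and invalid NJ inputs are handled", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr <- neighbor_joining(D2)
  expect_true(attr(tr, "degenerate"))
  expect_equal(sum(tr$edge.length), 3)
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("clade assignment follows the nearest reference leaf", {
  tl <- three_family_library()
  mu <- 1.3e-8 * 3e5
  seqs <- character(0)
  truth <- character(0)
  for (i in 1:9) {
    fam <- tl$fams[[1 + (i %% 3)]]
    seqs[paste0("e", i)] <- mutate_sequence(full_element_seq(fam), mu,
                                            seed = 1200 + i)
    truth[paste0("e", i)] <- fam$family_id
  }
  refs <- stats::setNames(vapply(tl$fams, full_element_seq, ""),
                          paste0("ref_", vapply(tl$fams, `[[`, "", "family_id")))
  D <- pairwise_distance_matrix(c(seqs, refs))
  tr <- neighbor_joining(D)
  ref_map <- stats::setNames(sub("^ref_", "", names(refs)), names(refs))
  rep <- clade_report(tr, ref_map, assignments = truth)
  expect_equal(nrow(rep), 9)
  expect_gte(attr(rep, "agreement"), 0.9)
  expect_true(all(rep$family == truth[rep$element]))
  expect_error(clade_report(tr, character(0)), "reference")
})
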