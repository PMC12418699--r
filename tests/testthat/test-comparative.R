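test_that("a self dot plot fills the forward main diagonal at identity 1", {
  s <- withr::with_seed(71, random_dna(6000))
  dp <- dotplot(s, s, window = 500, min_identity = 0.85)
  diag_hits <- dp$matches[dp$matches$x_window == dp$matches$y_window &
                          dp$matches$orientation == "forward", ]
  expect_equal(nrow(diag_hits), 12)
  expect_true(all(diag_hits$identity == 1))
  # forward matches are symmetric under (x, y) -> (y, x)
  fwd <- dp$matches[dp$matches$orientation == "forward", ]
  key <- paste(fwd$x_window, fwd$y_window)
  rev_key <- paste(fwd$y_window, fwd$x_window)
  expect_setequal(key, rev_key)
})

test_that("a reverse-complement dot plot fills the anti-diagonal", {
  s <- withr::with_seed(72, random_dna(4000))
  dp <- dotplot(s, revcomp(s), window = 500, min_identity = 0.85)
  rev_hits <- dp$matches[dp$matches$orientation == "reverse", ]
  expect_equal(nrow(rev_hits), 8)
  expect_true(all(rev_hits$y_window == dp$n_x - 1 - rev_hits$x_window))
  expect_true(all(rev_hits$identity == 1))
})

test_that("independent random sequences produce an empty dot plot", {
  a <- withr::with_seed(73, random_dna(50000))
  b <- withr::with_seed(74, random_dna(50000))
  dp <- dotplot(a, b, window = 500, min_identity = 0.85)
  expect_equal(nrow(dp$matches), 0)
  expect_error(dotplot(a, b, window = 0), "window")
})

test_that("monomerization chops, flags the remainder and scores identity", {
  unit <- withr::with_seed(75, random_dna(550))
  arr <- strrep(unit, 20)
  mh <- monomerize_and_heatmap(arr, 550)
  expect_equal(length(mh$monomers), 20)
  expect_equal(mh$remainder, 0)
  expect_true(all(mh$identity == 1))

  unit2 <- withr::with_seed(76, random_dna(566))
  arr2 <- paste0(strrep(unit2, 5), withr::with_seed(77, random_dna(100)))
  mh2 <- monomerize_and_heatmap(arr2, 566)
  expect_equal(length(mh2$monomers), 5)
  expect_equal(mh2$remainder, 100)
  expect_error(monomerize_and_heatmap(arr2, 0), "unit_len")
})

test_that("2% per-copy mutation gives ~0.96 off-diagonal monomer identity", {
  unit <- withr::with_seed(78, random_dna(550))
  copies <- vapply(1:10, function(i) mutate_sequence(unit, 0.02, seed = 1300 + i), "")
  mh <- monomerize_and_heatmap(paste(copies, collapse = ""), 550)
  off <- mh$identity[upper.tri(mh$identity)]
  expect_equal(mean(off), 0.96, tolerance = 0.01 / 0.96)
})

test_that("age summaries capture medians, incipient counts and KDE mass", {
  single <- age_distribution(1.0)
  expect_equal(single$median, 1.0)
  expect_equal(single$incipient_count, 0)
  allzero <- age_distribution(rep(0, 7))
  expect_equal(allzero$incipient_count, 7)
  mixed <- age_distribution(c(0, 0, 0.4, 1.1))
  expect_equal(mixed$incipient_count, 2)
  # density integrates to ~1 over its grid
  grid_step <- diff(mixed$grid[1:2])
  expect_equal(sum(mixed$density) * grid_step, 1, tolerance = 1e-3)
  expect_error(age_distribution(numeric(0)), "empty")
})

test_that("a bimodal age mixture shows both KDE modes near the truth", {
  set.seed(79)
  ages <- pmax(0, c(rnorm(250, 0.1, 0.02), rnorm(250, 1.0, 0.1)))
  s <- age_distribution(ages)
  dy <- s$density
  peaks <- which(diff(sign(diff(dy))) == -2) + 1
  px <- s$grid[peaks[order(dy[peaks], decreasing = TRUE)][1:2]]
  expect_true(any(abs(px - 0.1) < 0.05))
  expect_true(any(abs(px - 1.0) < 0.05))
})

test_that("the exact Mann-Whitney p matches full enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                       mode = "exact")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.05)  # 1 / choose(6, 3)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "exact")
  expect_equal(same$U, 4.5)
  expect_gte(same$p, 0.99)
  flat <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(flat$p, 1)
  expect_equal(flat$flag, "degenerate")
})

test_that("the exact p agrees with the reference implementation without ties", {
  for (i in 1:20) {
    set.seed(1400 + i)
    x <- rnorm(5); y <- rnorm(6)
    mine <- mann_whitney_u(x, y, "two.sided", "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact enumeration handles ties via midranks", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  mw <- mann_whitney_u(x, y, "less", "exact")
  # independent check: enumerate assignments of the midrank multiset directly
  r <- rank(c(x, y))
  combos <- utils::combn(8, 4)
  Ustar <- colSums(matrix(r[combos], nrow = 4)) - 4 * 5 / 2
  expect_equal(mw$p, mean(Ustar <= mw$U))
})

test_that("normal approximation tracks the exact p at n = 8 + 8", {
  diffs <- vapply(1:100, function(i) {
    set.seed(1500 + i)
    x <- rnorm(8); y <- rnorm(8, 0.5)
    ex <- mann_whitney_u(x, y, "two.sided", "exact")$p
    ap <- mann_whitney_u(x, y, "two.sided", "normal")$p
    abs(ex - ap)
  }, 0)
  expect_lt(max(diffs), 0.02)
})

test_that("region partitioning applies the coverage rules and tiles the domain", {
  anc <- replicate(3, data.frame(start = 10e6, end = 12e6), simplify = FALSE)
  der <- data.frame(start = 14e6, end = 16e6)
  p <- partition_regions(anc, der, c(10e6, 16e6))
  segs <- p$segments
  expect_equal(segs$class, c("ancestral_all", "neither", "derived_only"))
  expect_equal(segs$region, c(5L, 4L, 2L))
  expect_equal(sum(segs$end - segs$start), 6e6)
  expect_equal(segs$start[1], 10e6)
  expect_equal(segs$end[nrow(segs)], 16e6)

  # one of three accessions -> ancestral_one; two -> ancestral_some
  anc2 <- list(data.frame(start = 0, end = 4), data.frame(start = 2, end = 4),
               data.frame(start = c(0, 0), end = c(0, 0))[0, ])
  p2 <- partition_regions(anc2, data.frame(start = 5, end = 6), c(0, 8))
  expect_equal(p2$segments$class,
               c("ancestral_one", "ancestral_some", "neither", "derived_only",
                 "neither"))
  expect_error(partition_regions(anc, data.frame(start = 0, end = 20e6),
                                 c(10e6, 16e6)), "outside")
  # empty derived set: no derived_only segments
  p3 <- partition_regions(anc, NULL, c(10e6, 16e6))
  expect_false("derived_only" %in% p3$segments$class)
})

test_that("region age summaries order young and old compartments", {
  anc <- replicate(2, data.frame(start = 0e6, end = 2e6), simplify = FALSE)
  der <- data.frame(start = 3e6, end = 5e6)
  part <- partition_regions(anc, der, c(0, 5e6))
  ltr <- withr::with_seed(81, paste0("TG", random_dna(996), "CA"))
  dated_age <- function(t, seed) {
    p <- simulate_ltr_pair(ltr, t, seed = seed)
    age_from_distance(kimura2p(count_substitutions(align_ltr_pair(p$ltr5, p$ltr3))))
  }
  old <- vapply(1:15, function(i) dated_age(1.2e6, 1600 + i), 0)
  young <- vapply(1:15, function(i) dated_age(0.2e6, 1700 + i), 0)
  dated <- data.frame(
    start = c(seq(0.1e6, 1.9e6, length.out = 15), seq(3.1e6, 4.9e6, length.out = 15)) - 1000,
    end = c(seq(0.1e6, 1.9e6, length.out = 15), seq(3.1e6, 4.9e6, length.out = 15)) + 1000,
    age_ma = c(old, young)
  )
  ras <- region_age_summary(dated, part)
  expect_lt(ras$summaries$derived_only$median, ras$summaries$ancestral_all$median)
  tst <- ras$tests[ras$tests$class_a == "ancestral_all" &
                   ras$tests$class_b == "derived_only", ]
  expect_lt(tst$p, 0.01)
  expect_true("neither" %in% attr(ras, "empty_classes"))
})

test_that("elements on a segment boundary follow the midpoint rule", {
  part <- partition_regions(list(data.frame(start = 0, end = 10)),
                            data.frame(start = 10, end = 20), c(0, 20))
  dated <- data.frame(start = 9, end = 11, age_ma = 1)  # midpoint exactly 10
  ras <- region_age_summary(dated, part)
  expect_equal(names(ras$summaries), "derived_only")
})

test_that("copy tables count by midpoint and roll up superfamilies", {
  assignments <- data.frame(
    chrom = "chr1",
    start = c(10, 30, 50, 200) * 1000,
    end = c(14, 34, 54, 204) * 1000,
    family_id = c("A", "A", "B", "C"),
    superfamily = c("Gypsy", "Gypsy", "Copia", "Gypsy"),
    stringsAsFactors = FALSE
  )
  calls <- data.frame(chrom = "chr1", start = 0, end = 100000)
  ct <- crw_copy_table(assignments, calls)
  expect_equal(ct$total, 3)
  expect_equal(unname(ct$counts["A", "chr1"]), 2L)
  expect_equal(unname(ct$counts["B", "chr1"]), 1L)
  expect_equal(unname(ct$counts["C", "chr1"]), 0L)
  expect_equal(unname(ct$superfamily_pct["Gypsy"]), 66.7)
  empty <- crw_copy_table(assignments[0, ], calls)
  expect_equal(empty$total, 0)
})

test_that("published superfamily counts give the reported percentages", {
  pct <- superfamily_percentages(c(Gypsy = 3111, Copia = 141, unknown = 344))
  expect_equal(unname(pct["Gypsy"]), 86.5)
  expect_equal(unname(pct["Copia"]), 3.9)
  expect_equal(unname(pct["unknown"]), 9.6)
  expect_equal(sum(pct), 100.0, tolerance = 0.1 / 100)
})
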