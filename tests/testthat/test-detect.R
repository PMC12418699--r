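test_that("detector parameters are validated", {
  expect_error(detector_params(min_ltr = 3000, max_ltr = 2000), "min_ltr")
  expect_error(detector_params(min_dist = 30000, max_dist = 25000), "min_dist")
  expect_error(detector_params(min_similarity = 1.2), "min_similarity")
})

test_that("a random uniform sequence yields no candidate pairs", {
  g <- withr::with_seed(101, random_dna(100000))
  expect_equal(nrow(find_ltr_pairs(g)), 0)
})

test_that("a planted compliant element is recovered with accurate LTRs", {
  fam <- random_family("F", "Gypsy", 500, 3000, seed = 6)
  g <- withr::with_seed(7, random_dna(30000))
  res <- plant_element(g, 12000, fam, 6e5, seed = 8)  # ~95% LTR identity
  cands <- find_ltr_pairs(res$seq)
  expect_gte(nrow(cands), 1)
  e <- res$element
  ro5 <- reciprocal_overlap(e$ltr5_start, e$ltr5_end,
                            cands$ltr5_start[1], cands$ltr5_end[1])
  ro3 <- reciprocal_overlap(e$ltr3_start, e$ltr3_end,
                            cands$ltr3_start[1], cands$ltr3_end[1])
  expect_gte(ro5, 0.95)
  expect_gte(ro3, 0.95)
})

test_that("repeats below the minimum LTR length are not seeded into pairs", {
  # 50 nt identical repeats, 5 kb apart
  rep50 <- withr::with_seed(9, random_dna(50))
  g <- withr::with_seed(10, random_dna(20000))
  seq <- paste0(substr(g, 1, 5000), rep50, substr(g, 5001, 10000), rep50,
                substr(g, 10001, 20000))
  expect_equal(nrow(find_ltr_pairs(seq)), 0)
})

test_that("boundary refinement recovers a planted TSD and motif exactly", {
  fam <- random_family("F", "Gypsy", 500, 2700, seed = 12)
  g <- withr::with_seed(13, random_dna(16000))
  res <- plant_element(g, 6000, fam, 3e5, seed = 14)
  det <- detect_flltrs(res$seq)
  expect_equal(nrow(det), 1)
  expect_identical(det$tsd, res$element$tsd)
  expect_true(det$motif_ok)
  expect_equal(det$start, res$element$start)
  expect_equal(det$end, res$element$end)
  expect_match(det$quality_flags, "tsd")
})

test_that("one terminal motif mismatch is still accepted", {
  # LTR starting TA instead of TG: one mismatch over the four motif bases
  ltr <- withr::with_seed(15, paste0("TA", random_dna(496), "CA"))
  fam <- family_consensus("F", "Gypsy", ltr, withr::with_seed(16, random_dna(2700)),
                          validate = FALSE)
  g <- withr::with_seed(17, random_dna(16000))
  res <- plant_element(g, 6000, fam, 0, seed = 18)
  det <- detect_flltrs(res$seq)
  expect_equal(nrow(det), 1)
  expect_true(det$motif_ok)
})

test_that("absent TSD evidence is recorded, not fatal", {
  # flanks engineered so that no direct repeat of >= 4 nt exists anywhere in
  # the refinement vicinity: poly-A upstream, poly-C downstream, and LTR
  # termini padded with G- and T-runs
  rd <- function(n, s) withr::with_seed(s, random_dna(n))
  ltr <- paste0("TG", strrep("G", 60), rd(74, 22), strrep("T", 60), "CA")
  el <- paste0(ltr, rd(3000, 23), ltr)
  seq <- paste0(rd(3000, 24), strrep("A", 70), el, strrep("C", 70), rd(3000, 25))
  det <- detect_flltrs(seq)  # motif present, so still accepted
  expect_equal(nrow(det), 1)
  expect_true(is.na(det$tsd))
  expect_match(det$quality_flags, "no_tsd")
  expect_equal(det$start, 3070)
  expect_equal(det$end, 3070 + nchar(el))
})

test_that("overlap resolution keeps the best element by the stated tie-break", {
  el <- function(s, span, sim) {
    data.frame(ltr5_start = s, ltr5_end = s + 500, ltr3_start = s + span - 500,
               ltr3_end = s + span, strand = "+", ltr_similarity = sim,
               tsd = NA_character_, motif_ok = TRUE, element_span = span,
               quality_flags = "", stringsAsFactors = FALSE)
  }
  # higher similarity wins
  two <- rbind(el(1000, 8000, 0.92), el(3000, 8000, 0.88))
  kept <- resolve_overlaps(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$ltr_similarity, 0.92)
  # disjoint elements all survive
  far <- rbind(el(1000, 8000, 0.92), el(20000, 8000, 0.88))
  expect_equal(nrow(resolve_overlaps(far)), 2)
  # equal similarity: longer span, then leftmost
  three <- rbind(el(1000, 8000, 0.9), el(5000, 9000, 0.9), el(6000, 9000, 0.9))
  kept3 <- resolve_overlaps(three)
  expect_equal(kept3$ltr5_start, 5000)
  expect_equal(kept3$element_span, 9000)
  expect_error(resolve_overlaps(three, mode = "all"), "unknown overlap mode")
})

test_that("the fixture genome is detected with perfect recall and precision", {
  fx <- shared_fixture()
  st <- detection_stats(fx$detected, fx$truth, min_ro = 0.95)
  expect_equal(st$recall, 1.0)
  expect_equal(st$precision, 1.0)
  expect_equal(nrow(fx$detected), 10)
  # no detected element overlaps any decoy
  for (j in seq_len(nrow(fx$detected))) {
    for (i in seq_len(nrow(fx$decoys))) {
      expect_lt(reciprocal_overlap(fx$decoys$start[i], fx$decoys$end[i],
                                   fx$detected$start[j], fx$detected$end[j]),
                0.5)
    }
  }
})

test_that("an age-zero planted element reports LTR similarity 1.0", {
  fx <- shared_fixture()
  hit <- which.min(abs(fx$detected$start - fx$truth$start[fx$truth$true_age_ma == 0]))
  expect_equal(fx$detected$ltr_similarity[hit], 1.0)
})

test_that("every reported element satisfies the structural bounds", {
  fx <- shared_fixture()
  p <- detector_params()
  d <- fx$detected
  expect_true(all(d$ltr5_end - d$ltr5_start >= p$min_ltr))
  expect_true(all(d$ltr5_end - d$ltr5_start <= p$max_ltr))
  expect_true(all(d$ltr3_end - d$ltr3_start >= p$min_ltr))
  expect_true(all(d$ltr3_end - d$ltr3_start <= p$max_ltr))
  dd <- d$ltr3_start - d$ltr5_start
  expect_true(all(dd >= p$min_dist & dd <= p$max_dist))
  expect_true(all(d$ltr_similarity >= p$min_similarity))
  expect_true(all(d$ltr5_end <= d$ltr3_start))
})

test_that("raising min_similarity never increases the number of detections", {
  fx <- shared_fixture()
  n_prev <- Inf
  for (ms in c(0.85, 0.92, 0.97, 0.999)) {
    n <- nrow(detect_flltrs(fx$seq, detector_params(min_similarity = ms)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detection on the reverse complement mirrors the coordinates", {
  fam <- random_family("F", "Gypsy", 500, 2700, seed = 23)
  g <- withr::with_seed(24, random_dna(16000))
  res <- plant_element(g, 6000, fam, 3e5, seed = 25)
  fwd <- detect_flltrs(res$seq)
  rev <- detect_flltrs(revcomp(res$seq))
  expect_equal(nrow(fwd), 1)
  expect_equal(nrow(rev), 1)
  n <- nchar(res$seq)
  expect_equal(rev$start, n - fwd$end)
  expect_equal(rev$end, n - fwd$start)
})

test_that("an empty or short window yields an empty result", {
  expect_equal(nrow(detect_flltrs("ACGTACGT")), 0)
})

test_that("the brute-force all-diagonal oracle agrees on short windows", {
  # two elements of different families in an ~18 kb window
  fam1 <- random_family("O1", "Gypsy", 400, 2800, seed = 31)
  fam2 <- random_family("O2", "Copia", 500, 3200, seed = 32)
  g <- withr::with_seed(33, random_dna(9000))
  res1 <- plant_element(g, 2000, fam1, 4e5, seed = 34)
  res2 <- plant_element(res1$seq, 7500, fam2, 2e5, seed = 35)
  seq <- res2$seq
  expect_lte(nchar(seq), 20000)
  oracle <- oracle_ltr_diagonals(seq)
  cands <- find_ltr_pairs(seq)
  expect_setequal(cands$ltr3_start - cands$ltr5_start, oracle)
  expect_equal(nrow(cands), 2)
})

test_that("lowercase input is treated as uppercase and N breaks seeds", {
  fam <- random_family("F", "Gypsy", 500, 2700, seed = 41)
  g <- withr::with_seed(42, random_dna(16000))
  res <- plant_element(g, 6000, fam, 0, seed = 43)
  det_lower <- detect_flltrs(tolower(res$seq))
  expect_equal(nrow(det_lower), 1)
  # saturate the 5' LTR interior with N: its seeds disappear
  e <- res$element
  broken <- paste0(substr(res$seq, 1, e$ltr5_start + 10),
                   strrep("N", e$ltr5_end - e$ltr5_start - 20),
                   substr(res$seq, e$ltr5_end - 9, nchar(res$seq)))
  expect_equal(nrow(find_ltr_pairs(broken)), 0)
})
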