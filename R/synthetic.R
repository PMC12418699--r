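# Synthetic genomes with planted LTR retrotransposons, satellite arrays and
# ChIP/Input coverage, plus the ground truth needed to validate the analysis
# modules. The generator emulates the statistical structure the pipeline
# assumes: uniform ACGT background, elements with paired LTRs diverged by
# independent post-insertion substitution at a molecular-clock rate, 4-20 bp
# target-site duplications, TG...CA termini, and Poisson bin-level coverage
# with a fold enrichment over the centromere.

# ---------------------------------------------------------------------------
# substitution process

#' Mutate a DNA sequence under a two-class substitution process
#'
#' Applies to every site an independent Poisson number of substitution events
#' with mean `expected_subs_per_site`. Each event is a transition (A<->G,
#' C<->T) with probability `kappa / (kappa + 2)`, otherwise one of the two
#' possible transversions chosen uniformly. No indels are introduced, so the
#' output has the same length as the input. This is the forward process whose
#' divergence the Kimura two-parameter distance corrects, keeping
#' E\[K\] close to the expected number of substitutions per site.
#'
#' @param seq DNA string (ACGT only).
#' @param expected_subs_per_site expected substitutions per site (>= 0).
#' @param kappa transition:transversion rate ratio parameter (> 0); the
#'   default 2 makes transition and (pooled) transversion events equally
#'   likely per event.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return the mutated sequence as a character string.
#' @export
mutate_sequence <- function(seq, expected_subs_per_site, kappa = 2, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(expected_subs_per_site) || expected_subs_per_site < 0) {
    stop("expected_subs_per_site must be >= 0")
  }
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  chars <- seq_chars(seq)
  bad <- which(!chars %in% .BASES)
  if (length(bad)) {
    stop(sprintf("non-ACGT character '%s' at position %d", chars[bad[1]], bad[1]))
  }
  if (expected_subs_per_site == 0) {
    return(paste(chars, collapse = ""))
  }
  with_opt_seed(seed, {
    idx <- match(chars, .BASES)
    # index of the transition partner, and the two transversion partners
    transition <- c(3L, 4L, 1L, 2L)
    transversion <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
    n_events <- stats::rpois(length(idx), expected_subs_per_site)
    p_ts <- kappa / (kappa + 2)
    kmax <- max(n_events)
    k <- 1L
    while (k <= kmax) {
      at <- which(n_events >= k)
      is_ts <- stats::runif(length(at)) < p_ts
      cur <- idx[at]
      nxt <- integer(length(at))
      nxt[is_ts] <- transition[cur[is_ts]]
      if (any(!is_ts)) {
        col <- 1L + (stats::runif(sum(!is_ts)) < 0.5)
        nxt[!is_ts] <- transversion[cbind(cur[!is_ts], col)]
      }
      idx[at] <- nxt
      k <- k + 1L
    }
    paste(.BASES[idx], collapse = "")
  })
}

# ---------------------------------------------------------------------------
# family consensus

#' Construct an LTR retrotransposon family consensus
#'
#' A full-length element is `ltr_seq + internal_seq + ltr_seq`; by
#' construction it starts with TG and ends with CA (the canonical termini of
#' LTR retrotransposons), which is enforced on `ltr_seq` together with the
#' structural bounds the detector assumes (LTR 100-2000 nt, element
#' 3000-25000 nt).
#'
#' @param family_id family label (unique within a library).
#' @param superfamily one of `"Gypsy"`, `"Copia"`, `"unknown"`.
#' @param ltr_seq LTR consensus sequence (shared by both termini).
#' @param internal_seq internal-region consensus sequence.
#' @param autonomous logical, carried as metadata only.
#' @param validate set `FALSE` to bypass the structural invariants (used to
#'   build deliberately non-compliant decoy elements).
#' @return an object of class `family_consensus`.
#' @export
family_consensus <- function(family_id, superfamily = c("Gypsy", "Copia", "unknown"),
                             ltr_seq, internal_seq, autonomous = TRUE,
                             validate = TRUE) {
  superfamily <- match.arg(superfamily)
  ltr_seq <- toupper(ltr_seq)
  internal_seq <- toupper(internal_seq)
  if (validate) {
    nl <- nchar(ltr_seq)
    total <- 2 * nl + nchar(internal_seq)
    if (nl < 100 || nl > 2000) stop("LTR consensus length must be in [100, 2000]")
    if (total < 3000 || total > 25000) stop("full element length must be in [3000, 25000]")
    if (substr(ltr_seq, 1, 2) != "TG" || substr(ltr_seq, nl - 1, nl) != "CA") {
      stop("LTR consensus must start with TG and end with CA")
    }
  }
  structure(list(family_id = family_id, superfamily = superfamily,
                 ltr_seq = ltr_seq, internal_seq = internal_seq,
                 autonomous = autonomous),
            class = "family_consensus")
}

#' Generate a random family consensus
#'
#' @param family_id family label.
#' @param superfamily superfamily label.
#' @param ltr_len,internal_len consensus part lengths in nt.
#' @param seed optional seed.
#' @return a [family_consensus()] object with random TG...CA-compliant LTRs.
#' @export
random_family <- function(family_id, superfamily = "Gypsy",
                          ltr_len = 1000, internal_len = 2000, seed = NULL) {
  with_opt_seed(seed, {
    core <- random_dna(ltr_len - 4)
    ltr <- paste0("TG", core, "CA")
    family_consensus(family_id, superfamily, ltr, random_dna(internal_len))
  })
}

full_element_seq <- function(consensus, truncated = FALSE) {
  if (truncated) {
    paste0(consensus$ltr_seq, consensus$internal_seq)
  } else {
    paste0(consensus$ltr_seq, consensus$internal_seq, consensus$ltr_seq)
  }
}

# ---------------------------------------------------------------------------
# planting

#' Simulate a diverged 5'/3' LTR pair
#'
#' Both copies start from the same consensus and accumulate substitutions
#' independently with expected `r * age_years` substitutions per site each,
#' so their expected Kimura distance is about `2 * r * age_years` -- the
#' quantity the molecular clock `age = K / (2 r)` inverts.
#'
#' @param ltr_seq LTR consensus string.
#' @param age_years time since insertion in years.
#' @param r substitution rate per site per year.
#' @param kappa transition:transversion parameter, see [mutate_sequence()].
#' @param seed optional seed.
#' @return list with components `ltr5` and `ltr3`.
#' @export
simulate_ltr_pair <- function(ltr_seq, age_years, r = 1.3e-8, kappa = 2,
                              seed = NULL) {
  with_opt_seed(seed, {
    mu <- r * age_years
    list(ltr5 = mutate_sequence(ltr_seq, mu, kappa),
         ltr3 = mutate_sequence(ltr_seq, mu, kappa))
  })
}

#' Plant one LTR retrotransposon into a chromosome sequence
#'
#' Inserts a copy of the family consensus at offset `pos` (0-based). Both LTR
#' copies (and the internal region) are mutated independently with expected
#' `r * age_years` substitutions per site; a random target-site duplication of
#' 4-20 bp is placed on both flanks. The chromosome grows by the inserted
#' length; returned coordinates refer to the emitted sequence.
#'
#' @param chrom_seq chromosome sequence (character).
#' @param pos 0-based insertion offset within `chrom_seq`.
#' @param consensus a [family_consensus()].
#' @param age_years true insertion age in years (>= 0).
#' @param r,kappa substitution process parameters.
#' @param seed optional seed.
#' @param truncated if `TRUE` the 3' LTR is omitted (a solo-LTR-like decoy
#'   that must not be detected as full length).
#' @param with_tsd if `FALSE` no target-site duplication is added.
#' @return list with `seq` (the new chromosome) and `element` (truth record:
#'   0-based half-open element and LTR intervals, family, true age, TSD).
#' @export
plant_element <- function(chrom_seq, pos, consensus, age_years,
                          r = 1.3e-8, kappa = 2, seed = NULL,
                          truncated = FALSE, with_tsd = TRUE) {
  n <- nchar(chrom_seq)
  if (pos < 0 || pos > n) stop("element insertion position outside chromosome")
  if (age_years < 0) stop("age_years must be >= 0")
  with_opt_seed(seed, {
    mu <- r * age_years
    ltr5 <- mutate_sequence(consensus$ltr_seq, mu, kappa)
    ltr3 <- mutate_sequence(consensus$ltr_seq, mu, kappa)
    internal <- mutate_sequence(consensus$internal_seq, mu, kappa)
    element <- if (truncated) paste0(ltr5, internal) else paste0(ltr5, internal, ltr3)
    tsd <- if (with_tsd) random_dna(sample(4:20, 1)) else ""
    tl <- nchar(tsd)
    new_seq <- paste0(subseq0(chrom_seq, 0, pos), tsd, element, tsd,
                      subseq0(chrom_seq, pos, n))
    start <- pos + tl
    end <- start + nchar(element)
    ltr_len <- nchar(consensus$ltr_seq)
    rec <- data.frame(
      insert_pos = pos, start = start, end = end,
      ltr5_start = start, ltr5_end = start + ltr_len,
      ltr3_start = if (truncated) NA_real_ else end - ltr_len,
      ltr3_end = if (truncated) NA_real_ else end,
      strand = "+",
      family_id = consensus$family_id, superfamily = consensus$superfamily,
      true_age_ma = age_years / 1e6,
      tsd = if (with_tsd) tsd else NA_character_,
      truncated = truncated,
      stringsAsFactors = FALSE
    )
    list(seq = new_seq, element = rec)
  })
}

#' Plant a structurally non-compliant decoy element
#'
#' Decoys violate exactly one of the detector's acceptance rules and serve as
#' negative controls for precision: `short_ltr` (60 nt LTRs, below the 100 nt
#' minimum), `over_span` (5'-to-3' LTR start distance beyond 25 kb),
#' `low_identity` (ancient insertion, LTR identity < 0.85), `truncated`
#' (missing 3' LTR) and `no_evidence` (termini without the TG...CA motif and
#' no target-site duplication).
#'
#' @param chrom_seq chromosome sequence.
#' @param pos 0-based insertion offset.
#' @param type decoy type, see description.
#' @param family_id label recorded in the truth.
#' @param seed optional seed.
#' @return as [plant_element()], with a `decoy` column added to the record.
#' @export
plant_decoy <- function(chrom_seq, pos,
                        type = c("short_ltr", "over_span", "low_identity",
                                 "truncated", "no_evidence"),
                        family_id = paste0("decoy_", type), seed = NULL) {
  type <- match.arg(type)
  with_opt_seed(seed, {
    res <- switch(type,
      short_ltr = {
        fam <- family_consensus(family_id, "unknown",
                                paste0("TG", random_dna(56), "CA"),
                                random_dna(4000), validate = FALSE)
        plant_element(chrom_seq, pos, fam, 0)
      },
      over_span = {
        fam <- family_consensus(family_id, "unknown",
                                paste0("TG", random_dna(496), "CA"),
                                random_dna(30000), validate = FALSE)
        plant_element(chrom_seq, pos, fam, 0)
      },
      low_identity = {
        fam <- random_family(family_id, "unknown", 800, 2000)
        plant_element(chrom_seq, pos, fam, 12e6)
      },
      truncated = {
        fam <- random_family(family_id, "unknown", 800, 2000)
        plant_element(chrom_seq, pos, fam, 0, truncated = TRUE)
      },
      no_evidence = {
        fam <- family_consensus(family_id, "unknown",
                                paste0("AA", random_dna(796), "TT"),
                                random_dna(2000), validate = FALSE)
        plant_element(chrom_seq, pos, fam, 0, with_tsd = FALSE)
      }
    )
    res$element$decoy <- type
    res
  })
}

# ---------------------------------------------------------------------------
# whole-genome simulation

#' Age sampler specification
#'
#' @param type `"point"` (all elements at `value` Ma) or `"uniform"`
#'   (ages drawn uniformly in `[min, max]` Ma).
#' @param min,max,value ages in Ma.
#' @return a list usable as a per-region age sampler in [simulation_spec()].
#' @export
age_sampler <- function(type = c("uniform", "point"), min = 0, max = 2,
                        value = NULL) {
  type <- match.arg(type)
  if (type == "point") {
    stopifnot(!is.null(value), value >= 0)
    list(type = "point", value = value)
  } else {
    stopifnot(min >= 0, max >= min)
    list(type = "uniform", min = min, max = max)
  }
}

draw_ages <- function(sampler, n) {
  if (n == 0) return(numeric(0))
  switch(sampler$type,
    point = rep(sampler$value, n),
    uniform = stats::runif(n, sampler$min, sampler$max),
    stop("unknown age sampler type: ", sampler$type)
  )
}

#' Specification for a synthetic centromere locus
#'
#' Defaults describe a desk-scale locus that keeps every module exercisable:
#' a 400 kb chromosome with a 100 kb central CENH3 domain, 50 kb
#' pericentromeric flanks, three LTR-RT families (two Gypsy, one Copia;
#' 1 kb LTRs, 4.6 kb elements), young centromeric insertions and older flank
#' insertions, a wheat-like substitution rate r = 1.3e-8 /site/year, 4-fold
#' ChIP enrichment at 100 counts/bin mean depth. All randomness is fixed by
#' `seed`.
#'
#' @param chrom chromosome name.
#' @param chrom_length background length in nt (before insertions).
#' @param centromere `[start, end)` of the centromeric block, background
#'   coordinates.
#' @param peri_flank pericentromere width on each side, nt.
#' @param n_elements named integer vector: elements per region
#'   (`centromeric`, `pericentromeric`, `arm`).
#' @param ages named list of [age_sampler()] specs per region, ages in Ma.
#' @param families list of [family_consensus()]; `NULL` generates three
#'   default families from the seed.
#' @param r,kappa substitution process parameters.
#' @param enrichment_factor ChIP fold enrichment over the centromere (>= 1).
#' @param mean_depth mean Input counts per bin.
#' @param bin_size coverage bin size, nt.
#' @param satellite `c(unit_len, n_units)` tandem array to plant inside the
#'   centromere, or `NULL`.
#' @param seed integer seed; fully determines the simulation.
#' @return a validated spec list of class `simulation_spec`.
#' @export
simulation_spec <- function(chrom = "chr1",
                            chrom_length = 400000,
                            centromere = c(150000, 250000),
                            peri_flank = 50000,
                            n_elements = c(centromeric = 6, pericentromeric = 3, arm = 3),
                            ages = list(centromeric = age_sampler("uniform", 0.05, 0.5),
                                        pericentromeric = age_sampler("uniform", 1, 2),
                                        arm = age_sampler("uniform", 1, 2)),
                            families = NULL,
                            r = 1.3e-8, kappa = 2,
                            enrichment_factor = 4, mean_depth = 100,
                            bin_size = 2000,
                            satellite = NULL,
                            seed = 1L) {
  check_interval(centromere, "centromere")
  if (centromere[1] < 0 || centromere[2] > chrom_length) {
    stop("centromere interval must lie within the chromosome")
  }
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (bin_size <= 0) stop("bin_size must be positive")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  regs <- c("centromeric", "pericentromeric", "arm")
  n_elements <- n_elements[regs]
  n_elements[is.na(n_elements)] <- 0
  names(n_elements) <- regs
  if (!is.null(satellite)) {
    stopifnot(length(satellite) == 2, satellite[1] > 0, satellite[2] > 0)
  }
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 centromere = centromere, peri_flank = peri_flank,
                 n_elements = n_elements, ages = ages, families = families,
                 r = r, kappa = kappa, enrichment_factor = enrichment_factor,
                 mean_depth = mean_depth, bin_size = bin_size,
                 satellite = satellite, seed = as.integer(seed)),
            class = "simulation_spec")
}

default_families <- function() {
  list(random_family("CenFam1", "Gypsy", 1000, 2600),
       random_family("CenFam2", "Gypsy", 1000, 2600),
       random_family("CenFam3", "Copia", 1000, 2600))
}

# draw element positions region by region, enforcing a minimum spacing
# between any two insertions and a much larger spacing between insertions of
# the same family (a cross-element LTR pairing of two nearby same-family
# copies is structurally indistinguishable from a genuine element)
plan_positions <- function(spec, families, max_tries = 500L) {
  regions <- list(
    centromeric = rbind(spec$centromere),
    pericentromeric = rbind(c(max(0, spec$centromere[1] - spec$peri_flank), spec$centromere[1]),
                            c(spec$centromere[2], min(spec$chrom_length, spec$centromere[2] + spec$peri_flank))),
    arm = rbind(c(0, max(0, spec$centromere[1] - spec$peri_flank)),
                c(min(spec$chrom_length, spec$centromere[2] + spec$peri_flank), spec$chrom_length))
  )
  min_gap <- 200
  same_family_gap <- 27000
  pos <- numeric(0); fam <- character(0); region <- character(0)
  fam_ids <- vapply(families, `[[`, "", "family_id")
  for (rg in names(regions)) {
    n_want <- spec$n_elements[[rg]]
    if (n_want == 0) next
    segs <- regions[[rg]]
    segs <- segs[segs[, 2] - segs[, 1] > 2000, , drop = FALSE]
    if (nrow(segs) == 0) stop("region '", rg, "' too small to host elements")
    w <- segs[, 2] - segs[, 1]
    for (i in seq_len(n_want)) {
      f <- fam_ids[1 + (length(pos) %% length(fam_ids))]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(nrow(segs), 1, prob = w)
        p <- floor(stats::runif(1, segs[s, 1] + 500, segs[s, 2] - 500))
        if (length(pos)) {
          if (any(abs(pos - p) < min_gap)) next
          if (any(abs(pos[fam == f] - p) < same_family_gap)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place elements without overlap after ", max_tries, " tries")
      pos <- c(pos, p); fam <- c(fam, f); region <- c(region, rg)
    }
  }
  data.frame(pos = pos, family_id = fam, region = region, stringsAsFactors = FALSE)
}

#' Simulate a chromosome with planted elements and known truth
#'
#' Generates a uniform-ACGT background, plants full-length LTR
#' retrotransposons per region with ages drawn from the spec's samplers, and
#' optionally a tandem satellite array inside the centromere. Insertions
#' grow the sequence; all truth coordinates (including the shifted centromere
#' interval) refer to the emitted sequence, 0-based half-open. Identical
#' specs (including seed) give byte-identical output.
#'
#' @param spec a [simulation_spec()].
#' @return an object of class `cen_sim`: list with `spec`, `chrom`, `seq`
#'   (character), `chrom_length` (emitted), `families`, and `truth` (list
#'   with `centromere`, `elements` data frame, `satellite`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    families <- spec$families %||% default_families()
    plan <- plan_positions(spec, families)
    plan$age_ma <- rep(NA_real_, nrow(plan))
    for (rg in unique(plan$region)) {
      idx <- plan$region == rg
      sampler <- spec$ages[[rg]]
      if (is.null(sampler)) stop("no age sampler for region '", rg, "'")
      plan$age_ma[idx] <- draw_ages(sampler, sum(idx))
    }
    sat_pos <- NULL
    sat_len <- 0
    if (!is.null(spec$satellite)) {
      unit_len <- spec$satellite[1]; n_units <- spec$satellite[2]
      sat_len <- unit_len * n_units
      lo <- spec$centromere[1] + 1000; hi <- spec$centromere[2] - 1000
      repeat {
        sat_pos <- floor(stats::runif(1, lo, hi))
        if (!length(plan$pos) || all(abs(plan$pos - sat_pos) >= 200)) break
      }
      sat_unit <- random_dna(unit_len)
    }
    seq <- random_dna(spec$chrom_length)
    fams_by_id <- stats::setNames(families, vapply(families, `[[`, "", "family_id"))

    # plant right-to-left so earlier background offsets stay valid
    ord <- order(plan$pos, decreasing = TRUE)
    recs <- vector("list", nrow(plan))
    ins_len <- numeric(nrow(plan))
    for (i in ord) {
      res <- plant_element(seq, plan$pos[i], fams_by_id[[plan$family_id[i]]],
                           plan$age_ma[i] * 1e6, r = spec$r, kappa = spec$kappa)
      seq <- res$seq
      recs[[i]] <- res$element
      ins_len[i] <- res$element$end - res$element$start + 2 * nchar(res$element$tsd)
    }
    # satellite inserted last among items to its right already placed:
    # treat as one more insertion applied against the background-coordinate
    # frame; apply it after mapping is easier done by inserting now at the
    # shifted position
    if (!is.null(sat_pos)) {
      shift_sat <- sum(ins_len[plan$pos < sat_pos])
      array_seq <- paste(rep(sat_unit, spec$satellite[2]), collapse = "")
      at <- sat_pos + shift_sat
      seq <- paste0(subseq0(seq, 0, at), array_seq, subseq0(seq, at, nchar(seq)))
    }

    # background -> emitted coordinate shifts
    shift_for <- function(p, strict = TRUE) {
      s <- sum(ins_len[if (strict) plan$pos < p else plan$pos <= p])
      if (!is.null(sat_pos) && sat_pos < p) s <- s + sat_len
      s
    }
    elements <- do.call(rbind, recs)
    if (!is.null(elements) && nrow(elements)) {
      sh <- vapply(plan$pos, shift_for, 0)
      # record coordinates are relative to the background prefix at planting
      # time plus own tsd; final start = background pos + prior shifts + tsd
      tsd_len <- nchar(elements$tsd)
      delta <- plan$pos + sh + tsd_len - elements$start
      for (col in c("start", "end", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")) {
        elements[[col]] <- elements[[col]] + delta
      }
      elements$chrom <- spec$chrom
      elements$region <- plan$region
      elements$id <- sprintf("elem%03d", seq_len(nrow(elements)))
      elements <- elements[order(elements$start),
                           c("id", "chrom", "start", "end", "ltr5_start", "ltr5_end",
                             "ltr3_start", "ltr3_end", "strand", "family_id",
                             "superfamily", "true_age_ma", "tsd", "truncated", "region")]
      rownames(elements) <- NULL
    } else {
      elements <- empty_elements()
    }
    cen <- c(spec$centromere[1] + shift_for(spec$centromere[1]),
             spec$centromere[2] + shift_for(spec$centromere[2]))
    satellite <- NULL
    if (!is.null(sat_pos)) {
      s0 <- sat_pos + shift_for(sat_pos)
      satellite <- c(s0, s0 + sat_len)
    }
    structure(list(spec = spec, chrom = spec$chrom, seq = seq,
                   chrom_length = nchar(seq), families = families,
                   truth = list(centromere = cen, elements = elements,
                                satellite = satellite)),
              class = "cen_sim")
  })
}

empty_elements <- function() {
  data.frame(id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), ltr5_start = numeric(0), ltr5_end = numeric(0),
             ltr3_start = numeric(0), ltr3_end = numeric(0),
             strand = character(0), family_id = character(0),
             superfamily = character(0), true_age_ma = numeric(0),
             tsd = character(0), truncated = logical(0), region = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.cen_sim <- function(x, ...) {
  cat("Synthetic centromere locus:", x$chrom, "--", x$chrom_length, "nt\n")
  cat("  centromere:", paste(x$truth$centromere, collapse = "-"), "\n")
  cat("  planted elements:", nrow(x$truth$elements), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# coverage simulation

#' Binned coverage track
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in nt.
#' @param counts per-bin counts (nonnegative).
#' @param chrom_length chromosome length in nt.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, bin_size, counts, chrom_length) {
  stopifnot(bin_size > 0, all(counts >= 0),
            length(counts) == ceiling(chrom_length / bin_size))
  structure(list(chrom = chrom, bin_size = bin_size,
                 counts = as.numeric(counts), chrom_length = chrom_length),
            class = "coverage_track")
}

#' Simulate ChIP and Input coverage over a centromere
#'
#' Input bins are Poisson(`mean_depth`) everywhere; ChIP bins are
#' Poisson(`mean_depth * enrichment_factor`) for bins whose midpoint lies in
#' the centromere and Poisson(`mean_depth`) elsewhere. Coverage is simulated
#' directly at bin level; read-level effects are out of scope.
#'
#' @param chrom_length chromosome length in nt.
#' @param centromere `[start, end)` interval (may be empty).
#' @param enrichment_factor ChIP fold change inside the centromere (>= 1).
#' @param mean_depth expected counts per bin (> 0).
#' @param bin_size bin width in nt (> 0).
#' @param chrom chromosome name.
#' @param seed optional seed.
#' @return list with `chip` and `input` [coverage_track()]s.
#' @export
simulate_chip <- function(chrom_length, centromere, enrichment_factor = 4,
                          mean_depth = 100, bin_size = 10000, chrom = "chr1",
                          seed = NULL) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  check_interval(centromere, "centromere")
  with_opt_seed(seed, {
    nbins <- ceiling(chrom_length / bin_size)
    starts <- (seq_len(nbins) - 1) * bin_size
    ends <- pmin(starts + bin_size, chrom_length)
    mids <- (starts + ends) / 2
    inside <- mids >= centromere[1] & mids < centromere[2]
    input <- stats::rpois(nbins, mean_depth)
    chip <- stats::rpois(nbins, mean_depth * ifelse(inside, enrichment_factor, 1))
    list(chip = coverage_track(chrom, bin_size, chip, chrom_length),
         input = coverage_track(chrom, bin_size, input, chrom_length))
  })
}

# ---------------------------------------------------------------------------
# serialization of a simulation

#' Write a simulation and its ground truth to disk
#'
#' Emits genome FASTA, truth elements GFF3 (attributes `family_id`,
#' `true_age_Ma`, `tsd`), truth centromere BED (0-based half-open), ChIP and
#' Input bedGraph, and a YAML echo of the spec. Deterministic given the spec.
#'
#' @param sim a `cen_sim` from [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             elements = file.path(dir, "truth_elements.gff3"),
             centromere = file.path(dir, "truth_centromere.bed"),
             chip = file.path(dir, "chip.bedgraph"),
             input = file.path(dir, "input.bedgraph"),
             spec = file.path(dir, "spec.yaml"))
  write_fasta(stats::setNames(sim$seq, sim$chrom), paths["genome"])
  write_elements_gff3(sim$truth$elements, paths["elements"])
  write_bed(data.frame(chrom = sim$chrom, start = sim$truth$centromere[1],
                       end = sim$truth$centromere[2], name = "centromere"),
            paths["centromere"])
  tr <- simulate_chip(sim$chrom_length, sim$truth$centromere,
                      sim$spec$enrichment_factor, sim$spec$mean_depth,
                      sim$spec$bin_size, sim$chrom, seed = sim$spec$seed + 1L)
  write_bedgraph(tr$chip, paths["chip"])
  write_bedgraph(tr$input, paths["input"])
  spec_plain <- unclass(sim$spec)
  spec_plain$families <- lapply(sim$families, unclass)
  yaml::write_yaml(spec_plain, paths["spec"])
  invisible(paths)
}
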