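# End-to-end pipeline on a synthetic locus: simulate -> delimit -> detect ->
# date -> classify -> compare -> report. The pipeline is pure given
# (config, seed): re-running with the same config reproduces every output.

#' Pipeline configuration
#'
#' Collects the per-module parameter blocks and validates them before any
#' stage runs. Defaults describe the bundled desk-scale synthetic locus;
#' delimitation parameters are scaled to its 2 kb bins.
#'
#' @param simulation a [simulation_spec()].
#' @param enrichment list: `threshold` (log2), `merge_gap`, `min_len` (nt),
#'   `epsilon`.
#' @param detector a [detector_params()].
#' @param rate substitution rate r (/site/year).
#' @param min_identity classification threshold.
#' @param subgenome subgenome label for the simulated chromosome.
#' @param seed master seed; overrides the simulation spec's seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_spec(),
                            enrichment = list(threshold = 1.0,
                                              merge_gap = 10000,
                                              min_len = 20000,
                                              epsilon = 0.5),
                            detector = detector_params(),
                            rate = 1.3e-8,
                            min_identity = 0.80,
                            subgenome = "AA",
                            seed = NULL) {
  stopifnot(inherits(simulation, "simulation_spec"),
            inherits(detector, "detector_params"))
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  if (rate <= 0) stop("rate must be > 0")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]")
  for (f in c("threshold", "merge_gap", "min_len", "epsilon")) {
    if (is.null(enrichment[[f]])) stop("enrichment block missing field: ", f)
  }
  structure(list(simulation = simulation, enrichment = enrichment,
                 detector = detector, rate = rate,
                 min_identity = min_identity, subgenome = subgenome),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic locus
#'
#' Simulates the genome and coverage, delimits the CENH3 domain from the
#' log2(ChIP/Input) track, detects full-length LTR retrotransposons, dates
#' them from LTR divergence, classifies them against the simulation's own
#' family library, and summarises ages per compartment (inside vs outside the
#' called centromere) with a Mann-Whitney comparison. When `outdir` is given,
#' all standard files are emitted there (FASTA, GFF3, BED, bedGraph, TSVs and
#' a YAML parameter log).
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list of class `cenarch_run` with `sim`, `tracks`, `ratio`,
#'   `calls`, `summary`, `elements`, `dated`, `assignments`, `copy_table`,
#'   `age_tests`, `files`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_genome(config$simulation)
  tracks <- simulate_chip(sim$chrom_length, sim$truth$centromere,
                          config$simulation$enrichment_factor,
                          config$simulation$mean_depth,
                          config$simulation$bin_size, sim$chrom,
                          seed = config$simulation$seed + 1L)
  ratio <- compute_ratio_track(tracks$chip, tracks$input,
                               epsilon = config$enrichment$epsilon)
  calls <- call_enriched_intervals(ratio,
                                   threshold = config$enrichment$threshold,
                                   merge_gap = config$enrichment$merge_gap,
                                   min_len = config$enrichment$min_len)
  summary <- if (nrow(calls)) {
    summarize_centromeres(calls[calls$primary, , drop = FALSE],
                          stats::setNames(config$subgenome, sim$chrom))
  } else NULL
  elements <- detect_flltrs(sim$seq, config$detector, chrom = sim$chrom)
  dated <- date_elements(elements, stats::setNames(sim$seq, sim$chrom),
                         r = config$rate)
  lib <- family_library(sim$families, min_identity = config$min_identity)
  seqs <- stats::setNames(substring(sim$seq, elements$start + 1, elements$end),
                          elements$id)
  assignments <- assign_families(seqs, lib)
  assignments <- cbind(assignments[, setdiff(names(assignments), "id")],
                       elements[, c("id", "chrom", "start", "end")])
  cen_calls <- calls[calls$primary, , drop = FALSE]
  copy_table <- crw_copy_table(assignments, cen_calls)
  # centromeric vs outside insertion ages
  age_tests <- NULL
  if (nrow(cen_calls) == 1 && any(dated$valid)) {
    mid <- (dated$start + dated$end) / 2
    inside <- mid >= cen_calls$start & mid < cen_calls$end
    a <- dated$age_ma[inside & dated$valid]
    b <- dated$age_ma[!inside & dated$valid]
    if (length(a) >= 1 && length(b) >= 1) {
      mw <- mann_whitney_u(a, b, "two.sided")
      age_tests <- data.frame(group_a = "centromeric", group_b = "outside",
                              n_a = length(a), n_b = length(b),
                              median_a = stats::median(a),
                              median_b = stats::median(b),
                              U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
  }
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- write_simulation(sim, outdir)
    files <- c(files,
               calls = write_calls(calls, file.path(outdir, "centromere_calls.bed")),
               detected = write_elements_gff3(elements, file.path(outdir, "elements.gff3")),
               dating = write_dating_tsv(dated, file.path(outdir, "dating.tsv")),
               assignments = write_tsv_file(assignments, file.path(outdir, "assignments.tsv")))
    log <- list(detector = unclass(config$detector),
                enrichment = config$enrichment, rate = config$rate,
                min_identity = config$min_identity,
                seed = config$simulation$seed,
                package_version = as.character(utils::packageVersion("cenarch")))
    yaml::write_yaml(log, file.path(outdir, "run_parameters.yaml"))
    files <- c(files, log = file.path(outdir, "run_parameters.yaml"))
  }
  structure(list(sim = sim, tracks = tracks, ratio = ratio, calls = calls,
                 summary = summary, elements = elements, dated = dated,
                 assignments = assignments, copy_table = copy_table,
                 age_tests = age_tests, files = files),
            class = "cenarch_run")
}

write_calls <- function(calls, path) {
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- calls[, c("chrom", "start", "end")]
  bed$name <- ifelse(calls$primary, "primary", "secondary")
  write_bed(bed, path)
}

#' @export
print.cenarch_run <- function(x, ...) {
  cat("cenarch pipeline run\n")
  cat("  genome:", x$sim$chrom, "-", x$sim$chrom_length, "nt\n")
  cat("  centromere calls:", nrow(x$calls), "\n")
  cat("  elements detected:", nrow(x$elements),
      sprintf("(%d dated valid)", sum(x$dated$valid)), "\n")
  invisible(x)
}
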