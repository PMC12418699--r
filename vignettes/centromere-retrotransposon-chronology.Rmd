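---
title: "Centromere delimitation and LTR retrotransposon chronology with cenarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centromere delimitation and LTR retrotransposon chronology with cenarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenarch)
```

## The scientific problem

Centromeres of large plant genomes — allopolyploid wheat being the canonical
case — are built largely from centromere-specific LTR retrotransposons
rather than satellite arrays. Because the two long terminal repeats (LTRs)
of a retrotransposon are identical at the moment of insertion and then
diverge independently, every full-length element is a dated fossil: its
5′/3′ LTR divergence, read through a substitution model, gives the time
since insertion. Combining (i) CENH3 ChIP-based delimitation of the
functional centromere, (ii) structural detection of full-length elements,
(iii) molecular dating, and (iv) family classification yields a chronology
of how retrotransposon invasions built and reshaped each centromere.

cenarch implements that workflow as composable R functions, together with a
synthetic-genome generator that plants elements of known age so that every
stage can be validated against ground truth.

## CENH3 enrichment and centromere delimitation

ChIP and Input coverage enter as binned counts (bedGraph or
`coverage_track` objects). `compute_ratio_track()` scales both tracks to
counts per million (CPM) and computes per-bin
`log2((chip + eps) / (input + eps))` with a pseudocount `eps = 0.5` to keep
empty bins finite. CPM is the default because ChIP and Input libraries have
unrelated sequencing depths; note that per-library scaling deliberately
removes any global fold difference between the two libraries — only
*relative* enrichment along the chromosome is meaningful. `normalize =
"none"` is available when the inputs are already on a common scale.

`call_enriched_intervals()` delimits the centromere as the maximal runs of
bins at or above a log2 threshold (default 1.0, i.e. 2-fold), merging runs
separated by less than `merge_gap` and dropping merged runs shorter than
`min_len`; the longest surviving interval per chromosome is the primary
call. The Mb-scale defaults (10 kb bins, 500 kb gap and minimum) reproduce
contiguous megabase-scale domains of the kind reported for wheat; on the
desk-scale simulated locus the pipeline scales them to its 2 kb bins. The
published delimitation procedure these defaults emulate is not fully
parameterised in the literature, so all values are exposed in the
configuration. Reported coordinates are 0-based half-open nucleotides
internally; Mb summaries round half-up to one decimal, the dialect of the
published tables (e.g. per-subgenome means 6.5 / 5.7 / 6.0 Mb from the 21
bundled intervals, where half-even rounding would disagree).

## Structural detection of full-length LTR retrotransposons

`detect_flltrs()` is an ab initio single-pass detector with the structural
parameterisation standard for plant genomes: exact 30 nt seeds between the
two prospective LTR copies, greedy x-drop extension (match +2, mismatch −2,
x-drop 5), LTR length 100–2000 nt, 5′-to-3′ LTR start distance 3–25 kb,
pair identity ≥ 0.85, TSD of 4–20 bp, TG…CA termini with at most one
mismatch, and a ±60 nt boundary-refinement vicinity.

Design choices worth knowing:

* **Ungapped extension.** The x-drop extension is substitution-only; the
  indel score in `detector_params()` applies to the gapped alignments used
  downstream (similarity, dating). Post-insertion LTR divergence at the
  ages of interest is dominated by substitutions, and an ungapped extension
  makes the detector's acceptance exactly checkable by a brute-force
  all-diagonal oracle (the test suite does this on ≤ 20 kb windows).
* **Length cap as a chimera guard.** Extensions that exceed the maximal
  LTR length are discarded; this is what rejects tandem satellite arrays
  and whole-element matches between two copies of the same family.
* **Distance convention.** `min_dist`/`max_dist` bound the distance from
  5′ LTR start to 3′ LTR start.
* **Boundary refinement.** Within the vicinity of each provisional
  boundary the detector searches for an exact direct repeat of 4–20 bp
  flanking both ends (the TSD) and TG…CA termini. Evidence ranks
  TSD+motif > motif-only > TSD-only > none; among equal evidence the longer
  TSD wins, then the smallest boundary shift, and motif-only placements
  prefer exact termini. A boundary shift moves the corresponding boundary
  of *both* LTR copies, keeping the pair congruent. Because any 4-mer
  direct repeat in the vicinity is accepted as TSD evidence, an element
  that truly lacks a TSD can occasionally be annotated with a short
  spurious one — an ambiguity shared with the standard detectors.
* **Evidence filter.** With `require_evidence = TRUE` (default) an element
  lacking both TSD and motif is dropped. This is the integration-style
  false-positive filter; on the bundled decoy fixture (ten compliant
  elements, five decoys each violating one rule) detection achieves recall
  and precision 1.0.
* Overlapping candidates are resolved by highest LTR similarity, then
  longer span, then leftmost start. Soft-masked sequence is uppercased; N
  runs break seeds. The detector reports direct-repeat structure only and
  assigns "+" strand; without internal-domain evidence the orientation of
  an LTR pair is not identifiable (an element and its reverse complement
  present identical structure, including TG…CA termini).

## Molecular dating

For each element the two LTRs are aligned globally (match +2, mismatch −2,
linear gap −3). Gap and ambiguous columns are excluded; transitions
(A↔G, C↔T) and transversions are counted as fractions `P` and `Q` of the
retained columns, and the Kimura two-parameter distance is

K = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).

The insertion age is `K / (2 r)`, with the grass LTR clock
`r = 1.3e-8` substitutions/site/year as default; the factor 2 reflects the
independent divergence of the two copies. Elements outside the K2P domain
are kept with `valid = FALSE` and flag `"saturated"` rather than given a
number; elements with identical LTRs (K exactly 0) are *incipient*. K is
reported to 4 decimals and ages to 2 decimals (Ma) in the TSV writer. A
practical note: with an optimal pairwise aligner, saturation is nearly
unreachable for real 4-letter sequences (the aligner converts mismatch
excess into gapped chance matches), so the saturated path matters mainly
for degenerate inputs; the tests exercise it with disjoint-alphabet
repeats whose every alignment column is a transition.

On the simulator's study conditions (1.5 kb LTRs, 50 elements per age,
ages 0.2–2.0 Ma) the regression of estimated on true age has slope within
1 ± 0.1, and all age-0 elements report K = 0.

## Classification and trees

`best_hit_assign()` scores an element against each library consensus by
global-alignment identity over aligned columns (gaps count as mismatches)
and assigns the top family when identity ≥ 0.80, else `"other"`. Full-length
global identity is used rather than a local alignment score because a local
alignment awards identity 1.0 to any shared word, which would make the
threshold meaningless for full-length elements; random sequence scores
well below 0.8 under the global criterion.

`neighbor_joining()` implements Saitou–Nei agglomeration with the
Studier–Keppler Q-criterion on the package's own K2P distance matrix.
Distance-based NJ replaces likelihood tree search deliberately: the
downstream analysis consumes clade membership, not branch support, and NJ
reconstructs additive matrices exactly — the test suite verifies path
lengths to 1e-9 and checks topology against a brute-force least-squares
enumeration of all topologies. Ties in Q break by lexicographic label
pair; negative branch lengths are clamped to zero and counted. Saturated
pairs enter the matrix as 1.1 × the largest finite entry, flagged. K2P
distances need not satisfy the triangle inequality; no such property is
assumed. `clade_report()` assigns each element the family of its nearest
reference leaf by tree path length.

## Comparative analytics

* `dotplot()` compares non-overlapping windows (500 bp for
  centromere-scale comparisons, 300 bp for fine structure) in both
  orientations, reporting window pairs with global-alignment identity
  ≥ 0.85. A shared 12-mer prefilter skips pairs that cannot reach the
  threshold.
* `monomerize_and_heatmap()` chops a satellite array into fixed-length
  monomers (566 / 550 bp are the wheat unit sizes) and computes the
  all-vs-all identity matrix; trailing remainders are dropped and counted.
* `age_distribution()` summarises an age cohort with median, quartiles,
  incipient count and a Gaussian KDE (Silverman bandwidth; a fixed 0.05 Ma
  bandwidth for n = 1).
* `mann_whitney_u()` computes U from midranks; for `n_x + n_y <= 12` the
  p-value is exact by full enumeration of the observed rank multiset
  (valid under ties), otherwise a normal approximation with tie-corrected
  variance and continuity correction is used. Exact and approximate p
  agree within 0.02 at n = 8+8.
* `partition_regions()` labels every base of a domain by ancestral
  accession coverage count and derived coverage, yielding the five classes
  (covered by one / some / all ancestral sets, derived-only, neither) used
  to contrast old and newly formed centromere segments; elements map to
  segments by midpoint (boundary midpoints belong to the right-hand
  segment). Region numbers in the published figures are positional; the
  classes here are order-free with a fixed numbering map (1 =
  ancestral_one, 2 = derived_only, 3 = ancestral_some, 4 = neither, 5 =
  ancestral_all).
* `crw_copy_table()` tabulates family-by-centromere copy counts and rolls
  superfamily percentages up to one decimal (half-up).

## The synthetic generator: what it emulates, and what it does not

`simulate_genome()` produces a uniform-ACGT background with planted
full-length elements. The substitution process is per-site Poisson event
counts; each event is a transition with probability `kappa/(kappa+2)`
(default kappa = 2, i.e. transition and pooled-transversion events equally
likely). K2P estimation is consistent for any kappa, so acceptance results
do not depend on this free parameter. Both LTRs (and the internal region)
mutate independently with expected `r·t` substitutions per site, giving
E[K] ≈ 2rt. TSDs are drawn uniformly at 4–20 bp; elements carry TG…CA
termini by construction. Coverage is simulated at bin level
(Poisson(depth) Input everywhere, Poisson(depth × enrichment) ChIP inside
the centromere); read-level artefacts are out of scope.

Deliberate simplifications: no indels, no nested insertions, no GC or
mappability bias, no truncation except as an explicit decoy, and
same-family insertions are kept at least `max_dist` + 2 kb apart — two
nearby same-family copies would present a cross-element LTR pairing that a
purely structural detector cannot distinguish from a genuine element, and
keeping the planted truth unambiguous is what makes recall/precision
measurable. Consequently, passing tests demonstrate correctness of the
algorithms under clean structural conditions; they do not certify
performance on real genomes with nested, truncated and recombined
elements, which is why every threshold is exposed rather than hard-coded.

Desk-scale problem sizes used throughout the package's own validation: a
400 kb chromosome with a 100 kb centromere and twelve 4.6 kb elements for
the end-to-end pipeline; a 500 kb fixture with ten compliant elements and
five decoys for detection; 50 LTR pairs per age point for clock recovery;
200 Mb of 10 kb bins for delimitation. These sizes were chosen so the full
validation remains interactive while keeping every statistical check
well-powered.

## Reproducibility and numerical conventions

All coordinates are 0-based half-open internally; conversion to 1-based
inclusive happens only at the GFF3 boundary. Mb reporting rounds half-up
to one decimal. Every stochastic function takes a seed (or inherits the
caller's RNG stream), and `run_pipeline()` re-running under the same
configuration writes byte-identical files. The bundled survey tables
(21 centromere intervals, superfamily and subgenome element counts for
hexaploid wheat) are shipped as printed in the literature; the
per-superfamily tallies carry a known off-by-one relative to the
per-subgenome total (3596 vs 3595), and both are reported as printed.

## Known limitations

* Strand of detected elements is not inferred (no internal-domain scan).
* The detector's TSD search can report a short spurious direct repeat for
  elements genuinely lacking one.
* K2P saturation handling treats the affected pair conservatively
  (flagged, or capped in distance matrices) rather than modelling it.
* The enrichment caller assumes one dominant centromere per chromosome;
  polycentric or holocentric organisation would need different post-rules.
* Real-data quantities from the wheat literature that require the full
  assembly and ChIP accessions (per-centromere copy numbers, region
  medians, between-generation R²) are represented here only by
  property-based synthetic analogues.
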