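---
title: "Detecting crossovers and copy-number variation in allopolyploid hybrid gametes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting crossovers and copy-number variation in allopolyploid hybrid gametes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscan)
```

## The biological problem

*Brassica* interspecific hybrids with an AABC or CCAB genome complement
carry one diploid subgenome (A or C) and two haploid subgenomes. During
meiosis I the diploid subgenome forms bivalents and recombines normally,
while the closely related A and C subgenomes can also pair with each other
and exchange material non-homologously (homoeologous recombination). Both
processes leave characteristic footprints in SNP-array data from
gamete-derived individuals:

* **Homologous crossovers** appear as switches in parental origin along a
  chromosome — in a reduced gamete, a transition between runs of the two
  parental homozygotes; in an unreduced gamete formed by first-division
  restitution (FDR), a switch between heterozygosity and homozygosity.
* **Homoeologous exchanges** appear as regions carrying both parental
  alleles (or neither), and as copy-number shifts in the log R ratio (logR)
  and B-allele frequency (BAF) signals — three-copy regions sit at the
  AAB/BBA BAF ratios 1/3 and 2/3.
* **Aneuploidy** (whole-chromosome gain or loss) shifts logR across the
  entire chromosome.

meioscan codifies the detection of all three event classes into explicit,
configurable rules, and pairs them with a chromatid-level meiosis simulator
so that every stage can be verified against known ground truth.

## Genotype filtering and recoding

Markers are filtered per cross-combination with four rules, applied
independently to the raw matrix and intersected:

1. markers with more than 70% heterozygous (AB) calls across all parent
   genotypes are dropped (`max_parent_het_fraction = 0.70`);
2. markers with more than 90% no-calls across all lines are dropped
   (`max_missing_fraction = 0.90`);
3. the combination's two parents must be homozygous for different alleles
   ("homozygous in and polymorphic between");
4. the F1 hybrid parent must be heterozygous.

Both fraction thresholds are strict "over" comparisons: a marker at exactly
the threshold is kept. Rule 1 pools the parental columns of every
combination in the run, and rule 2 pools every column; this is the broadest
reading of "all parent genotypes" / "all lines" and makes the kept set for
one combination depend on other combinations only through these two
population-level screens. Progeny calls at kept markers are recoded to
parental-origin symbols: the *B. napus* parent's homozygote becomes `a`,
the other parent's `b`, heterozygous calls `h`, and no-calls stay missing.
By convention `parent1_id` in the metadata is the *B. napus* parent.

## Crossover calling

Per individual and chromosome, the recoded vector passes through four
stages.

**Missing-run masking.** Runs of missing calls longer than
`na_deletion_min_run` are putative chromosomal deletions: they are recorded
and masked, and crossover evaluation never joins the flanking segments
across them. Shorter missing runs are imputed to the flanking state when
both flanks agree (this is the imputation step that precedes haplotype
profiling), otherwise left missing and dropped.

**Heterozygous runs.** For reduced gametes, `h` runs of qualifying length
are non-homologous signals (both parental alleles present), so they are
masked exactly like deletions and surface as translocation events instead.
For unreduced FDR gametes, `h` is a legitimate run state: FDR gametes are
heterozygous from the centromere outward and switch to homozygosity distal
to a crossover, so het–hom transitions *are* the crossover signal there.
This asymmetry is the package's resolution of treating heterozygous
regions as "non-homologous signals, not crossovers": it is true for
reduced gametes and false for unreduced ones.

**Run-length smoothing.** The vector is run-length encoded and the
leftmost run shorter than `min_run` is replaced by the preceding run's
value (the first run, if short, takes the following run's value); adjacent
equal runs merge, and the process iterates to a fixpoint. The replacement
direction is a deterministic choice the underlying rule description leaves
open; iterating leftmost-first to fixpoint makes the result well defined
and idempotent. One consequence worth knowing: the transition count is not
strictly monotone between neighbouring `min_run` values, because
replacement cascades can resolve differently — about 4% of random
80-marker sequences yield more transitions at an intermediate `min_run`
than at the one below it. The production extremes order as expected
(smoothing at 15 never yields more breakpoints than at 3 in 5,000 random
sequences), and terminal short runs are replaced like interior runs, which
suppresses near-telomeric single-marker transitions.

**Minimum crossover distance.** Surviving transitions whose midpoints lie
closer than `min_co_distance_bp` (default 2 Mb) are merged: the enclosed
segment is "too short to comprise a crossover" and takes the left flank's
state, which removes both transitions when the flanks agree and one when
they differ. Breakpoints are reported as the inter-marker interval between
the last marker of the left run and the first marker of the right run,
with the interval midpoint used for binning.

**Choosing `min_run`.** Candidate minimum run lengths 3–30 are evaluated
per chromosome across the population; any candidate for which some
individual yields more than `qc_max_breakpoints = 20` breakpoints signals
a data-quality problem and is inadmissible. The chosen value is the
smallest admissible member of the production set {5, 10, 13, 15}; if none
is admissible the largest production value (15) is used and a QC flag is
recorded in the run manifest together with the per-chromosome choices.

## Copy-number calling

The allele-specific copy-number stage is a transparent desk-scale
segmentation rather than a port of a black-box caller, which is used in
this setting only to produce segment means and cut-offs. logR is segmented
by recursive binary segmentation on segment means with a BIC-style penalty
`2·sigma²·log(n)`, sigma estimated robustly from first differences
(`mad(diff(x))/sqrt(2)`), so a noise-free constant signal yields exactly
one segment and a noise-free step is split at the exact boundary. Segments
need at least `min_segment_markers = 10` markers. Each segment gets a
mirrored-BAF state (fold at 0.5, nearest-centre assignment to 0, 1/3,
1/2): a dominant 1/3 cluster marks the three-copy AAB/BBA state; a
substantial 1/2 cluster marks heterozygosity (on population-polymorphic
markers a het region mixes BAF values 0, 0.5 and 1, so the 0.5 cluster
need not be the majority).

Classification is monotone in the segment mean: at or below
`logr_del = −0.30` a deletion, at or above `logr_dup = +0.25` a
duplication, otherwise normal. The defaults bracket the single-copy
expectations on a two-copy baseline (−1 for a loss, +0.58 for a gain) with
generous allowance for shrinkage and noise, since the source analysis
reports only that "a specific threshold" was used. Events covering at
least 90% of a chromosome's marker span are labelled whole-chromosome.

## Non-homologous events and breakpoint exclusion

Events that were curated manually in the original analysis are codified
here as threshold rules on the stated evidence types:

* **Reduced gametes** — `h` runs of at least `na_deletion_min_run` markers
  are translocation-type events (both parental alleles present); missing
  runs qualifying as deletions require a corroborating copy-number
  deletion; copy-number duplications overlapping normal `a`/`b` runs are
  translocation-type.
* **Unreduced gametes** — segments at the 1/3–2/3 BAF ratio or with a
  non-normal copy-number class become events; NC-dominated deletion
  segments are deletion-type.

Events touching the first or last kept marker are terminal, others
interstitial. Homoeologous origin is inferred, not proven — events are
putative, and no attempt is made to identify the donor chromosome (the
array's SNPs are subgenome-specific). Crossovers whose interval overlaps a
non-homologous event expanded by `margin_bp = 500` kb are relabelled
`excluded_nonhomologous`; homologous + excluded always equals the raw
count, so the exclusion is an auditable partition, not a deletion.

## Distributions and statistics

Homologous crossover midpoints are binned into fixed 1 Mb windows,
half-open and anchored at bp 1 (a midpoint exactly on a boundary falls in
the right-hand window; the last partial window is kept). Events at
identical (chromosome, interval) positions across the merged reduced +
unreduced dataset collapse into a unique-crossover set; both raw and
unique sets are classified against the centromere and pericentromere
(centromere containment tested first, midpoint-based). Counts are compared
with Pearson's chi-square test (no continuity correction, zero expected
counts rejected), genotype effects with one-way ANOVA followed by LSD
pairwise comparisons and a compact letter display at P < 0.01, and
chromosome length versus crossover count with Pearson correlation.

## What the simulator emulates — and what it does not

`simulate_population()` generates, per gamete and per diploid-subgenome
chromosome, a four-chromatid bivalent with Poisson(`co_rate = 2`)
crossovers (optionally zero-truncated for the obligate crossover; off by
default so `co_rate` is the exact mean). Crossover positions are uniform
(or telomere-biased) with density scaled by `centromere_suppression`
(default 0: fully suppressed) inside the centromere, and each crossover
exchanges the chromatid arm segments distal to its position relative to
the centromere. Reduced gametes take one chromatid; FDR gametes take one
chromatid from each homolog, preserving centromeric heterozygosity.
Structural events are layered on physical copies: homoeologous exchanges
(terminal by default, 20% interstitial) delete one copy of an interval on
one side and duplicate it on the homoeologue, and whole-chromosome
loss/gain removes or duplicates a copy; at most one event per chromosome
per gamete keeps the truth log unambiguous. Signals follow allele dosage:
logR = log2(copies/expected) with the euploid gamete complement as
baseline, BAF = B-dose/total, Gaussian noise (`noise_sd_logr = 0.15`,
`noise_sd_baf = 0.03`), and a 5% no-call rate. Zero-copy regions emit NC
with logR floored at −2. Default structural rates
(`p_nonhom_exchange = 0.75`, `p_whole_chrom_loss = 0.2`,
`p_whole_chrom_gain = 0.1`, losses deliberately more common than gains)
put the fraction of affected gametes near 0.8, in the range reported for
these hybrid populations.

The simulator deliberately omits: crossover interference and chromatid
interference (counts are Poisson), B-genome markers, test-cross allele
deduction (all individuals are modelled at the gamete level, as
microspore-derived material), partial marker informativeness by default
(parents are fully divergent; `marker_informativeness < 1` exercises the
polymorphism filter), segregating parental translocations, and
sequence-level artefacts such as probe cross-hybridisation. Passing
recovery tests on simulated data therefore demonstrates the correctness of
the calling rules under the generative model, not their robustness to
every failure mode of real array data — in particular, real non-homologous
calls involve judgement about signal quality that threshold rules only
approximate.

Randomness flows from one seeded global stream (`config$seed`), which
makes runs bit-reproducible; per-gamete substreams would only matter for
parallel generation, which is out of scope.

```{r simulate-example}
cfg <- sim_config(
  markers_per_chromosome = 50L, n_chrom_a = 2L, n_chrom_c = 2L,
  chrom_lengths_bp = c(A1 = 30e6, A2 = 34e6, C1 = 42e6, C2 = 46e6),
  combinations = data.frame(
    combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
    n_reduced = 4L, n_unreduced = 4L, co_rate = NA_real_
  ),
  seed = 1L
)
sim <- simulate_population(cfg)
res <- run_pipeline_stages(sim$calls, sim$map, sim$arch, sim$meta,
                           quiet = TRUE)
table(res$crossovers$subtype)
score_crossover_recovery(res$crossovers, sim$truth, sim$map)[
  c("recovery", "fp_rate")
]
```

## Numerical and design choices

* **Coordinates** are 1-based and closed on marker positions throughout;
  BED inputs are converted on read. This matches the marker-position
  semantics of array maps.
* **Missing cells**: empty/NA/NaN numeric cells become NA; missing
  genotype cells become NC, which downstream is one class with no-calls.
* **Degenerate inputs**: chromosomes with fewer markers than
  `min_segment_markers` return a single segment with a warning; groups
  with one observation are excluded from the ANOVA with a warning; empty
  event sets propagate as header-only tables and zero counts.
* **Rule-evaluation order** for filtering (rules computed independently on
  the raw matrix, then intersected) was chosen over sequential filtering
  because it makes each rule's report column interpretable in isolation;
  with the default thresholds the two orders give identical kept sets on
  all fixtures tested.
* **Ambiguous dataset for the centromeric-crossover claim**: both the raw
  and deduplicated region classifications are emitted, since either could
  underlie a per-chromosome centromere-crossover statement.
* **Problem sizes**: the verification suite enumerates all two-state
  sequences to length 12 exhaustively for the smoothing rules, and uses
  populations of 200 gametes (19 chromosomes × 200 markers) for crossover
  recovery, 30 unreduced gametes for copy-number recovery, 2,000 FDR
  gametes for the segregation-ratio checks, and 10,000 replicates for the
  chi-square calibration. The acceptance workflow simulates the full study
  layout (42 reduced + 76 unreduced AABC, 43 reduced + 92 unreduced CCAB
  individuals across their cross-combinations).

## Known limitations

* The codified non-homologous rules will not reproduce manual curation
  exactly; thresholds (`logr_del`, `logr_dup`, BAF tolerance, margins) are
  exposed in the configuration for recalibration against curated data.
* Crossovers inside masked regions (deletions, reduced-gamete `h` runs)
  are undetectable by construction; recovery statements always refer to
  eligible crossovers (at least 2 Mb from their neighbours and `min_run`
  markers from chromosome ends).
* Unreduced-gamete crossovers that involve both sampled chromatids (or
  neither) are invisible to any genotype-based method — FDR genetics, not
  a software limitation; expect roughly half of the bivalent's crossovers
  to be observable per unreduced gamete.
* Per-chromosome `min_run` selection depends on population-wide data
  quality; the manifest records every choice and QC flag so that runs are
  auditable and comparable.
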