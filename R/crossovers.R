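# Homologous crossover calling from recoded genotype vectors.
#
# Stages per individual x chromosome:
#   1. mask_na_deletions: long missing runs become putative deletions and
#      split the chromosome; short missing runs are imputed from agreeing
#      flanks or dropped.
#   2. For reduced gametes, long h runs are masked the same way (they are
#      non-homologous signals, handled by the nonhom module); for unreduced
#      (FDR) gametes h is a legitimate run state, since crossovers there
#      appear as het<->hom switches.
#   3. smooth_runs: iterated run-length replacement until every run reaches
#      min_run markers.
#   4. Transitions between states are candidate breakpoints; candidates
#      whose midpoints lie closer than min_co_distance_bp are merged away
#      (the enclosed segment takes the left flank's state).

#' Smoothing and crossover-calling parameters
#'
#' @param min_run minimum run length in markers (candidates 3–30; production
#'   values 5, 10, 13, 15).
#' @param na_deletion_min_run missing-run length above which a run is called
#'   a deletion; defaults to `min_run`.
#' @param min_co_distance_bp minimum distance between successive crossover
#'   midpoints (default 2 Mb).
#' @param qc_max_breakpoints per-chromosome breakpoint count above which a
#'   candidate min_run is considered to indicate data-quality problems
#'   (default 20).
#' @return a `smoothing_params` list.
#' @export
smoothing_params <- function(min_run = 5L,
                             na_deletion_min_run = min_run,
                             min_co_distance_bp = 2e6,
                             qc_max_breakpoints = 20L) {
  stopifnot(min_run >= 1, na_deletion_min_run >= 1, min_co_distance_bp > 0)
  structure(
    list(
      min_run = as.integer(min_run),
      na_deletion_min_run = as.integer(na_deletion_min_run),
      min_co_distance_bp = as.double(min_co_distance_bp),
      qc_max_breakpoints = as.integer(qc_max_breakpoints)
    ),
    class = "smoothing_params"
  )
}

#' Smooth a symbol sequence by iterated run-length replacement
#'
#' Repeatedly run-length encodes the sequence and replaces the leftmost run
#' shorter than `min_run` with the value of the preceding run (the first
#' run, if short, takes the following run's value); adjacent equal runs
#' merge, and the process iterates to a fixpoint: all runs have length
#' `>= min_run`, or a single run remains. Idempotent.
#'
#' @param symbols character vector of run states.
#' @param min_run minimum run length.
#' @return smoothed character vector, same length.
#' @export
smooth_runs <- function(symbols, min_run) {
  stopifnot(length(symbols) >= 1, min_run >= 1)
  repeat {
    r <- rle(symbols)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    i <- short[1L]
    r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
    symbols <- inverse.rle(r)
  }
  symbols
}

#' Mask long missing runs as deletions and impute short ones
#'
#' Runs of `missing` longer than `na_min_run` are recorded as deletion
#' intervals and masked: crossover evaluation never joins the flanking
#' segments across them. Shorter missing runs are imputed to the flanking
#' state when both flanks agree, otherwise left missing.
#'
#' @param symbols character vector over a/b/h/missing.
#' @param positions_bp marker positions aligned to `symbols`.
#' @param na_min_run threshold run length.
#' @param mask_state which state to treat as maskable (default "missing";
#'   used with "h" to mask heterozygous runs in reduced gametes).
#' @return list with `symbols` (imputed), `masked` (logical: marker inside a
#'   masked run) and `deletions` (data.frame chromosome-less intervals:
#'   start_bp, end_bp, n_markers).
#' @export
mask_na_deletions <- function(symbols, positions_bp, na_min_run,
                              mask_state = "missing") {
  stopifnot(length(symbols) == length(positions_bp))
  n <- length(symbols)
  masked <- logical(n)
  dels <- list()
  r <- rle(symbols)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != mask_state) next
    idx <- starts[k]:ends[k]
    if (r$lengths[k] > na_min_run) {
      masked[idx] <- TRUE
      dels[[length(dels) + 1L]] <- data.frame(
        start_bp = positions_bp[starts[k]], end_bp = positions_bp[ends[k]],
        n_markers = r$lengths[k]
      )
    } else {
      left <- if (k > 1L) r$values[k - 1L] else NA_character_
      right <- if (k < length(r$values)) r$values[k + 1L] else NA_character_
      if (!is.na(left) && !is.na(right) && left == right &&
          left %in% c("a", "b", "h")) {
        symbols[idx] <- left
      }
    }
  }
  deletions <- if (length(dels)) do.call(rbind, dels) else {
    data.frame(start_bp = double(0), end_bp = double(0), n_markers = integer(0))
  }
  list(symbols = symbols, masked = masked, deletions = deletions)
}

# transitions of a smoothed state sequence: data.frame of
# (start_bp, end_bp, midpoint_bp, left_state, right_state)
state_transitions <- function(symbols, positions_bp) {
  r <- rle(symbols)
  if (length(r$lengths) <= 1L) {
    return(data.frame(
      start_bp = double(0), end_bp = double(0), midpoint_bp = double(0),
      left_state = character(0), right_state = character(0),
      stringsAsFactors = FALSE
    ))
  }
  ends <- cumsum(r$lengths)
  k <- length(r$lengths) - 1L
  left_pos <- positions_bp[ends[seq_len(k)]]
  right_pos <- positions_bp[ends[seq_len(k)] + 1L]
  data.frame(
    start_bp = left_pos, end_bp = right_pos,
    midpoint_bp = floor((left_pos + right_pos) / 2),
    left_state = r$values[seq_len(k)], right_state = r$values[seq_len(k) + 1L],
    stringsAsFactors = FALSE
  )
}

# merge transitions closer than min_dist: the run enclosed by the offending
# pair takes the left flank's state (removing both transitions when the
# flanks agree, one when they differ); leftmost-first, to fixpoint.
merge_close_transitions <- function(symbols, positions_bp, min_dist) {
  repeat {
    tr <- state_transitions(symbols, positions_bp)
    if (nrow(tr) < 2L) return(list(symbols = symbols, transitions = tr))
    gaps <- diff(tr$midpoint_bp)
    bad <- which(gaps < min_dist)
    if (!length(bad)) return(list(symbols = symbols, transitions = tr))
    j <- bad[1L]
    r <- rle(symbols)
    # transition j sits between runs j and j+1; run j+1 is enclosed
    r$values[j + 1L] <- r$values[j]
    symbols <- inverse.rle(r)
  }
}

#' Call crossover breakpoints on one recoded chromosome vector
#'
#' Applies deletion masking, optional heterozygous-run masking (reduced
#' gametes), run-length smoothing and the minimum-crossover-distance merge,
#' then reports every surviving state transition as a crossover event with
#' origin "homologous" (pending non-homologous exclusion).
#'
#' @param vec a `recoded_vector` (see [recode_progeny()]).
#' @param params a [smoothing_params()].
#' @param gamete_class "reduced" or "unreduced". For reduced gametes h runs
#'   are masked like deletions (both-allele regions are non-homologous
#'   signals); for unreduced gametes h is a valid run state and het<->hom
#'   transitions are crossovers.
#' @return list with `events` (canonical event table rows, event_type
#'   "crossover", subtype "homologous"), `transitions` (detailed breakpoint
#'   table with states and midpoints), `deletions` (masked missing-run
#'   intervals) and `het_blocks` (masked h-run intervals, reduced only).
#' @export
call_crossovers <- function(vec, params = smoothing_params(),
                            gamete_class = c("reduced", "unreduced")) {
  gamete_class <- match.arg(gamete_class)
  sym <- vec$symbols
  pos <- vec$positions_bp
  na_mask <- mask_na_deletions(sym, pos, params$na_deletion_min_run)
  sym <- na_mask$symbols
  masked <- na_mask$masked
  het_blocks <- data.frame(
    start_bp = double(0), end_bp = double(0), n_markers = integer(0)
  )
  if (gamete_class == "reduced") {
    # h runs of qualifying length are putative non-homologous regions; the
    # spec rule is ">= na_deletion_min_run", hence threshold - 1 here
    h_mask <- mask_na_deletions(
      sym, pos, params$na_deletion_min_run - 1L, mask_state = "h"
    )
    sym <- h_mask$symbols
    masked <- masked | h_mask$masked
    het_blocks <- h_mask$deletions
  }
  valid_states <- if (gamete_class == "reduced") c("a", "b") else c("a", "b", "h")

  # segments are maximal unmasked index ranges; crossovers never span masks
  seg_id <- cumsum(masked)
  keep <- !masked & sym %in% valid_states
  trans <- list()
  for (sid in unique(seg_id[keep])) {
    sel <- keep & seg_id == sid
    s_sym <- sym[sel]
    s_pos <- pos[sel]
    if (length(s_sym) < 2L) next
    sm <- smooth_runs(s_sym, params$min_run)
    m <- merge_close_transitions(sm, s_pos, params$min_co_distance_bp)
    if (nrow(m$transitions)) trans[[length(trans) + 1L]] <- m$transitions
  }
  transitions <- if (length(trans)) do.call(rbind, trans) else
    state_transitions("a", 1)
  events <- if (nrow(transitions)) {
    data.frame(
      individual_id = vec$individual_id, chromosome = vec$chromosome,
      start_bp = transitions$start_bp, end_bp = transitions$end_bp,
      event_type = "crossover", subtype = "homologous",
      support = NA_integer_, stringsAsFactors = FALSE
    )
  } else {
    empty_event_table()
  }
  transitions$individual_id <- rep(vec$individual_id, nrow(transitions))
  transitions$chromosome <- rep(vec$chromosome, nrow(transitions))
  list(
    events = events, transitions = transitions,
    deletions = na_mask$deletions, het_blocks = het_blocks
  )
}

#' Choose the minimum run length per chromosome for a population
#'
#' Evaluates candidate minimum run lengths (3–30) on every individual's
#' vector for one chromosome. A candidate is inadmissible when any
#' individual yields more than `qc_max_breakpoints` breakpoints; the chosen
#' value is the smallest admissible member of the production set
#' (5, 10, 13, 15). When none is admissible the largest production value is
#' used and a QC flag raised.
#'
#' @param vectors list of `recoded_vector`s for one chromosome (one per
#'   individual).
#' @param gamete_classes character vector aligned to `vectors`.
#' @param params a [smoothing_params()] (its `min_run` is ignored).
#' @param candidates candidate run lengths to tabulate (default 3:30).
#' @param production the values eligible for selection (default 5, 10, 13, 15).
#' @return list with `chosen` (integer), `qc_flag` (logical) and
#'   `max_breakpoints` (named integer vector: worst individual count per
#'   candidate).
#' @export
select_min_run <- function(vectors, gamete_classes, params = smoothing_params(),
                           candidates = 3:30,
                           production = c(5L, 10L, 13L, 15L)) {
  if (!length(vectors)) stop("empty population")
  stopifnot(length(gamete_classes) == length(vectors))
  max_bp <- stats::setNames(integer(length(candidates)), candidates)
  for (ci in seq_along(candidates)) {
    p <- params
    p$min_run <- as.integer(candidates[ci])
    p$na_deletion_min_run <- p$min_run
    worst <- 0L
    for (vi in seq_along(vectors)) {
      n <- nrow(call_crossovers(vectors[[vi]], p, gamete_classes[vi])$events)
      if (n > worst) worst <- n
      if (worst > params$qc_max_breakpoints &&
          !(candidates[ci] %in% production)) break
    }
    max_bp[ci] <- worst
  }
  prod_in <- production[production %in% candidates]
  admissible <- prod_in[
    max_bp[as.character(prod_in)] <= params$qc_max_breakpoints
  ]
  if (length(admissible)) {
    list(chosen = min(admissible), qc_flag = FALSE, max_breakpoints = max_bp)
  } else {
    list(chosen = max(production), qc_flag = TRUE, max_breakpoints = max_bp)
  }
}

#' Count breakpoints per individual and chromosome
#'
#' @param events event table of crossover events (after non-homologous
#'   exclusion, i.e. subtype "homologous" rows are counted).
#' @param individuals character vector of all individuals (zero counts kept).
#' @param chromosomes character vector of chromosomes to tabulate.
#' @return list with `counts` (individual x chromosome integer matrix),
#'   `genome_total` (named per-individual totals) and `population_mean`
#'   (mean of the genome totals).
#' @export
count_breakpoints <- function(events, individuals, chromosomes) {
  counts <- matrix(
    0L, nrow = length(individuals), ncol = length(chromosomes),
    dimnames = list(individuals, chromosomes)
  )
  ev <- events[
    events$event_type == "crossover" & events$subtype == "homologous" &
      events$chromosome %in% chromosomes, , drop = FALSE
  ]
  if (nrow(ev)) {
    tab <- table(
      factor(ev$individual_id, levels = individuals),
      factor(ev$chromosome, levels = chromosomes)
    )
    counts[] <- as.integer(tab)
  }
  genome_total <- rowSums(counts)
  list(
    counts = counts, genome_total = genome_total,
    population_mean = mean(genome_total)
  )
}
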