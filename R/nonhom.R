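# Detection of putative non-homologous (homoeologous A-C) recombination
# events on the diploid subgenome, and exclusion of their breakpoints from
# homologous crossover counts.
#
# Reduced gametes carry one allele per locus, so a region showing both
# parental alleles (h run) implies a segment of the other homolog attached
# elsewhere (translocation), and a region with neither allele (missing run,
# corroborated by a copy-number deletion) implies a loss. Unreduced gametes
# are diploid in the focal subgenome, so exchanges appear as three-copy
# (AAB/BBA) BAF ratios or copy-number shifts rather than genotype classes.

#' Detect non-homologous events in a reduced gamete
#'
#' Rules: h runs of length `>= na_deletion_min_run` are translocation-type
#' events (both parental alleles present); missing runs qualifying as
#' deletions with a corroborating CNV deletion segment are deletion-type
#' events; CNV duplication segments overlapping normal a/b runs are
#' translocation-type events. Events touching the first or last kept marker
#' are "terminal", otherwise "interstitial".
#'
#' @param vec a `recoded_vector`.
#' @param cnv_segments classified segment table from [call_cnv()] for the
#'   same individual and chromosome (may be NULL).
#' @param params a [smoothing_params()] (its `na_deletion_min_run` is the
#'   minimum evidence run length).
#' @return canonical event table with event_type "nonhom", subtype
#'   "translocation"/"deletion"; columns `evidence` and `location_class`
#'   appended.
#' @export
detect_nonhom_reduced <- function(vec, cnv_segments = NULL,
                                  params = smoothing_params()) {
  sym <- vec$symbols
  pos <- vec$positions_bp
  first_bp <- pos[1]
  last_bp <- pos[length(pos)]
  rows <- list()
  add <- function(start, end, subtype, evidence, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      individual_id = vec$individual_id, chromosome = vec$chromosome,
      start_bp = start, end_bp = end, event_type = "nonhom",
      subtype = subtype, support = as.integer(n),
      evidence = evidence, stringsAsFactors = FALSE
    )
  }
  r <- rle(sym)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "h" && r$lengths[k] >= params$na_deletion_min_run) {
      add(pos[starts[k]], pos[ends[k]], "translocation", "het_calls",
          r$lengths[k])
    }
    if (r$values[k] == "missing" &&
        r$lengths[k] > params$na_deletion_min_run) {
      corroborated <- is.null(cnv_segments) || any(
        cnv_segments$cnv_class == "deletion" &
          cnv_segments$start_bp <= pos[ends[k]] &
          cnv_segments$end_bp >= pos[starts[k]]
      )
      if (corroborated) {
        add(pos[starts[k]], pos[ends[k]], "deletion",
            if (is.null(cnv_segments)) "nc_calls" else "nc_calls,cnv",
            r$lengths[k])
      }
    }
  }
  if (!is.null(cnv_segments)) {
    dups <- cnv_segments[cnv_segments$cnv_class == "duplication", ,
                         drop = FALSE]
    for (i in seq_len(nrow(dups))) {
      in_seg <- pos >= dups$start_bp[i] & pos <= dups$end_bp[i]
      if (any(sym[in_seg] %in% c("a", "b"))) {
        add(dups$start_bp[i], dups$end_bp[i], "translocation", "cnv",
            sum(in_seg))
      }
    }
  }
  out <- bind_events(rows)
  if (!nrow(out)) {
    out$evidence <- character(0)
    out$location_class <- character(0)
    return(out)
  }
  out$location_class <- ifelse(
    out$start_bp <= first_bp | out$end_bp >= last_bp, "terminal",
    "interstitial"
  )
  out <- out[!duplicated(out[c("start_bp", "end_bp", "subtype")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect non-homologous events in an unreduced gamete
#'
#' Segments whose mirrored BAF sits at the three-copy (1/3, 2/3) ratio or
#' whose copy-number class is non-normal become events: deletions when the
#' segment is a copy-number deletion or dominated by NC calls, otherwise
#' translocation-type (gained material from the other subgenome).
#'
#' @param individual_id,chromosome identifiers for the event rows.
#' @param cnv_segments classified segment table from [call_cnv()].
#' @param genotype optional genotype calls aligned to the chromosome's
#'   markers, used to flag NC-dominated segments.
#' @param positions_bp marker positions aligned to `genotype`.
#' @return canonical event table with `evidence` and `location_class`.
#' @export
detect_nonhom_unreduced <- function(individual_id, chromosome, cnv_segments,
                                    genotype = NULL, positions_bp = NULL) {
  rows <- list()
  first_bp <- cnv_segments$start_bp[1]
  last_bp <- cnv_segments$end_bp[nrow(cnv_segments)]
  for (i in seq_len(nrow(cnv_segments))) {
    s <- cnv_segments[i, ]
    is_third <- s$baf_state == "third_ratio"
    is_cnv <- s$cnv_class != "normal"
    if (!is_third && !is_cnv) next
    nc_dom <- FALSE
    if (!is.null(genotype) && !is.null(positions_bp)) {
      in_seg <- positions_bp >= s$start_bp & positions_bp <= s$end_bp
      nc_dom <- mean(genotype[in_seg] == "NC") > 0.5
    }
    subtype <- if (s$cnv_class == "deletion" || nc_dom) "deletion" else
      "translocation"
    evidence <- paste(
      c(
        if (is_third) "baf_third_ratio",
        if (is_cnv) "logr_shift",
        if (nc_dom) "nc_calls"
      ),
      collapse = ","
    )
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = individual_id, chromosome = chromosome,
      start_bp = s$start_bp, end_bp = s$end_bp, event_type = "nonhom",
      subtype = subtype, support = s$n_markers, evidence = evidence,
      location_class = if (s$start_bp <= first_bp || s$end_bp >= last_bp)
        "terminal" else "interstitial",
      stringsAsFactors = FALSE
    )
  }
  out <- bind_events(rows)
  if (!nrow(out)) {
    out$evidence <- character(0)
    out$location_class <- character(0)
  }
  out
}

#' Exclude crossovers at non-homologous event boundaries
#'
#' Any crossover whose breakpoint interval overlaps a non-homologous event
#' interval expanded by `margin_bp` is relabelled subtype
#' "excluded_nonhomologous"; the remainder stay "homologous".
#'
#' @param co_events crossover event table for one individual (or a whole
#'   population; matching is per individual and chromosome).
#' @param nonhom_events non-homologous event table.
#' @param margin_bp expansion margin (default 500 kb).
#' @return the crossover table with updated `subtype`.
#' @export
exclude_nonhom_breakpoints <- function(co_events, nonhom_events,
                                       margin_bp = 5e5) {
  if (!nrow(co_events) || !nrow(nonhom_events)) return(co_events)
  for (i in seq_len(nrow(co_events))) {
    hit <- nonhom_events$individual_id == co_events$individual_id[i] &
      nonhom_events$chromosome == co_events$chromosome[i] &
      nonhom_events$start_bp - margin_bp <= co_events$end_bp[i] &
      nonhom_events$end_bp + margin_bp >= co_events$start_bp[i]
    if (any(hit)) co_events$subtype[i] <- "excluded_nonhomologous"
  }
  co_events
}

#' Summarise non-homologous events across a population
#'
#' @param events non-homologous event table.
#' @param individuals all individual ids.
#' @param chromosomes chromosomes to tabulate.
#' @return list with `by_chromosome` (translocation/deletion counts of
#'   affected individuals per chromosome), `any_event` (named logical) and
#'   `fraction_affected`.
#' @export
summarize_nonhom <- function(events, individuals, chromosomes) {
  ev <- events[events$event_type == "nonhom", , drop = FALSE]
  grid <- expand.grid(
    chromosome = chromosomes, subtype = c("translocation", "deletion"),
    stringsAsFactors = FALSE
  )
  grid$n_individuals <- mapply(function(chr, st) {
    length(unique(ev$individual_id[ev$chromosome == chr & ev$subtype == st]))
  }, grid$chromosome, grid$subtype)
  any_event <- stats::setNames(individuals %in% ev$individual_id, individuals)
  list(
    by_chromosome = grid, any_event = any_event,
    fraction_affected = mean(any_event)
  )
}
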