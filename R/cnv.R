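# Allele-specific copy-number stage: piecewise-constant segmentation of the
# logR signal per chromosome per individual (binary segmentation on segment
# means, BIC-style penalty) with a mirrored-BAF state per segment, and
# threshold classification into deletion / duplication / normal.
#
# This is a transparent desk-scale replacement for black-box allele-specific
# copy-number callers: those are used in this field only to produce segment
# means and copy-number cut-offs, which is exactly what this reproduces.

#' CNV thresholds
#'
#' @param logr_del segment mean logR at or below which a segment is a
#'   deletion (default -0.30, below the -0.58 expected for a one-copy loss
#'   on a two-copy baseline with allowance for shrinkage).
#' @param logr_dup segment mean logR at or above which a segment is a
#'   duplication (default +0.25; a 2->3 gain expects +0.58).
#' @param baf_third_tol tolerance around 1/3 and 2/3 for the three-copy
#'   (AAB/BBA) BAF state (default 0.08).
#' @param min_segment_markers minimum markers per segment (default 10).
#' @param whole_chrom_fraction fraction of the chromosome marker span above
#'   which an event is labelled whole-chromosome (default 0.9).
#' @return a `cnv_thresholds` list.
#' @export
cnv_thresholds <- function(logr_del = -0.30, logr_dup = 0.25,
                           baf_third_tol = 0.08, min_segment_markers = 10L,
                           whole_chrom_fraction = 0.9) {
  stopifnot(logr_del < 0, logr_dup > 0, baf_third_tol > 0,
            min_segment_markers >= 2)
  structure(
    list(
      logr_del = logr_del, logr_dup = logr_dup,
      baf_third_tol = baf_third_tol,
      min_segment_markers = as.integer(min_segment_markers),
      whole_chrom_fraction = whole_chrom_fraction
    ),
    class = "cnv_thresholds"
  )
}

# best single split of y[l..r] by residual-sum-of-squares gain, with both
# parts >= min_size; returns c(split_index, gain) or NULL
best_split <- function(cs, cs2, l, r, min_size) {
  n <- r - l + 1L
  if (n < 2L * min_size) return(NULL)
  sum_lr <- cs[r + 1L] - cs[l]
  rss_full <- (cs2[r + 1L] - cs2[l]) - sum_lr^2 / n
  s <- (l + min_size - 1L):(r - min_size)
  n_left <- s - l + 1L
  sum_left <- cs[s + 1L] - cs[l]
  rss_left <- (cs2[s + 1L] - cs2[l]) - sum_left^2 / n_left
  n_right <- r - s
  sum_right <- cs[r + 1L] - cs[s + 1L]
  rss_right <- (cs2[r + 1L] - cs2[s + 1L]) - sum_right^2 / n_right
  gain <- rss_full - (rss_left + rss_right)
  i <- which.max(gain)
  c(s[i], gain[i])
}

# mirrored-BAF state of a segment. Markers are assigned to the nearest
# cluster centre in {0, 1/3, 1/2}; a third-ratio (three-copy AAB/BBA) state
# needs a dominant 1/3 cluster, a het state needs a substantial 1/2 cluster
# (a het region genotyped on population-polymorphic markers mixes 0/0.5/1
# BAF values, so the 1/2 cluster need not be the majority).
segment_baf_state <- function(baf, tol) {
  m <- pmin(baf, 1 - baf)
  m <- m[!is.na(m)]
  if (!length(m)) return("hom")
  centres <- c(hom = 0, third_ratio = 1 / 3, het = 0.5)
  nearest <- names(centres)[apply(abs(outer(m, centres, "-")), 1L, which.min)]
  frac_third <- mean(nearest == "third_ratio" & abs(m - 1 / 3) <= tol)
  frac_het <- mean(nearest == "het")
  if (frac_third >= 0.25 && frac_third > frac_het) "third_ratio"
  else if (frac_het >= 0.15) "het"
  else "hom"
}

#' Segment one chromosome's logR/BAF signal
#'
#' Recursive binary segmentation on logR segment means. The split penalty is
#' BIC-style, `2 * sigma^2 * log(n)`, with sigma estimated robustly from
#' first differences, so a noise-free constant signal yields exactly one
#' segment. Each segment is summarised by its mean logR and a mirrored-BAF
#' (folded at 0.5) state from nearest-centre assignment to {0, 1/3, 1/2}.
#'
#' @param logr,baf numeric vectors for one individual on one chromosome.
#' @param positions_bp marker positions (sorted ascending).
#' @param th a [cnv_thresholds()].
#' @return data.frame of unclassified segments: start_bp, end_bp,
#'   start_index, end_index, n_markers, mean_logr, baf_state. Segments tile
#'   the marker span.
#' @export
segment_chromosome <- function(logr, baf, positions_bp, th = cnv_thresholds()) {
  n <- length(logr)
  stopifnot(length(baf) == n, length(positions_bp) == n)
  y <- logr
  y[!is.finite(y)] <- 0
  if (n < th$min_segment_markers) {
    warning("fewer than min_segment_markers markers; returning one segment")
    bounds <- list(c(1L, n))
  } else {
    d <- diff(y)
    sigma <- stats::mad(d) / sqrt(2)
    penalty <- max(2 * sigma^2 * log(n), 1e-12)
    cs <- c(0, cumsum(y))
    cs2 <- c(0, cumsum(y^2))
    bounds <- list()
    recurse <- function(l, r) {
      sp <- best_split(cs, cs2, l, r, th$min_segment_markers)
      if (is.null(sp) || sp[2] <= penalty) {
        bounds[[length(bounds) + 1L]] <<- c(l, r)
        return(invisible(NULL))
      }
      recurse(l, as.integer(sp[1]))
      recurse(as.integer(sp[1]) + 1L, r)
    }
    recurse(1L, n)
    bounds <- bounds[order(vapply(bounds, `[`, integer(1), 1L))]
  }
  segs <- lapply(bounds, function(b) {
    idx <- b[1]:b[2]
    data.frame(
      start_bp = positions_bp[b[1]], end_bp = positions_bp[b[2]],
      start_index = b[1], end_index = b[2], n_markers = length(idx),
      mean_logr = mean(y[idx]),
      baf_state = segment_baf_state(baf[idx], th$baf_third_tol),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, segs)
}

#' Classify segments as deletion, duplication or normal
#'
#' Monotone in mean logR: `mean_logr <= logr_del` is a deletion,
#' `mean_logr >= logr_dup` a duplication, anything between is normal.
#'
#' @param segments output of [segment_chromosome()].
#' @param th a [cnv_thresholds()].
#' @return the segments with an added `cnv_class` column.
#' @export
classify_segments <- function(segments, th = cnv_thresholds()) {
  cls <- rep("normal", nrow(segments))
  cls[segments$mean_logr <= th$logr_del] <- "deletion"
  cls[segments$mean_logr >= th$logr_dup] <- "duplication"
  segments$cnv_class <- cls
  segments
}

#' Call CNV events for one individual on one chromosome
#'
#' Runs segmentation and classification and emits non-normal segments as
#' canonical events (event_type "cnv", subtype "deletion"/"duplication",
#' with "whole_chromosome" appended when the segment covers at least
#' `whole_chrom_fraction` of the chromosome's marker span).
#'
#' @param individual_id,chromosome identifiers for the event rows.
#' @inheritParams segment_chromosome
#' @return list with `segments` (classified) and `events` (event table).
#' @export
call_cnv <- function(individual_id, chromosome, logr, baf, positions_bp,
                     th = cnv_thresholds()) {
  segs <- classify_segments(
    segment_chromosome(logr, baf, positions_bp, th), th
  )
  hits <- segs[segs$cnv_class != "normal", , drop = FALSE]
  events <- if (nrow(hits)) {
    span <- positions_bp[length(positions_bp)] - positions_bp[1]
    whole <- (hits$end_bp - hits$start_bp) >= th$whole_chrom_fraction * span
    data.frame(
      individual_id = individual_id, chromosome = chromosome,
      start_bp = hits$start_bp, end_bp = hits$end_bp,
      event_type = "cnv",
      subtype = paste0(hits$cnv_class, ifelse(whole, "_whole_chromosome", "")),
      support = hits$n_markers, stringsAsFactors = FALSE
    )
  } else {
    empty_event_table()
  }
  list(segments = segs, events = events)
}

#' Summarise CNV calls across a population
#'
#' @param events event table of CNV events for a population.
#' @param individuals all individual ids (so individuals without events are
#'   counted).
#' @param chromosomes chromosomes to tabulate.
#' @return list with `by_chromosome` (data.frame chromosome x class counts
#'   of affected individuals), `any_event` (named logical per individual)
#'   and `fraction_affected`.
#' @export
summarize_cnv <- function(events, individuals, chromosomes) {
  ev <- events[events$event_type == "cnv", , drop = FALSE]
  ev$class <- sub("_whole_chromosome$", "", ev$subtype)
  grid <- expand.grid(
    chromosome = chromosomes, class = c("deletion", "duplication"),
    stringsAsFactors = FALSE
  )
  grid$n_individuals <- mapply(function(chr, cl) {
    length(unique(ev$individual_id[ev$chromosome == chr & ev$class == cl]))
  }, grid$chromosome, grid$class)
  any_event <- stats::setNames(
    individuals %in% ev$individual_id, individuals
  )
  list(
    by_chromosome = grid, any_event = any_event,
    fraction_affected = mean(any_event)
  )
}
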