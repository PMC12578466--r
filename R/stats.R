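# Crossover landscape summaries (1 Mb windows, centromere classes, unique
# crossovers) and the population statistics: Pearson chi-square, one-way
# ANOVA with LSD pairwise comparisons, Pearson correlation.

event_midpoints <- function(events) {
  floor((events$start_bp + events$end_bp) / 2)
}

#' Bin crossover midpoints into fixed 1 Mb windows
#'
#' Windows are half-open `[start, start + 1e6)` on a grid anchored at bp 1,
#' so window k covers `[1 + k*1e6, 1 + (k+1)*1e6)`; midpoints exactly on a
#' boundary fall in the right-hand window. Raw counts, no smoothing or
#' normalisation; the last partial window is kept.
#'
#' @param events crossover event table (reduced and unreduced pooled).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window_bp window width (default 1e6).
#' @return data.frame (chromosome, window_start_bp, co_count) covering every
#'   window of every chromosome in `chrom_lengths`.
#' @export
bin_crossovers <- function(events, chrom_lengths, window_bp = 1e6) {
  out <- list()
  mids <- event_midpoints(events)
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    starts <- seq(1, len, by = window_bp)
    m <- mids[events$chromosome == chr]
    if (any(m > len)) {
      stop("crossover midpoint beyond length of chromosome ", chr)
    }
    idx <- floor((m - 1) / window_bp) + 1L
    cnt <- tabulate(idx, nbins = length(starts))
    out[[chr]] <- data.frame(
      chromosome = chr, window_start_bp = starts, co_count = cnt,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse crossovers at identical positions
#'
#' Events sharing (chromosome, start_bp, end_bp) collapse to a single
#' unique crossover; used for the distribution-shift analysis on the merged
#' reduced + unreduced dataset.
#'
#' @param events crossover event table.
#' @return the unique event set.
#' @export
dedupe_crossovers <- function(events) {
  out <- events[!duplicated(events[c("chromosome", "start_bp", "end_bp")]), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an event midpoint relative to the centromere
#'
#' Centromere containment is tested before pericentromere; everything else
#' is "arm".
#'
#' @param events crossover event table.
#' @param arch a [chromosome_architecture()].
#' @return character vector of classes aligned to `events` rows:
#'   centromeric / pericentromeric / arm.
#' @export
classify_region <- function(events, arch) {
  mids <- event_midpoints(events)
  cls <- rep("arm", nrow(events))
  for (i in seq_len(nrow(events))) {
    chr <- events$chromosome[i]
    cen <- arch_feature(arch, chr, "centromere")
    if (nrow(cen) && any(mids[i] >= cen$start_bp & mids[i] <= cen$end_bp)) {
      cls[i] <- "centromeric"
      next
    }
    per <- arch_feature(arch, chr, "pericentromere")
    if (nrow(per) && any(mids[i] >= per$start_bp & mids[i] <= per$end_bp)) {
      cls[i] <- "pericentromeric"
    }
  }
  cls
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic, `sum((O - E)^2 / E)`, with
#' `df = (r - 1)(c - 1)` and an upper-tail p value; no continuity
#' correction. Errors when any expected count is zero.
#'
#' @param table integer matrix of observed counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_event_counts <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("zero expected count in contingency table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}

# compact letter display: groups ordered by decreasing mean; each letter is
# a maximal window of consecutively ordered groups with no significant pair
cld_letters <- function(group_names, means, sig_matrix) {
  o <- order(-means)
  g <- group_names[o]
  k <- length(g)
  windows <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig_matrix[g[i:(j + 1)], g[i:(j + 1)]])) j <- j + 1L
    windows[[i]] <- i:j
  }
  # drop subset windows
  keep <- rep(TRUE, length(windows))
  for (a in seq_along(windows)) {
    for (b in seq_along(windows)) {
      if (a != b && keep[b] && all(windows[[a]] %in% windows[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  windows <- windows[keep]
  lets <- rep("", k)
  for (w in seq_along(windows)) {
    lets[windows[[w]]] <- paste0(lets[windows[[w]]], letters[w])
  }
  stats::setNames(lets, g)[group_names]
}

#' One-way ANOVA with LSD pairwise comparisons
#'
#' Fits `aov(value ~ group)`, then compares all group pairs with the least
#' significant difference test (t statistics on the pooled residual mean
#' square) and assigns a compact letter display at `alpha`: groups sharing
#' a letter are not significantly different.
#'
#' @param values numeric response (e.g. per-individual crossover totals).
#' @param groups factor/character of group labels (e.g. combinations).
#' @param alpha significance level for the letters (default 0.01).
#' @return list with `F`, `p_value`, `df`, `group_means`, `letters`,
#'   `pairwise` (data.frame of pairwise p values) and `excluded_groups`
#'   (groups with fewer than 2 observations, dropped with a warning).
#' @export
anova_lsd <- function(values, groups, alpha = 0.01) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning(
      "excluding group(s) with a single observation: ",
      paste(small, collapse = ", ")
    )
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least two groups")
  d <- data.frame(value = values, group = factor(groups))
  fit <- stats::aov(value ~ group, data = d)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  g <- levels(d$group)
  ns <- table(d$group)[g]
  ms <- tapply(d$value, d$group, mean)[g]
  pairs <- utils::combn(g, 2)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_value = NA_real_, stringsAsFactors = FALSE
  )
  sig <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tstat <- if (se == 0) 0 else abs(ms[[a]] - ms[[b]]) / se
    p <- 2 * stats::pt(tstat, df_err, lower.tail = FALSE)
    pw$p_value[i] <- p
    if (!is.na(p) && p < alpha) sig[a, b] <- sig[b, a] <- TRUE
  }
  list(
    F = an["group", "F value"], p_value = an["group", "Pr(>F)"],
    df = c(group = an["group", "Df"], residual = df_err),
    group_means = ms, letters = cld_letters(g, ms, sig), pairwise = pw,
    excluded_groups = small
  )
}

#' Correlate per-chromosome crossover totals with chromosome length
#'
#' @param co_totals named numeric vector of per-chromosome crossover counts.
#' @param lengths named numeric vector of chromosome lengths (bp), matched
#'   by name.
#' @return list with `r` (Pearson correlation) and `p_value` (two-sided).
#' @export
correlate_length_vs_co <- function(co_totals, lengths) {
  common <- intersect(names(co_totals), names(lengths))
  if (length(common) < 3) stop("need at least three chromosomes")
  x <- lengths[common]
  y <- co_totals[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in lengths or counts")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value)
}
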