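# Synthetic allopolyploid-meiosis simulator with full ground truth.
#
# An F1 hybrid carries one diploid subgenome (A in AABC, C in CCAB) that is
# heterozygous at every informative marker (homolog 1 from the B. napus
# parent, all "a"; homolog 2 from the other species parent, all "b") plus
# two haploid subgenomes. Meiosis is simulated at chromatid level per
# bivalent; gametes are sampled either reduced (one chromatid) or unreduced
# via first-division restitution (one chromatid from each homolog, so
# centromere-proximal regions stay heterozygous). Homoeologous A-C
# exchanges, whole-chromosome loss/gain, array noise and missing calls are
# layered on top, and every anomaly is recorded in a truth log.
#
# Individuals are modelled at the gamete level (microspore-derived
# material); the logR baseline is the euploid gamete complement per
# chromosome, so a one-copy loss on a two-copy baseline reads logR -1 and a
# zero-copy region reads the floor (-2) with NC genotype calls.

LOGR_FLOOR <- -2

#' Simulator configuration
#'
#' Defaults describe a desk-scale version of the study system: 10 A + 9 C
#' chromosomes, 200 evenly spaced informative markers per chromosome, two
#' crossovers per bivalent on average, and structural-event rates high
#' enough that most gametes carry at least one homoeologous exchange or
#' aneuploidy, as observed in these hybrid populations.
#'
#' @param hybrid_type "AABC" (diploid A subgenome) or "CCAB" (diploid C).
#' @param n_chrom_a,n_chrom_c chromosomes per subgenome.
#' @param chrom_lengths_bp named vector of lengths; default 24–42 Mb (A) and
#'   38–62 Mb (C).
#' @param markers_per_chromosome markers per chromosome (default 200).
#' @param centromere_fraction,pericentromere_fractions fractional intervals
#'   placing the centromere and its two flanking pericentromeric intervals.
#' @param co_rate expected crossovers per bivalent (Poisson mean, default 2).
#' @param obligate_co zero-truncate the Poisson draw (default FALSE, so
#'   `co_rate` is the exact mean).
#' @param co_position_model "uniform" or "telomere_biased".
#' @param centromere_suppression relative crossover density inside the
#'   centromere (0 = fully suppressed, default 0).
#' @param p_nonhom_exchange probability per gamete of one homoeologous A-C
#'   exchange (default 0.75).
#' @param interstitial_fraction fraction of exchanges that are interstitial
#'   rather than terminal (default 0.2).
#' @param p_whole_chrom_loss,p_whole_chrom_gain per-gamete probabilities of
#'   whole-chromosome aneuploidy (defaults 0.2 and 0.1; losses more common
#'   than gains).
#' @param gamete_class_mix fraction of unreduced gametes, used when a
#'   combination specifies `n_total` instead of explicit `n_reduced` /
#'   `n_unreduced` counts (default 0.66, the unreduced share of the study
#'   populations).
#' @param noise_sd_logr,noise_sd_baf Gaussian noise SDs (defaults 0.15,
#'   0.03).
#' @param missing_rate per-call no-call probability (default 0.05).
#' @param marker_informativeness fraction of diploid-subgenome markers at
#'   which the two parents are polymorphic (default 1).
#' @param combinations data.frame(combination, parent1_id, parent2_id,
#'   n_reduced, n_unreduced, co_rate) describing the cross-combinations to
#'   simulate; `co_rate` may be NA to use the global rate. `parent1_id` is
#'   the *B. napus* parent.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(hybrid_type = "AABC",
                       n_chrom_a = 10L, n_chrom_c = 9L,
                       chrom_lengths_bp = NULL,
                       markers_per_chromosome = 200L,
                       centromere_fraction = c(0.45, 0.52),
                       pericentromere_fractions = list(
                         c(0.35, 0.45), c(0.52, 0.62)
                       ),
                       co_rate = 2,
                       obligate_co = FALSE,
                       co_position_model = c("uniform", "telomere_biased"),
                       centromere_suppression = 0,
                       p_nonhom_exchange = 0.75,
                       interstitial_fraction = 0.2,
                       p_whole_chrom_loss = 0.2,
                       p_whole_chrom_gain = 0.1,
                       gamete_class_mix = 0.66,
                       noise_sd_logr = 0.15,
                       noise_sd_baf = 0.03,
                       missing_rate = 0.05,
                       marker_informativeness = 1,
                       combinations = NULL,
                       seed = 1L) {
  co_position_model <- match.arg(co_position_model)
  stopifnot(
    hybrid_type %in% c("AABC", "CCAB"),
    markers_per_chromosome >= 1,
    co_rate >= 0,
    centromere_suppression >= 0, centromere_suppression <= 1
  )
  for (p in c(p_nonhom_exchange, p_whole_chrom_loss, p_whole_chrom_gain,
              gamete_class_mix, missing_rate, marker_informativeness,
              interstitial_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (is.null(chrom_lengths_bp)) {
    chrom_lengths_bp <- c(
      stats::setNames(
        round(seq(24e6, 42e6, length.out = n_chrom_a)),
        paste0("A", seq_len(n_chrom_a))
      ),
      stats::setNames(
        round(seq(38e6, 62e6, length.out = n_chrom_c)),
        paste0("C", seq_len(n_chrom_c))
      )
    )
  }
  if (is.null(combinations)) {
    combinations <- data.frame(
      combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
      n_reduced = 10L, n_unreduced = 20L, co_rate = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      hybrid_type = hybrid_type, n_chrom_a = n_chrom_a, n_chrom_c = n_chrom_c,
      chrom_lengths_bp = chrom_lengths_bp,
      markers_per_chromosome = as.integer(markers_per_chromosome),
      centromere_fraction = centromere_fraction,
      pericentromere_fractions = pericentromere_fractions,
      co_rate = co_rate, obligate_co = obligate_co,
      co_position_model = co_position_model,
      centromere_suppression = centromere_suppression,
      p_nonhom_exchange = p_nonhom_exchange,
      interstitial_fraction = interstitial_fraction,
      p_whole_chrom_loss = p_whole_chrom_loss,
      p_whole_chrom_gain = p_whole_chrom_gain,
      gamete_class_mix = gamete_class_mix,
      noise_sd_logr = noise_sd_logr, noise_sd_baf = noise_sd_baf,
      missing_rate = missing_rate,
      marker_informativeness = marker_informativeness,
      combinations = combinations, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

sim_diploid_subgenome <- function(config) {
  diploid_subgenome(config$hybrid_type)
}

#' Build the simulated chromosome architecture
#' @param config a [sim_config()].
#' @return a [chromosome_architecture()] for all chromosomes.
#' @export
sim_architecture <- function(config) {
  rows <- list()
  for (chr in names(config$chrom_lengths_bp)) {
    len <- config$chrom_lengths_bp[[chr]]
    cen <- round(config$centromere_fraction * len)
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = chr, length_bp = len, feature = "centromere",
      start_bp = cen[1], end_bp = cen[2], stringsAsFactors = FALSE
    )
    for (pf in config$pericentromere_fractions) {
      per <- round(pf * len)
      # clip to abut (not overlap) the centromere
      if (per[2] >= cen[1] && per[1] < cen[1]) per[2] <- cen[1] - 1
      if (per[1] <= cen[2] && per[2] > cen[2]) per[1] <- cen[2] + 1
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chr, length_bp = len, feature = "pericentromere",
        start_bp = per[1], end_bp = per[2], stringsAsFactors = FALSE
      )
    }
  }
  chromosome_architecture(do.call(rbind, rows))
}

#' Build the simulated marker map
#' @param config a [sim_config()].
#' @return a [marker_map()] with evenly spaced markers.
#' @export
sim_marker_map <- function(config) {
  rows <- lapply(names(config$chrom_lengths_bp), function(chr) {
    len <- config$chrom_lengths_bp[[chr]]
    n <- config$markers_per_chromosome
    pos <- round(seq(len / (n + 1), len * n / (n + 1), length.out = n))
    data.frame(
      marker_id = sprintf("%s_m%04d", chr, seq_len(n)),
      chromosome = chr, position_bp = pos, stringsAsFactors = FALSE
    )
  })
  marker_map(do.call(rbind, rows))
}

draw_co_positions <- function(n_co, length_bp, centromere, model, suppression) {
  out <- numeric(0)
  while (length(out) < n_co) {
    x <- if (model == "telomere_biased") {
      length_bp * stats::rbeta(1, 0.6, 0.6)
    } else {
      stats::runif(1, 0, length_bp)
    }
    inside <- x >= centromere[1] && x <= centromere[2]
    if (!inside || stats::runif(1) < suppression) out <- c(out, x)
  }
  sort(out)
}

#' Simulate one bivalent
#'
#' Draws a Poisson crossover count (optionally zero-truncated), places each
#' crossover under the position model (density scaled by
#' `centromere_suppression` inside the centromere), assigns it to one of the
#' four two-chromatid combinations uniformly, and exchanges the chromatid
#' arm segments distal to the crossover relative to the centromere.
#'
#' @param positions_bp marker positions on the chromosome.
#' @param length_bp chromosome length.
#' @param centromere c(start, end) of the centromere.
#' @param co_rate expected crossovers.
#' @param model "uniform" or "telomere_biased".
#' @param suppression relative density inside the centromere.
#' @param obligate zero-truncate the crossover count.
#' @return list with `chromatids` (4 x n matrix over "a"/"b"; rows 1–2 from
#'   the napus homolog, 3–4 from the other) and `co` (data.frame
#'   position_bp, chromatid1, chromatid2).
#' @export
simulate_bivalent <- function(positions_bp, length_bp, centromere,
                              co_rate, model = "uniform", suppression = 0,
                              obligate = FALSE) {
  n <- length(positions_bp)
  chromatids <- rbind(
    matrix("a", 2, n), matrix("b", 2, n)
  )
  n_co <- stats::rpois(1, co_rate)
  if (obligate && co_rate > 0) {
    while (n_co == 0) n_co <- stats::rpois(1, co_rate)
  }
  if (n_co == 0) {
    return(list(chromatids = chromatids, co = data.frame(
      position_bp = numeric(0), chromatid1 = integer(0), chromatid2 = integer(0)
    )))
  }
  xs <- draw_co_positions(n_co, length_bp, centromere, model, suppression)
  cen_mid <- mean(centromere)
  co <- data.frame(
    position_bp = xs,
    chromatid1 = sample(1:2, n_co, replace = TRUE),
    chromatid2 = sample(3:4, n_co, replace = TRUE)
  )
  for (i in seq_len(n_co)) {
    x <- co$position_bp[i]
    idx <- if (x < cen_mid) which(positions_bp <= x) else
      which(positions_bp >= x)
    if (!length(idx)) next
    c1 <- co$chromatid1[i]
    c2 <- co$chromatid2[i]
    tmp <- chromatids[c1, idx]
    chromatids[c1, idx] <- chromatids[c2, idx]
    chromatids[c2, idx] <- tmp
  }
  list(chromatids = chromatids, co = co)
}

#' Sample a gamete from a bivalent
#'
#' Reduced gametes receive one chromatid sampled uniformly. Unreduced (FDR)
#' gametes receive two chromatids, one from each homolog's centromere
#' class, so centromere-proximal regions are heterozygous and
#' heterozygosity switches to homozygosity distal to crossovers.
#'
#' @param bivalent output of [simulate_bivalent()].
#' @param mechanism "reduced" or "FDR_unreduced".
#' @return character matrix (1 or 2 rows) of the gamete haplotype(s).
#' @export
sample_gamete <- function(bivalent, mechanism) {
  ch <- bivalent$chromatids
  switch(mechanism,
    reduced = ch[sample(1:4, 1), , drop = FALSE],
    FDR_unreduced = ch[c(sample(1:2, 1), sample(3:4, 1)), , drop = FALSE],
    stop("unknown gamete mechanism: ", mechanism)
  )
}

# joint state per marker ("a", "b" or "h") of a 1- or 2-row haplotype matrix
gamete_states <- function(hap) {
  if (nrow(hap) == 1L) return(hap[1, ])
  ifelse(hap[1, ] == hap[2, ], hap[1, ], "h")
}

# visible crossovers: inter-marker intervals where the joint state changes
visible_crossovers <- function(hap, positions_bp) {
  s <- gamete_states(hap)
  idx <- which(s[-1] != s[-length(s)])
  data.frame(
    start_bp = positions_bp[idx], end_bp = positions_bp[idx + 1L],
    left_state = s[idx], right_state = s[idx + 1L],
    stringsAsFactors = FALSE
  )
}

homoeologous_partner <- function(chrom, config) {
  sub <- substr(chrom, 1, 1)
  i <- as.integer(substr(chrom, 2, nchar(chrom)))
  if (sub == "A") paste0("C", min(i, config$n_chrom_c))
  else paste0("A", min(i, config$n_chrom_a))
}

draw_exchange_interval <- function(length_bp, interstitial_fraction) {
  if (stats::runif(1) < interstitial_fraction) {
    centre <- stats::runif(1, 0.3, 0.7) * length_bp
    width <- stats::runif(1, 0.08, 0.2) * length_bp
    c(max(1, centre - width / 2), min(length_bp, centre + width / 2))
  } else {
    f <- stats::runif(1, 0.06, 0.3)
    if (stats::runif(1) < 0.5) c(1, f * length_bp) else
      c((1 - f) * length_bp, length_bp)
  }
}

#' Apply structural events to a gamete
#'
#' With the configured probabilities, injects at most one event per
#' chromosome: a homoeologous exchange between a diploid-subgenome
#' chromosome and its haploid-subgenome homoeologue (a copy of the segment
#' gained on one side and lost on the other, reciprocally), a
#' whole-chromosome loss, or a whole-chromosome gain. Events act on
#' physical haplotype copies: a loss removes one copy's alleles over the
#' interval (NA marks absent sequence), a gain adds a copy. Every event is
#' returned as a truth record.
#'
#' @param haps named list per chromosome of character haplotype matrices
#'   (rows = physical copies, columns = markers, values "a"/"b"/NA).
#' @param config a [sim_config()].
#' @param map a [marker_map()].
#' @return list with `haps` (modified) and `truth` (data.frame of truth
#'   records: chromosome, event_type, start_bp, end_bp, detail).
#' @export
apply_structural_events <- function(haps, config, map) {
  truth <- list()
  touched <- character(0)
  add <- function(chrom, type, start, end, detail) {
    truth[[length(truth) + 1L]] <<- data.frame(
      chromosome = chrom, event_type = type, start_bp = start, end_bp = end,
      detail = detail, stringsAsFactors = FALSE
    )
  }
  dip <- sim_diploid_subgenome(config)
  dip_chroms <- names(config$chrom_lengths_bp)[
    startsWith(names(config$chrom_lengths_bp), dip)
  ]

  if (stats::runif(1) < config$p_nonhom_exchange) {
    chrom <- sample(dip_chroms, 1)
    partner <- homoeologous_partner(chrom, config)
    len <- config$chrom_lengths_bp[[chrom]]
    len_p <- config$chrom_lengths_bp[[partner]]
    iv <- draw_exchange_interval(len, config$interstitial_fraction)
    iv_p <- iv / len * len_p # proportional interval on the homoeologue
    pos <- map$position_bp[map$chromosome == chrom]
    pos_p <- map$position_bp[map$chromosome == partner]
    sel <- pos >= iv[1] & pos <= iv[2]
    sel_p <- pos_p >= iv_p[1] & pos_p <= iv_p[2]
    dup_on_diploid <- stats::runif(1) < 0.5
    if (dup_on_diploid) {
      # extra copy of the interval from one parental homolog; the
      # homoeologue loses one copy of its matching interval
      src <- sample(c("a", "b"), 1)
      extra <- rep(NA_character_, length(pos))
      extra[sel] <- src
      haps[[chrom]] <- rbind(haps[[chrom]], extra)
      r <- sample(nrow(haps[[partner]]), 1)
      haps[[partner]][r, sel_p] <- NA_character_
      add(chrom, "nonhom_exchange", iv[1], iv[2],
          paste0("duplication,src=", src))
      add(partner, "nonhom_exchange", iv_p[1], iv_p[2], "deletion")
    } else {
      # one physical copy of the diploid interval is replaced by
      # homoeologous material; the homoeologue gains a copy
      r <- sample(nrow(haps[[chrom]]), 1)
      haps[[chrom]][r, sel] <- NA_character_
      extra <- rep(NA_character_, length(pos_p))
      extra[sel_p] <- "a"
      haps[[partner]] <- rbind(haps[[partner]], extra)
      add(chrom, "nonhom_exchange", iv[1], iv[2], "deletion")
      add(partner, "nonhom_exchange", iv_p[1], iv_p[2], "duplication")
    }
    touched <- c(touched, chrom, partner)
  }

  all_chroms <- names(config$chrom_lengths_bp)
  if (stats::runif(1) < config$p_whole_chrom_loss) {
    cand <- setdiff(all_chroms, touched)
    if (length(cand)) {
      chrom <- sample(cand, 1)
      r <- sample(nrow(haps[[chrom]]), 1)
      haps[[chrom]] <- haps[[chrom]][-r, , drop = FALSE]
      add(chrom, "whole_loss", 1, config$chrom_lengths_bp[[chrom]],
          paste0("lost_copy=", r))
      touched <- c(touched, chrom)
    }
  }
  if (stats::runif(1) < config$p_whole_chrom_gain) {
    cand <- setdiff(all_chroms, touched)
    if (length(cand)) {
      chrom <- sample(cand, 1)
      if (nrow(haps[[chrom]]) > 0L) {
        r <- sample(nrow(haps[[chrom]]), 1)
        haps[[chrom]] <- rbind(haps[[chrom]], haps[[chrom]][r, ])
        add(chrom, "whole_gain", 1, config$chrom_lengths_bp[[chrom]],
            paste0("gained_copy=", r))
      }
    }
  }
  list(
    haps = haps,
    truth = if (length(truth)) do.call(rbind, truth) else data.frame(
      chromosome = character(0), event_type = character(0),
      start_bp = double(0), end_bp = double(0), detail = character(0),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate a population and emit array signals
#'
#' Runs the full generative loop — bivalent meiosis, gamete sampling,
#' structural events, signal emission with noise and missing calls — for
#' every combination in the configuration, and returns the exact containers
#' the analysis pipeline consumes plus the ground-truth log. Deterministic
#' under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `calls` ([call_matrices()]), `map`, `meta`, `arch`,
#'   `truth` (data.frame: individual_id, chromosome, event_type, start_bp,
#'   end_bp, detail).
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  map <- sim_marker_map(config)
  arch <- sim_architecture(config)
  dip <- sim_diploid_subgenome(config)
  chroms <- names(config$chrom_lengths_bp)
  dip_chroms <- chroms[startsWith(chroms, dip)]
  n_mark <- nrow(map)
  informative <- stats::setNames(
    map$subgenome == dip &
      stats::runif(n_mark) < config$marker_informativeness,
    map$marker_id
  )

  meta_rows <- list()
  truth_rows <- list()
  individuals <- character(0)
  geno <- list()
  logr <- list()
  baf <- list()

  pos_by_chrom <- split(map$position_bp, map$chromosome)[chroms]
  idx_by_chrom <- split(seq_len(n_mark), map$chromosome)[chroms]

  emit_individual <- function(doses, expected) {
    g <- character(n_mark)
    r <- numeric(n_mark)
    b <- numeric(n_mark)
    for (chr in chroms) {
      idx <- idx_by_chrom[[chr]]
      d <- doses[[chr]]
      inf <- informative[idx]
      eff_b <- ifelse(inf, d$b, 0L)
      eff_a <- d$a + ifelse(inf, 0L, d$b)
      total <- eff_a + eff_b
      frac <- ifelse(total > 0, eff_b / total, 0.5)
      g_chr <- ifelse(
        total == 0L, "NC",
        ifelse(frac == 0, "AA", ifelse(frac == 1, "BB", "AB"))
      )
      r_chr <- ifelse(total > 0, log2(total / expected[[chr]]), LOGR_FLOOR)
      g[idx] <- g_chr
      r[idx] <- r_chr
      b[idx] <- frac
    }
    if (config$noise_sd_logr > 0) {
      r <- r + stats::rnorm(n_mark, 0, config$noise_sd_logr)
    }
    if (config$noise_sd_baf > 0) {
      b <- pmin(pmax(b + stats::rnorm(n_mark, 0, config$noise_sd_baf), 0), 1)
    }
    if (config$missing_rate > 0) {
      g[stats::runif(n_mark) < config$missing_rate] <- "NC"
    }
    list(g = g, r = r, b = b)
  }

  parent_profile <- function(kind) {
    # kind: "napus" (all-a), "other" (b where informative), "f1" (het)
    g <- character(n_mark)
    b <- numeric(n_mark)
    for (i in seq_len(n_mark)) {
      if (informative[i] && kind == "other") {
        g[i] <- "BB"; b[i] <- 1
      } else if (informative[i] && kind == "f1") {
        g[i] <- "AB"; b[i] <- 0.5
      } else {
        g[i] <- "AA"; b[i] <- 0
      }
    }
    r <- numeric(n_mark)
    if (config$noise_sd_logr > 0) {
      r <- r + stats::rnorm(n_mark, 0, config$noise_sd_logr)
    }
    if (config$noise_sd_baf > 0) {
      b <- pmin(pmax(b + stats::rnorm(n_mark, 0, config$noise_sd_baf), 0), 1)
    }
    list(g = g, r = r, b = b)
  }

  for (ci in seq_len(nrow(config$combinations))) {
    cmb <- config$combinations[ci, ]
    rate <- if (is.na(cmb$co_rate)) config$co_rate else cmb$co_rate
    f1_id <- paste0("F1_", cmb$combination)
    for (col_id in c(cmb$parent1_id, cmb$parent2_id, f1_id)) {
      if (!col_id %in% individuals) {
        kind <- if (col_id == cmb$parent1_id) "napus" else
          if (col_id == cmb$parent2_id) "other" else "f1"
        prof <- parent_profile(kind)
        individuals <- c(individuals, col_id)
        geno[[col_id]] <- prof$g
        logr[[col_id]] <- prof$r
        baf[[col_id]] <- prof$b
      }
    }
    classes <- if (!is.null(cmb$n_total) && !is.na(cmb$n_total)) {
      # class drawn per gamete from the configured unreduced fraction
      ifelse(
        stats::runif(cmb$n_total) < config$gamete_class_mix,
        "unreduced", "reduced"
      )
    } else {
      c(rep("reduced", cmb$n_reduced), rep("unreduced", cmb$n_unreduced))
    }
    for (gi in seq_along(classes)) {
      cls <- classes[gi]
      ind <- sprintf("%s_%s_%02d", cmb$combination,
                     if (cls == "reduced") "n" else "2n", gi)
      mechanism <- if (cls == "reduced") "reduced" else "FDR_unreduced"
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        individual_id = ind, chromosome = NA_character_,
        event_type = "mechanism", start_bp = NA_real_, end_bp = NA_real_,
        detail = mechanism, stringsAsFactors = FALSE
      )
      haps <- list()
      expected <- list()
      for (chr in chroms) {
        pos <- pos_by_chrom[[chr]]
        if (chr %in% dip_chroms) {
          cen <- arch_feature(arch, chr, "centromere")
          biv <- simulate_bivalent(
            pos, config$chrom_lengths_bp[[chr]],
            c(cen$start_bp, cen$end_bp), rate,
            config$co_position_model, config$centromere_suppression,
            config$obligate_co
          )
          hap <- sample_gamete(biv, mechanism)
          vis <- visible_crossovers(hap, pos)
          if (nrow(vis)) {
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
              individual_id = ind, chromosome = chr,
              event_type = "crossover", start_bp = vis$start_bp,
              end_bp = vis$end_bp,
              detail = paste0(vis$left_state, ">", vis$right_state),
              stringsAsFactors = FALSE
            )
          }
          haps[[chr]] <- hap
          expected[[chr]] <- nrow(hap)
        } else {
          # haploid subgenomes: one napus-derived copy
          haps[[chr]] <- matrix("a", 1L, length(pos))
          expected[[chr]] <- 1
        }
      }
      se <- apply_structural_events(haps, config, map)
      doses <- lapply(se$haps, function(h) list(
        a = colSums(h == "a", na.rm = TRUE),
        b = colSums(h == "b", na.rm = TRUE)
      ))
      if (nrow(se$truth)) {
        se$truth$individual_id <- ind
        truth_rows[[length(truth_rows) + 1L]] <-
          se$truth[c("individual_id", "chromosome", "event_type",
                     "start_bp", "end_bp", "detail")]
      }
      sig <- emit_individual(doses, expected)
      individuals <- c(individuals, ind)
      geno[[ind]] <- sig$g
      logr[[ind]] <- sig$r
      baf[[ind]] <- sig$b
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        individual_id = ind, combination = cmb$combination,
        hybrid_type = config$hybrid_type, gamete_class = cls,
        derivation = "microspore", parent1_id = cmb$parent1_id,
        parent2_id = cmb$parent2_id, f1_id = f1_id, stringsAsFactors = FALSE
      )
    }
  }

  g <- do.call(cbind, geno)
  r <- do.call(cbind, logr)
  b <- do.call(cbind, baf)
  rownames(g) <- rownames(r) <- rownames(b) <- map$marker_id
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(
    calls = call_matrices(g, r, b), map = map,
    meta = population_metadata(do.call(rbind, meta_rows)),
    arch = arch, truth = truth
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the exact file formats the readers consume: genotype/logR/BAF TSV
#' matrices, marker map TSV, metadata TSV, BED architecture, truth log TSV.
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotype = file.path(dir, "genotype.tsv"),
    logr = file.path(dir, "logr.tsv"),
    baf = file.path(dir, "baf.tsv"),
    map = file.path(dir, "marker_map.tsv"),
    meta = file.path(dir, "metadata.tsv"),
    arch = file.path(dir, "architecture.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  write_matrix_tsv(sim$calls$genotype, paths[["genotype"]])
  write_matrix_tsv(sim$calls$logr, paths[["logr"]])
  write_matrix_tsv(sim$calls$baf, paths[["baf"]])
  utils::write.table(
    as.data.frame(sim$map)[c("marker_id", "chromosome", "position_bp")],
    paths[["map"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    as.data.frame(sim$meta), paths[["meta"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  arch <- sim$arch
  lens <- chromosome_lengths(arch)
  bed <- rbind(
    data.frame(
      chromosome = names(lens), start = 0, end = as.double(lens),
      feature = "chromosome", stringsAsFactors = FALSE
    ),
    data.frame(
      chromosome = arch$chromosome, start = arch$start_bp - 1,
      end = arch$end_bp, feature = arch$feature, stringsAsFactors = FALSE
    )
  )
  utils::write.table(
    bed, paths[["arch"]],
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    sim$truth, paths[["truth"]],
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(paths)
}

#' Score crossover recovery against simulator truth
#'
#' A true crossover is recovered when a called homologous crossover on the
#' same individual and chromosome overlaps its inter-marker interval
#' expanded by `slack_bp`; called events matching no true crossover are
#' false positives. Eligibility restricts truth events to those at least
#' `min_sep_bp` from the nearest other visible crossover and at least
#' `edge_markers` markers from the chromosome ends.
#'
#' @param events called crossover event table (subtype "homologous").
#' @param truth simulator truth log.
#' @param map a [marker_map()].
#' @param min_sep_bp eligibility separation (default 2 Mb).
#' @param edge_markers eligibility distance from chromosome ends in markers
#'   (default 5).
#' @param slack_bp matching slack (default 1 Mb).
#' @return list with `recovery` (recovered / eligible), `fp_rate` (false
#'   positives / called), and the underlying counts.
#' @export
score_crossover_recovery <- function(events, truth, map,
                                     min_sep_bp = 2e6, edge_markers = 5L,
                                     slack_bp = 1e6) {
  tr <- truth[truth$event_type == "crossover", , drop = FALSE]
  ev <- events[
    events$event_type == "crossover" & events$subtype == "homologous", ,
    drop = FALSE
  ]
  pos_by_chrom <- split(map$position_bp, map$chromosome)
  eligible <- logical(nrow(tr))
  recovered <- logical(nrow(tr))
  matched_any <- rep(FALSE, nrow(ev))
  for (key in unique(paste(tr$individual_id, tr$chromosome))) {
    sel <- paste(tr$individual_id, tr$chromosome) == key
    t_sub <- tr[sel, , drop = FALSE]
    chr <- t_sub$chromosome[1]
    pos <- pos_by_chrom[[chr]]
    mids <- (t_sub$start_bp + t_sub$end_bp) / 2
    sep_ok <- if (length(mids) == 1L) rep(TRUE, 1L) else {
      d <- diff(sort(mids))
      ord <- order(mids)
      ok <- rep(TRUE, length(mids))
      gap_prev <- c(Inf, d)
      gap_next <- c(d, Inf)
      ok[ord] <- gap_prev >= min_sep_bp & gap_next >= min_sep_bp
      ok
    }
    edge_ok <- t_sub$start_bp >= pos[edge_markers] &
      t_sub$end_bp <= pos[length(pos) - edge_markers + 1L]
    eligible[sel] <- sep_ok & edge_ok
    e_sel <- ev$individual_id == t_sub$individual_id[1] &
      ev$chromosome == chr
    e_sub <- ev[e_sel, , drop = FALSE]
    if (nrow(e_sub)) {
      hit <- outer(
        seq_len(nrow(t_sub)), seq_len(nrow(e_sub)),
        Vectorize(function(i, j) {
          t_sub$start_bp[i] - slack_bp <= e_sub$end_bp[j] &&
            t_sub$end_bp[i] + slack_bp >= e_sub$start_bp[j]
        })
      )
      recovered[sel] <- apply(hit, 1, any)
      matched_any[e_sel] <- apply(hit, 2, any)
    }
  }
  n_eligible <- sum(eligible)
  n_recovered <- sum(recovered & eligible)
  n_called <- nrow(ev)
  n_fp <- sum(!matched_any)
  list(
    recovery = if (n_eligible) n_recovered / n_eligible else NA_real_,
    fp_rate = if (n_called) n_fp / n_called else 0,
    n_eligible = n_eligible, n_recovered = n_recovered,
    n_called = n_called, n_false_positive = n_fp
  )
}
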