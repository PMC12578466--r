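# End-to-end orchestration: filter -> recode -> cnv -> crossover ->
# non-homologous exclusion -> distributions -> statistics, with a run
# manifest (config hash, chosen per-chromosome min_run, QC flags) and
# reproducible outputs.

#' Build a run configuration
#'
#' @param genotype_path,logr_path,baf_path,map_path,arch_path,meta_path
#'   input file paths.
#' @param outdir output directory.
#' @param filter a [filter_thresholds()].
#' @param cnv a [cnv_thresholds()].
#' @param smoothing a [smoothing_params()]; its `min_run` is a fallback —
#'   the pipeline selects per-chromosome values via [select_min_run()]
#'   unless `select_min_run = FALSE`.
#' @param margin_bp non-homologous exclusion margin (default 500 kb).
#' @param select_min_run choose min_run per chromosome (default TRUE).
#' @param seed integer seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(genotype_path, logr_path, baf_path, map_path,
                       arch_path, meta_path, outdir,
                       filter = filter_thresholds(),
                       cnv = cnv_thresholds(),
                       smoothing = smoothing_params(),
                       margin_bp = 5e5,
                       select_min_run = TRUE,
                       seed = 1L) {
  paths <- c(
    genotype = genotype_path, logr = logr_path, baf = baf_path,
    map = map_path, arch = arch_path, meta = meta_path
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(
      "input path(s) do not exist: ",
      paste(names(missing), "=", missing, collapse = "; ")
    )
  }
  structure(
    list(
      paths = as.list(paths), outdir = outdir, filter = filter, cnv = cnv,
      smoothing = smoothing, margin_bp = margin_bp,
      select_min_run = select_min_run, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]: `paths` (genotype, logr,
#' baf, map, arch, meta), `outdir`, `filter`, `cnv`, `smoothing`,
#' `margin_bp`, `select_min_run`, `seed`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    genotype_path = y$paths$genotype, logr_path = y$paths$logr,
    baf_path = y$paths$baf, map_path = y$paths$map,
    arch_path = y$paths$arch, meta_path = y$paths$meta,
    outdir = y$outdir,
    filter = do.call(filter_thresholds, as.list(y$filter)),
    cnv = do.call(cnv_thresholds, as.list(y$cnv)),
    smoothing = do.call(smoothing_params, as.list(y$smoothing)),
    margin_bp = if (is.null(y$margin_bp)) 5e5 else y$margin_bp,
    select_min_run = !isFALSE(y$select_min_run),
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  flat <- config
  flat$outdir <- NULL # the hash identifies inputs + parameters
  yaml::write_yaml(lapply(flat, unclass), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read and validate inputs; per-combination marker
#' filtering and parental-origin recoding; CNV segmentation and
#' classification for every individual and chromosome; per-chromosome
#' min-run selection and crossover calling on the diploid subgenome;
#' non-homologous event detection and breakpoint exclusion; 1 Mb window
#' binning, deduplication, region classification; chi-square / ANOVA-LSD /
#' correlation statistics. Writes event tables, summary TSVs, a statistics
#' JSON and a run manifest into `config$outdir`, and returns all results.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with elements `crossovers`, `cnv_events`,
#'   `nonhom_events`, `counts`, `windows`, `unique_crossovers`,
#'   `region_classes`, `stats`, `min_run_by_chrom`, `qc_flags`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  say("reading inputs")
  calls <- read_call_matrices(
    config$paths$genotype, config$paths$logr, config$paths$baf
  )
  map <- read_marker_map(config$paths$map)
  arch <- read_architecture(config$paths$arch)
  meta <- read_population_metadata(config$paths$meta)
  absent <- setdiff(meta$individual_id, calls$individual_ids)
  if (length(absent)) {
    stop("metadata individuals missing from matrices: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  res <- run_pipeline_stages(
    calls, map, arch, meta, config$filter, config$cnv, config$smoothing,
    config$margin_bp, config$select_min_run, quiet = quiet
  )

  say("writing outputs")
  out <- function(f) file.path(config$outdir, f)
  write_event_table(res$crossovers, out("crossovers.tsv"), hash)
  write_event_table(res$cnv_events[names(empty_event_table())],
                    out("cnv_events.tsv"), hash)
  write_event_table(res$nonhom_events[names(empty_event_table())],
                    out("nonhom_events.tsv"), hash)
  count_df <- data.frame(
    individual_id = rownames(res$counts$counts), res$counts$counts,
    check.names = FALSE
  )
  utils::write.table(count_df, out("breakpoint_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$windows, out("window_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$region_classes, out("region_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    res$stats, out("statistics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  manifest <- c(
    list(
      manifest_hash = hash, seed = config$seed,
      tool = paste0(
        "meioscan ", as.character(utils::packageVersion("meioscan"))
      ),
      qc_flags = res$qc_flags
    ),
    list(min_run_by_chrom = as.list(res$min_run_by_chrom))
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}

# pipeline core on in-memory objects (shared by run_pipeline and tests)
#' Run the analysis stages on in-memory containers
#'
#' The computational core of [run_pipeline()], usable directly on a
#' [simulate_population()] result without touching disk.
#'
#' @param calls a [call_matrices()].
#' @param map a [marker_map()].
#' @param arch a [chromosome_architecture()].
#' @param meta a [population_metadata()].
#' @param filter,cnv,smoothing parameter objects.
#' @param margin_bp exclusion margin.
#' @param select per-chromosome min-run selection (logical).
#' @param quiet suppress messages.
#' @return see [run_pipeline()].
#' @export
run_pipeline_stages <- function(calls, map, arch, meta,
                                filter = filter_thresholds(),
                                cnv = cnv_thresholds(),
                                smoothing = smoothing_params(),
                                margin_bp = 5e5, select = TRUE,
                                quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)

  say("filtering markers per combination")
  filt <- filter_markers(calls, map, meta, filter)

  say("recoding progeny")
  vecs <- list() # individual -> chromosome -> recoded_vector
  for (cmb in names(filt)) {
    rv <- recode_progeny(calls, map, meta, filt[[cmb]]$kept, cmb)
    vecs[names(rv)] <- rv
  }
  gclass <- stats::setNames(meta$gamete_class, meta$individual_id)

  say("calling copy-number variants")
  chroms <- unique(map$chromosome)
  pos_by_chrom <- split(map$position_bp, map$chromosome)[chroms]
  idx_by_chrom <- split(seq_len(nrow(map)), map$chromosome)[chroms]
  cnv_rows <- list()
  segments <- list() # individual -> chromosome -> classified segments
  for (ind in meta$individual_id) {
    segments[[ind]] <- list()
    for (chr in chroms) {
      idx <- idx_by_chrom[[chr]]
      cc <- call_cnv(
        ind, chr, calls$logr[idx, ind], calls$baf[idx, ind],
        pos_by_chrom[[chr]], cnv
      )
      segments[[ind]][[chr]] <- cc$segments
      if (nrow(cc$events)) cnv_rows[[length(cnv_rows) + 1L]] <- cc$events
    }
  }
  cnv_events <- bind_events(cnv_rows)

  say("selecting min_run and calling crossovers")
  dip_chroms_all <- unique(unlist(lapply(names(filt), function(cmb) {
    sub <- diploid_subgenome(combination_info(meta, cmb)$hybrid_type)
    chroms[startsWith(chroms, sub)]
  })))
  min_run_by_chrom <- integer(0)
  qc_flags <- character(0)
  co_rows <- list()
  for (chr in dip_chroms_all) {
    chr_vecs <- list()
    chr_cls <- character(0)
    for (ind in names(vecs)) {
      v <- vecs[[ind]][[chr]]
      if (!is.null(v)) {
        chr_vecs[[length(chr_vecs) + 1L]] <- v
        chr_cls <- c(chr_cls, gclass[[ind]])
      }
    }
    if (!length(chr_vecs)) next
    if (select) {
      sel <- select_min_run(chr_vecs, chr_cls, smoothing)
      mr <- sel$chosen
      if (sel$qc_flag) {
        qc_flags <- c(qc_flags, paste0(
          chr, ": no admissible min_run, using ", mr
        ))
      }
    } else {
      mr <- smoothing$min_run
    }
    min_run_by_chrom[chr] <- mr
    p <- smoothing
    p$min_run <- mr
    p$na_deletion_min_run <- mr
    for (vi in seq_along(chr_vecs)) {
      cc <- call_crossovers(chr_vecs[[vi]], p, chr_cls[vi])
      if (nrow(cc$events)) co_rows[[length(co_rows) + 1L]] <- cc$events
    }
  }
  crossovers <- bind_events(co_rows)

  say("detecting non-homologous events")
  nh_rows <- list()
  for (ind in names(vecs)) {
    for (chr in names(vecs[[ind]])) {
      v <- vecs[[ind]][[chr]]
      segs <- segments[[ind]][[chr]]
      p <- smoothing
      mr <- min_run_by_chrom[chr]
      if (!is.na(mr)) {
        p$min_run <- mr
        p$na_deletion_min_run <- mr
      }
      nh <- if (gclass[[ind]] == "reduced") {
        detect_nonhom_reduced(v, segs, p)
      } else {
        idx <- idx_by_chrom[[chr]]
        detect_nonhom_unreduced(
          ind, chr, segs, calls$genotype[idx, ind], pos_by_chrom[[chr]]
        )
      }
      if (nrow(nh)) nh_rows[[length(nh_rows) + 1L]] <- nh
    }
  }
  nonhom_events <- bind_events(nh_rows)
  if (!nrow(nonhom_events)) {
    nonhom_events$evidence <- character(0)
    nonhom_events$location_class <- character(0)
  }

  say("excluding non-homologous breakpoints")
  crossovers <- exclude_nonhom_breakpoints(
    crossovers, nonhom_events, margin_bp
  )

  say("summarising distributions and statistics")
  counts <- count_breakpoints(
    crossovers, meta$individual_id, dip_chroms_all
  )
  homologous <- crossovers[crossovers$subtype == "homologous", , drop = FALSE]
  lens <- chromosome_lengths(arch)
  windows <- bin_crossovers(homologous, lens[dip_chroms_all])
  uniq <- dedupe_crossovers(homologous)
  region_raw <- classify_region(homologous, arch)
  region_classes <- data.frame(
    dataset = rep(c("raw", "unique"), c(nrow(homologous), nrow(uniq))),
    rbind(homologous, uniq),
    region = c(region_raw, classify_region(uniq, arch)),
    stringsAsFactors = FALSE
  )

  stats_out <- list()
  totals <- counts$genome_total
  combo <- stats::setNames(meta$combination, meta$individual_id)
  grp <- combo[names(totals)]
  if (length(unique(grp[table(grp)[grp] >= 2])) >= 2) {
    al <- withCallingHandlers(
      anova_lsd(as.numeric(totals), grp),
      warning = function(w) invokeRestart("muffleWarning")
    )
    stats_out$anova <- list(
      test = "one-way ANOVA + LSD", F = al$F, p_value = al$p_value,
      letters = as.list(al$letters)
    )
  }
  per_chrom_totals <- colSums(counts$counts)
  if (length(per_chrom_totals) >= 3 && stats::sd(per_chrom_totals) > 0) {
    ct <- correlate_length_vs_co(per_chrom_totals, lens)
    stats_out$length_correlation <- list(
      test = "Pearson correlation", r = ct$r, p_value = ct$p_value
    )
  }
  nh_sum <- summarize_nonhom(
    nonhom_events, meta$individual_id, dip_chroms_all
  )
  # translocation vs deletion frequency across chromosomes
  nh_tab <- stats::xtabs(
    n_individuals ~ chromosome + subtype, data = nh_sum$by_chromosome
  )
  cs <- tryCatch(chisq_event_counts(nh_tab), error = function(e) NULL)
  if (!is.null(cs)) {
    stats_out$nonhom_by_chromosome <- list(
      test = "Pearson chi-square", statistic = cs$statistic, df = cs$df,
      p_value = cs$p_value
    )
  }

  list(
    crossovers = crossovers, cnv_events = cnv_events,
    nonhom_events = nonhom_events, counts = counts, windows = windows,
    unique_crossovers = uniq, region_classes = region_classes,
    stats = stats_out, min_run_by_chrom = min_run_by_chrom,
    qc_flags = qc_flags, segments = segments,
    cnv_summary = summarize_cnv(cnv_events, meta$individual_id, chroms),
    nonhom_summary = nh_sum
  )
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper: builds a [sim_config()], runs
#' [simulate_population()], writes files via [write_simulated_dataset()].
#'
#' @param dir output directory.
#' @param ... passed to [sim_config()].
#' @return (invisibly) the simulation result.
#' @export
simulate_dataset <- function(dir, ...) {
  config <- sim_config(...)
  sim <- simulate_population(config)
  write_simulated_dataset(sim, dir)
  invisible(sim)
}
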