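# Per-combination SNP filtering and parental-origin recoding.
#
# Four rules, evaluated independently on the raw matrix and intersected:
#   1. fraction of AB calls across all parent columns (union over every
#      combination in the run) must not exceed max_parent_het_fraction;
#   2. fraction of NC across all columns must not exceed max_missing_fraction;
#   3. the combination's two parents are homozygous and carry different
#      homozygous calls ("homozygous in and polymorphic between");
#   4. the combination's F1 hybrid parent is AB.
# Rules 1 and 2 use strict "over" comparisons: a marker is dropped only when
# the fraction exceeds the threshold.

#' Filtering thresholds
#'
#' @param max_parent_het_fraction drop markers whose AB fraction across all
#'   parent genotypes exceeds this (default 0.70).
#' @param max_missing_fraction drop markers whose NC fraction across all
#'   lines exceeds this (default 0.90).
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_parent_het_fraction = 0.70,
                              max_missing_fraction = 0.90) {
  stopifnot(
    max_parent_het_fraction >= 0, max_parent_het_fraction <= 1,
    max_missing_fraction >= 0, max_missing_fraction <= 1
  )
  structure(
    list(
      max_parent_het_fraction = max_parent_het_fraction,
      max_missing_fraction = max_missing_fraction
    ),
    class = "filter_thresholds"
  )
}

diploid_subgenome <- function(hybrid_type) {
  c(AABC = "A", CCAB = "C")[[hybrid_type]]
}

combination_info <- function(meta, combination) {
  rows <- meta[meta$combination == combination, , drop = FALSE]
  if (!nrow(rows)) stop("unknown combination: ", combination)
  list(
    combination = combination,
    hybrid_type = rows$hybrid_type[1],
    parent1 = rows$parent1_id[1],
    parent2 = rows$parent2_id[1],
    f1 = rows$f1_id[1],
    individuals = rows$individual_id
  )
}

#' Filter markers per cross-combination
#'
#' Applies the four filtering rules and returns, per combination, the kept
#' marker-id set on the diploid-subgenome chromosomes (A for AABC, C for
#' CCAB), plus a per-marker rule report.
#'
#' @param calls a [call_matrices()] object containing progeny, parent and F1
#'   columns.
#' @param map a [marker_map()].
#' @param meta a [population_metadata()].
#' @param th a [filter_thresholds()].
#' @return list with one element per combination, each a list of `kept`
#'   (character marker ids, in map order) and `report` (data.frame with
#'   per-rule pass flags).
#' @export
filter_markers <- function(calls, map, meta, th = filter_thresholds()) {
  g <- calls$genotype
  combos <- unique(meta$combination)
  parent_cols <- unique(c(meta$parent1_id, meta$parent2_id))
  absent <- setdiff(
    c(parent_cols, unique(meta$f1_id)), colnames(g)
  )
  if (length(absent)) {
    stop(
      "parent/F1 column(s) missing from genotype matrix: ",
      paste(absent, collapse = ", ")
    )
  }
  gp <- g[, parent_cols, drop = FALSE]
  frac_ab_parents <- rowMeans(gp == "AB")
  frac_nc_all <- rowMeans(g == "NC")
  pass1 <- frac_ab_parents <= th$max_parent_het_fraction
  pass2 <- frac_nc_all <= th$max_missing_fraction

  out <- list()
  for (cmb in combos) {
    info <- combination_info(meta, cmb)
    sub <- diploid_subgenome(info$hybrid_type)
    on_diploid <- map$marker_id[map$subgenome == sub]
    p1 <- g[, info$parent1]
    p2 <- g[, info$parent2]
    f1 <- g[, info$f1]
    pass3 <- p1 %in% c("AA", "BB") & p2 %in% c("AA", "BB") & p1 != p2
    pass4 <- f1 == "AB"
    report <- data.frame(
      marker_id = rownames(g),
      rule1_parent_het = pass1,
      rule2_missingness = pass2,
      rule3_hom_polymorphic = pass3,
      rule4_f1_het = pass4,
      stringsAsFactors = FALSE
    )
    report$kept <- with(
      report,
      rule1_parent_het & rule2_missingness & rule3_hom_polymorphic &
        rule4_f1_het & marker_id %in% on_diploid
    )
    kept <- intersect(on_diploid, report$marker_id[report$kept])
    out[[cmb]] <- list(kept = kept, report = report)
  }
  out
}

#' Write a per-marker filter report
#' @param filter_result one element of the [filter_markers()] result.
#' @param path destination TSV path.
#' @export
write_filter_report <- function(filter_result, path) {
  utils::write.table(
    filter_result$report, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}

recode_cell <- function(call, p1_call, p2_call) {
  if (call == "NC") return("missing")
  if (call == "AB") return("h")
  if (call == p1_call) return("a")
  if (call == p2_call) return("b")
  # homozygous call matching neither parent: treat as missing signal
  "missing"
}

#' Recode progeny genotypes to parental-origin symbols
#'
#' For each progeny of a combination and each kept marker, the call equal to
#' the *B. napus* parent homozygote becomes "a", the other parent's
#' homozygote "b", AB becomes "h" and NC stays missing. Returns one
#' `recoded_vector` per individual per diploid-subgenome chromosome.
#'
#' @param calls a [call_matrices()].
#' @param map a [marker_map()].
#' @param meta a [population_metadata()].
#' @param kept kept marker ids for one combination (from [filter_markers()]).
#' @param combination the combination to recode.
#' @return named list (individual id) of named lists (chromosome) of
#'   `recoded_vector` objects: lists with `individual_id`, `chromosome`,
#'   `symbols` (character over a/b/h/missing), `positions_bp`, `marker_ids`.
#' @export
recode_progeny <- function(calls, map, meta, kept, combination) {
  info <- combination_info(meta, combination)
  g <- calls$genotype
  kept <- intersect(map$marker_id, kept) # map order
  km <- map[match(kept, map$marker_id), , drop = FALSE]
  p1 <- g[kept, info$parent1]
  p2 <- g[kept, info$parent2]
  out <- list()
  for (ind in info$individuals) {
    calls_ind <- g[kept, ind]
    bad <- setdiff(unique(calls_ind), GENOTYPE_TOKENS)
    if (length(bad)) stop("invalid progeny call(s): ", paste(bad, collapse = ", "))
    sym <- character(length(kept))
    for (i in seq_along(kept)) sym[i] <- recode_cell(calls_ind[i], p1[i], p2[i])
    per_chrom <- list()
    for (chr in unique(km$chromosome)) {
      sel <- km$chromosome == chr
      per_chrom[[chr]] <- structure(
        list(
          individual_id = ind, chromosome = chr,
          symbols = sym[sel], positions_bp = km$position_bp[sel],
          marker_ids = kept[sel]
        ),
        class = "recoded_vector"
      )
    }
    out[[ind]] <- per_chrom
  }
  out
}
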