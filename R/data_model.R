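#' meioscan: crossover and copy-number detection in allopolyploid hybrid
#' gamete populations
#'
#' Shared data model used throughout the package. All downstream stages
#' consume only these validated containers; no stage re-parses files.
#'
#' @section Coordinate convention:
#' Internally every interval is 1-based and closed on marker positions.
#' BED-style architecture files (0-based, half-open) are converted on read.
#'
#' @name meioscan-package
#' @keywords internal
"_PACKAGE"

GENOTYPE_TOKENS <- c("AA", "AB", "BB", "NC")
CHROMOSOMES_A <- paste0("A", 1:10)
CHROMOSOMES_C <- paste0("C", 1:9)
ALL_CHROMOSOMES <- c(CHROMOSOMES_A, CHROMOSOMES_C)

#' Construct and validate a marker map
#'
#' The marker map is the genomic coordinate system for every call: ordered
#' SNP markers with a chromosome (A1–A10, C1–C9) and a 1-based bp position.
#' Rows are sorted by (chromosome, position); the subgenome (A or C) is
#' derived from the chromosome prefix.
#'
#' @param df data.frame with columns `marker_id`, `chromosome`, `position_bp`.
#' @return A `marker_map`: the sorted data.frame with an added `subgenome`
#'   column.
#' @export
marker_map <- function(df) {
  req <- c("marker_id", "chromosome", "position_bp")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("marker map is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[req]
  df$marker_id <- as.character(df$marker_id)
  df$chromosome <- as.character(df$chromosome)
  df$position_bp <- as.integer(df$position_bp)
  bad <- setdiff(unique(df$chromosome), ALL_CHROMOSOMES)
  if (length(bad)) {
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  }
  dup <- unique(df$marker_id[duplicated(df$marker_id)])
  if (length(dup)) {
    stop("duplicate marker_id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(df$position_bp < 1L)) stop("marker positions must be >= 1")
  df$chromosome <- factor(df$chromosome, levels = ALL_CHROMOSOMES)
  df <- df[order(df$chromosome, df$position_bp), , drop = FALSE]
  df$chromosome <- as.character(df$chromosome)
  pos_dup <- vapply(
    split(df$position_bp, df$chromosome),
    function(p) anyDuplicated(p) > 0L, logical(1)
  )
  if (any(pos_dup)) {
    stop(
      "duplicated positions within chromosome(s): ",
      paste(names(pos_dup)[pos_dup], collapse = ", ")
    )
  }
  df$subgenome <- substr(df$chromosome, 1, 1)
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Construct aligned genotype / logR / BAF call matrices
#'
#' The three grids share identical marker (row) and individual (column)
#' index sets. Genotype tokens are restricted to AA, AB, BB, NC; missing
#' genotype cells are mapped to NC, missing numeric cells to NA. NC is
#' allowed to co-occur with finite logR/BAF (a no-call still has intensity).
#'
#' @param genotype character matrix (markers x individuals) over
#'   {AA, AB, BB, NC}.
#' @param logr,baf numeric matrices aligned to `genotype`; `baf` in `[0, 1]`.
#' @return A `call_matrices` list with elements `genotype`, `logr`, `baf`,
#'   `marker_ids`, `individual_ids`.
#' @export
call_matrices <- function(genotype, logr, baf) {
  genotype <- as.matrix(genotype)
  logr <- as.matrix(logr)
  baf <- as.matrix(baf)
  if (is.null(rownames(genotype)) || is.null(colnames(genotype))) {
    stop("genotype matrix must have marker rownames and individual colnames")
  }
  for (nm in c("logr", "baf")) {
    m <- get(nm)
    extra_ind <- setdiff(colnames(genotype), colnames(m))
    if (length(extra_ind)) {
      stop(
        "individual(s) present in genotype but absent in ", nm, ": ",
        paste(utils::head(extra_ind, 5), collapse = ", ")
      )
    }
    if (!identical(dim(m), dim(genotype)) ||
        !identical(rownames(m), rownames(genotype)) ||
        !identical(colnames(m), colnames(genotype))) {
      stop("index sets of ", nm, " do not match the genotype matrix")
    }
  }
  genotype[is.na(genotype) | genotype == ""] <- "NC"
  bad <- setdiff(unique(as.vector(genotype)), GENOTYPE_TOKENS)
  if (length(bad)) {
    stop("invalid genotype token(s): ", paste(bad, collapse = ", "))
  }
  storage.mode(logr) <- "double"
  storage.mode(baf) <- "double"
  if (any(baf < -1e-9 | baf > 1 + 1e-9, na.rm = TRUE)) {
    stop("BAF values outside [0, 1]")
  }
  structure(
    list(
      genotype = genotype, logr = logr, baf = baf,
      marker_ids = rownames(genotype), individual_ids = colnames(genotype)
    ),
    class = "call_matrices"
  )
}

#' @export
print.call_matrices <- function(x, ...) {
  cat(
    "call_matrices:", length(x$marker_ids), "markers x",
    length(x$individual_ids), "individuals\n"
  )
  invisible(x)
}

#' Construct and validate population metadata
#'
#' One row per genotyped individual: the cross combination it derives from
#' (e.g. J1N1, N3C2), the hybrid type (AABC or CCAB), the gamete class
#' (reduced or unreduced) and the ids of the two species parents and the F1
#' hybrid. By package convention `parent1_id` is the *B. napus* parent, whose
#' homozygous allele is recoded to "a".
#'
#' @param df data.frame with columns `individual_id`, `combination`,
#'   `hybrid_type`, `gamete_class`, `derivation`, `parent1_id`, `parent2_id`,
#'   `f1_id`.
#' @return A `population_metadata` data.frame.
#' @export
population_metadata <- function(df) {
  req <- c(
    "individual_id", "combination", "hybrid_type", "gamete_class",
    "derivation", "parent1_id", "parent2_id", "f1_id"
  )
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[req]
  for (nm in req) df[[nm]] <- as.character(df[[nm]])
  if (anyDuplicated(df$individual_id)) {
    stop("individual_id values must be unique (one combination per individual)")
  }
  if (!all(df$hybrid_type %in% c("AABC", "CCAB"))) {
    stop("hybrid_type must be AABC or CCAB")
  }
  if (!all(df$gamete_class %in% c("reduced", "unreduced"))) {
    stop("gamete_class must be reduced or unreduced")
  }
  if (!all(df$derivation %in% c("microspore", "testcross"))) {
    stop("derivation must be microspore or testcross")
  }
  comb <- unique(df[c("combination", "parent1_id", "parent2_id", "f1_id")])
  if (anyDuplicated(comb$combination)) {
    stop("a combination maps to more than one parent/F1 trio")
  }
  rownames(df) <- NULL
  class(df) <- c("population_metadata", "data.frame")
  df
}

#' Construct and validate per-chromosome architecture
#'
#' Chromosome length plus centromere and pericentromere intervals (1-based,
#' closed). The pericentromere may be one interval or two flanking intervals.
#'
#' @param df data.frame with columns `chromosome`, `length_bp`, and one row
#'   per feature interval: `feature` in {centromere, pericentromere},
#'   `start_bp`, `end_bp`.
#' @return A `chromosome_architecture` data.frame (one row per feature
#'   interval, plus attribute-free `length_bp` per chromosome repeated on
#'   each row).
#' @export
chromosome_architecture <- function(df) {
  req <- c("chromosome", "length_bp", "feature", "start_bp", "end_bp")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("architecture is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[req]
  df$chromosome <- as.character(df$chromosome)
  for (nm in c("length_bp", "start_bp", "end_bp")) df[[nm]] <- as.double(df[[nm]])
  if (!all(df$feature %in% c("centromere", "pericentromere"))) {
    stop("feature must be centromere or pericentromere")
  }
  if (any(df$start_bp < 1 | df$end_bp > df$length_bp | df$start_bp > df$end_bp)) {
    stop("feature interval outside [1, length_bp] or start > end")
  }
  for (chr in unique(df$chromosome)) {
    sub <- df[df$chromosome == chr, , drop = FALSE]
    if (length(unique(sub$length_bp)) != 1L) {
      stop("inconsistent length_bp for chromosome ", chr)
    }
    ncen <- sum(sub$feature == "centromere")
    if (ncen == 0L) stop("chromosome ", chr, " has no centromere interval")
    if (ncen > 1L) stop("chromosome ", chr, " has ", ncen, " centromere rows")
    if (sum(sub$feature == "pericentromere") > 2L) {
      stop("chromosome ", chr, " has more than two pericentromere intervals")
    }
    o <- order(sub$start_bp)
    s <- sub[o, ]
    if (nrow(s) > 1L && any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
      stop("overlapping architecture intervals on chromosome ", chr)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("chromosome_architecture", "data.frame")
  df
}

#' Look up one architecture feature interval
#'
#' @param arch a [chromosome_architecture()] table.
#' @param chrom chromosome id.
#' @param feature "centromere" or "pericentromere".
#' @return data.frame of matching rows (0, 1 or 2 rows).
#' @keywords internal
arch_feature <- function(arch, chrom, feature) {
  arch[arch$chromosome == chrom & arch$feature == feature, , drop = FALSE]
}

#' Chromosome lengths from an architecture table
#' @param arch a [chromosome_architecture()] table.
#' @return named numeric vector of lengths in bp.
#' @export
chromosome_lengths <- function(arch) {
  u <- unique(arch[c("chromosome", "length_bp")])
  stats::setNames(u$length_bp, u$chromosome)
}

#' Construct an empty event table
#'
#' Event tables are plain data.frames with a stable column order shared by
#' crossover, CNV and non-homologous event sets.
#'
#' @return zero-row data.frame with the canonical event columns.
#' @export
empty_event_table <- function() {
  data.frame(
    individual_id = character(0), chromosome = character(0),
    start_bp = double(0), end_bp = double(0),
    event_type = character(0), subtype = character(0),
    support = integer(0), stringsAsFactors = FALSE
  )
}

#' Coerce a list of event rows into a canonical event table
#' @param rows list of one-row data.frames (or NULL entries).
#' @return canonical event table, sorted by individual, chromosome, start.
#' @keywords internal
bind_events <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  rows <- Filter(function(r) nrow(r) > 0, rows)
  if (!length(rows)) return(empty_event_table())
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$chromosome, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
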