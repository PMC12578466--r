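# Readers/writers for the external formats: GenomeStudio-export-like TSV
# matrices, marker-map TSV, BED architecture, event-table TSV.
# Lines starting with '#' are treated as comments in every text format.

detect_delim <- function(path) {
  first <- readLines(path, n = 25L)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) stop("empty file: ", path)
  if (grepl("\t", first[1])) "\t" else ","
}

read_table_generic <- function(path, ...) {
  utils::read.table(
    path,
    sep = detect_delim(path), header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE, quote = "\"", ...
  )
}

read_matrix_tsv <- function(path, numeric = FALSE, markers_as = c("rows", "cols")) {
  markers_as <- match.arg(markers_as)
  df <- read_table_generic(path)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (markers_as == "cols") m <- t(m)
  if (numeric) {
    suppressWarnings(num <- matrix(
      as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)
    ))
    bad <- which(is.na(num) & !(is.na(m) | m %in% c("", "NA", "NaN", "nan")))
    if (length(bad)) {
      i <- bad[1]
      stop(
        "unparseable numeric cell in ", basename(path), " at row '",
        rownames(m)[(i - 1) %% nrow(m) + 1], "', column '",
        colnames(m)[(i - 1) %/% nrow(m) + 1], "': '", m[i], "'"
      )
    }
    num
  } else {
    m
  }
}

#' Read aligned genotype, logR and BAF matrices
#'
#' Reads three Infinium-export-style delimited files (TSV or CSV, delimiter
#' auto-detected) holding genotype calls, log R ratios and B-allele
#' frequencies, and aligns them into one [call_matrices()] container.
#' The first column carries marker ids, remaining columns are individuals
#' (set `markers_as = "cols"` for the transposed layout). Missing numeric
#' cells (empty, NA, NaN) become NA; missing genotype cells become NC.
#'
#' @param genotype_path,logr_path,baf_path file paths.
#' @param markers_as "rows" (default) or "cols".
#' @return a [call_matrices()] object.
#' @export
read_call_matrices <- function(genotype_path, logr_path, baf_path,
                               markers_as = c("rows", "cols")) {
  markers_as <- match.arg(markers_as)
  g <- read_matrix_tsv(genotype_path, numeric = FALSE, markers_as = markers_as)
  r <- read_matrix_tsv(logr_path, numeric = TRUE, markers_as = markers_as)
  b <- read_matrix_tsv(baf_path, numeric = TRUE, markers_as = markers_as)
  for (nm in c("r", "b")) {
    m <- get(nm)
    lab <- if (nm == "r") "logR" else "BAF"
    missing_ind <- setdiff(colnames(g), colnames(m))
    if (length(missing_ind)) {
      stop(
        "individual(s) in genotype but not in ", lab, ": ",
        paste(utils::head(missing_ind, 5), collapse = ", ")
      )
    }
    missing_mk <- setdiff(rownames(g), rownames(m))
    if (length(missing_mk)) {
      stop(
        "marker(s) in genotype but not in ", lab, ": ",
        paste(utils::head(missing_mk, 5), collapse = ", ")
      )
    }
    assign(nm, m[rownames(g), colnames(g), drop = FALSE])
  }
  call_matrices(g, r, b)
}

#' Read a marker map TSV
#'
#' Expects columns `marker_id`, `chromosome`, `position_bp`; rows are sorted
#' by (chromosome, position) and duplicate marker ids are rejected.
#'
#' @param path file path.
#' @return a [marker_map()] object.
#' @export
read_marker_map <- function(path) {
  marker_map(read_table_generic(path))
}

#' Read chromosome architecture from a BED-like file
#'
#' The file is 0-based, half-open with columns chromosome, start, end,
#' feature; feature is one of `chromosome` (defines the length),
#' `centromere`, `pericentromere`. Coordinates are converted to the internal
#' 1-based closed convention. Every chromosome must have a `chromosome` row
#' and exactly one centromere.
#'
#' @param path file path.
#' @return a [chromosome_architecture()] object.
#' @export
read_architecture <- function(path) {
  raw <- utils::read.table(
    path,
    sep = "\t", header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE,
    col.names = c("chromosome", "start", "end", "feature")
  )
  lens <- raw[raw$feature == "chromosome", , drop = FALSE]
  if (!nrow(lens)) stop("architecture file has no 'chromosome' length rows")
  feat <- raw[raw$feature != "chromosome", , drop = FALSE]
  len_map <- stats::setNames(lens$end - lens$start, lens$chromosome)
  nolen <- setdiff(feat$chromosome, names(len_map))
  if (length(nolen)) {
    stop("feature rows for chromosome(s) without a length row: ",
         paste(nolen, collapse = ", "))
  }
  out <- data.frame(
    chromosome = feat$chromosome,
    length_bp = as.double(len_map[feat$chromosome]),
    feature = feat$feature,
    start_bp = feat$start + 1, # 0-based half-open -> 1-based closed
    end_bp = feat$end,
    stringsAsFactors = FALSE
  )
  nocen <- setdiff(
    names(len_map), out$chromosome[out$feature == "centromere"]
  )
  if (length(nocen)) {
    stop("missing centromere for chromosome(s): ", paste(nocen, collapse = ", "))
  }
  chromosome_architecture(out)
}

#' Read population metadata TSV
#' @param path file path.
#' @return a [population_metadata()] object.
#' @export
read_population_metadata <- function(path) {
  population_metadata(read_table_generic(path))
}

#' Write an event table to TSV
#'
#' Columns: individual_id, chromosome, start_bp, end_bp, event_type,
#' subtype, support — in that order. An empty event set yields a header-only
#' file. A manifest hash, when supplied, is written as a leading `#` comment.
#'
#' @param events canonical event table (see [empty_event_table()]).
#' @param path destination path.
#' @param manifest_hash optional string recorded as a comment header.
#' @export
write_event_table <- function(events, path, manifest_hash = NULL) {
  cols <- names(empty_event_table())
  miss <- setdiff(cols, names(events))
  if (length(miss)) {
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(manifest_hash)) {
    writeLines(paste0("# manifest_hash: ", manifest_hash), con)
  }
  utils::write.table(
    events[cols], con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}

#' Read an event table written by [write_event_table()]
#' @param path file path.
#' @return canonical event table.
#' @export
read_event_table <- function(path) {
  df <- utils::read.table(
    path,
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE,
    colClasses = c(
      individual_id = "character", chromosome = "character",
      start_bp = "numeric", end_bp = "numeric",
      event_type = "character", subtype = "character", support = "integer"
    )
  )
  df[names(empty_event_table())]
}

# digits = 15 keeps the numeric round-trip within 1e-12
write_matrix_tsv <- function(m, path, id_col = "marker_id", digits = 15) {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  if (is.numeric(m)) {
    for (j in seq(2, ncol(df))) df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    df[df == "NA"] <- "NA"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
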