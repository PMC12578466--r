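# Independent oracles, kept deliberately naive: explicit scans and loops,
# no rle(), so they share no code path with the implementation.

# leftmost-short-run replacement to fixpoint, by explicit scanning
oracle_smooth <- function(x, min_run) {
  repeat {
    runs <- list()
    s <- 1L
    for (i in seq_along(x)) {
      if (i == length(x) || x[i + 1L] != x[i]) {
        runs[[length(runs) + 1L]] <- c(s, i)
        s <- i + 1L
      }
    }
    if (length(runs) <= 1L) return(x)
    lens <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
    k <- which(lens < min_run)
    if (!length(k)) return(x)
    k <- k[1L]
    idx <- runs[[k]][1]:runs[[k]][2]
    x[idx] <- if (k == 1L) x[runs[[2L]][1]] else x[runs[[k - 1L]][1]]
  }
}

oracle_transition_count <- function(x) {
  n <- 0L
  for (i in seq_len(length(x) - 1L)) if (x[i] != x[i + 1L]) n <- n + 1L
  n
}

# all sequences over {a,b} of a given length, as a character matrix
all_ab_sequences <- function(len) {
  grid <- do.call(expand.grid, rep(list(c("a", "b")), len))
  as.matrix(grid)
}

make_vec <- function(symbols, positions_bp, chrom = "A1", ind = "ind1") {
  structure(
    list(
      individual_id = ind, chromosome = chrom,
      symbols = symbols, positions_bp = positions_bp,
      marker_ids = sprintf("m%03d", seq_along(symbols))
    ),
    class = "recoded_vector"
  )
}

# tiny three-individual call set: 10 markers on A1, hand-specified calls
toy_dataset <- function() {
  markers <- sprintf("m%02d", 1:10)
  map <- marker_map(data.frame(
    marker_id = markers, chromosome = "A1",
    position_bp = seq(1e6, 10e6, by = 1e6)
  ))
  ind <- c("N1", "J1", "F1_J1N1", "prog1", "prog2")
  g <- matrix("AA", 10, 5, dimnames = list(markers, ind))
  g[, "J1"] <- "BB"
  g[, "F1_J1N1"] <- "AB"
  g[, "prog1"] <- c(rep("AA", 5), rep("BB", 5))
  g[, "prog2"] <- c(rep("BB", 3), "AB", "NC", rep("AA", 5))
  r <- matrix(0, 10, 5, dimnames = dimnames(g))
  b <- matrix(0, 10, 5, dimnames = dimnames(g))
  b[, "J1"] <- 1
  b[, "F1_J1N1"] <- 0.5
  b[, "prog1"] <- c(rep(0, 5), rep(1, 5))
  b[, "prog2"] <- c(rep(1, 3), 0.5, 0.5, rep(0, 5))
  meta <- population_metadata(data.frame(
    individual_id = c("prog1", "prog2"), combination = "J1N1",
    hybrid_type = "AABC", gamete_class = "reduced",
    derivation = "microspore", parent1_id = "N1", parent2_id = "J1",
    f1_id = "F1_J1N1", stringsAsFactors = FALSE
  ))
  list(calls = call_matrices(g, r, b), map = map, meta = meta)
}
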