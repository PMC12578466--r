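test_that("run smoothing follows the leftmost-replacement fixpoint rules", {
  # uniform sequence unchanged for any min_run
  expect_equal(smooth_runs(rep("a", 20), 13), rep("a", 20))
  # interior short run absorbed into the preceding run
  expect_equal(
    smooth_runs(c(rep("a", 6), rep("b", 2), rep("a", 6)), 5),
    rep("a", 14)
  )
  # leading short run takes the following run's value, runs merge
  expect_equal(smooth_runs(c(rep("a", 3), rep("b", 3)), 5), rep("b", 6))
})

test_that("smoothing is idempotent and leaves no short runs", {
  set.seed(101)
  for (rep_i in 1:50) {
    x <- sample(c("a", "b", "h"), sample(5:60, 1), replace = TRUE)
    for (L in c(2, 3, 5, 8)) {
      sm <- smooth_runs(x, L)
      expect_identical(smooth_runs(sm, L), sm)
      r <- rle(sm)
      expect_true(all(r$lengths >= L) || length(r$lengths) == 1L)
    }
  }
})

test_that("smoothing agrees with the naive scanning oracle", {
  set.seed(202)
  for (rep_i in 1:200) {
    x <- sample(c("a", "b"), sample(2:30, 1), replace = TRUE)
    L <- sample(2:6, 1)
    expect_identical(smooth_runs(x, L), oracle_smooth(x, L))
  }
})

test_that("NA-deletion masking records deletions and imputes short gaps", {
  pos <- (1:20) * 1e6
  # no missing: nothing changes
  x <- rep(c("a", "b"), each = 10)
  m <- mask_na_deletions(x, pos, 10)
  expect_equal(m$symbols, x)
  expect_equal(nrow(m$deletions), 0L)

  # 12-long missing run with threshold 10 -> one deletion interval
  x <- c(rep("a", 4), rep("missing", 12), rep("a", 4))
  m <- mask_na_deletions(x, pos, 10)
  expect_equal(nrow(m$deletions), 1L)
  expect_equal(m$deletions$start_bp, 5e6)
  expect_equal(m$deletions$end_bp, 16e6)
  expect_true(all(m$masked[5:16]))

  # short gap with agreeing flanks is imputed
  x <- c(rep("a", 8), rep("missing", 2), rep("a", 8))
  m <- mask_na_deletions(x, pos[1:18], 10)
  expect_equal(m$symbols, rep("a", 18))

  # short gap with disagreeing flanks stays missing
  x <- c(rep("a", 8), rep("missing", 2), rep("b", 8))
  m <- mask_na_deletions(x, pos[1:18], 10)
  expect_equal(m$symbols[9:10], c("missing", "missing"))
})

test_that("crossover calls report the inter-marker interval and midpoint", {
  # all-a chromosome: no transitions
  vec <- make_vec(rep("a", 20), (1:20) * 5e5)
  expect_equal(nrow(call_crossovers(vec)$events), 0L)

  # a-block then b-block with boundary between 4.1 and 4.3 Mb
  pos <- c(seq(0.1e6, 4.1e6, by = 0.5e6), seq(4.3e6, 8.3e6, by = 0.5e6))
  sym <- rep(c("a", "b"), each = 9)
  res <- call_crossovers(make_vec(sym, pos))
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$start_bp, 4.1e6)
  expect_equal(res$events$end_bp, 4.3e6)
  expect_equal(res$transitions$midpoint_bp, 4.2e6)
  expect_equal(res$transitions$left_state, "a")
  expect_equal(res$transitions$right_state, "b")
})

test_that("transitions closer than 2 Mb are merged away", {
  # a,b,a blocks with transitions 1 Mb apart: inner b removed, 0 crossovers
  pos <- (1:30) * 1e5 # 100 kb spacing
  sym <- c(rep("a", 10), rep("b", 10), rep("a", 10))
  res <- call_crossovers(make_vec(sym, pos), smoothing_params(min_run = 5))
  expect_equal(nrow(res$events), 0L)

  # same geometry but transitions > 2 Mb apart: both kept
  pos2 <- (1:30) * 1.1e6
  res2 <- call_crossovers(make_vec(sym, pos2), smoothing_params(min_run = 5))
  expect_equal(nrow(res2$events), 2L)
  expect_true(all(diff(res2$transitions$midpoint_bp) >= 2e6))

  # differing flanks: one transition survives the merge
  sym3 <- c(rep("a", 10), rep("h", 10), rep("b", 10))
  res3 <- call_crossovers(
    make_vec(sym3, pos), smoothing_params(min_run = 5), "unreduced"
  )
  expect_equal(nrow(res3$events), 1L)
})

test_that("crossover counts match the oracle on all short {a,b} sequences", {
  # exhaustive check restricted here to length <= 8; the full sweep to
  # length 12 runs in the acceptance suite
  for (len in 2:8) {
    seqs <- all_ab_sequences(len)
    pos <- (1:len) * 3e6 # spacing > 2 Mb so merging never triggers
    for (i in seq_len(nrow(seqs))) {
      x <- unname(seqs[i, ])
      for (L in c(2, 3)) {
        expected <- oracle_transition_count(oracle_smooth(x, L))
        got <- nrow(call_crossovers(
          make_vec(x, pos), smoothing_params(min_run = L)
        )$events)
        expect_equal(got, expected)
      }
    }
  }
})

test_that("strong smoothing yields no more breakpoints than weak smoothing", {
  # leftmost-replacement smoothing is not strictly monotone between every
  # pair of neighbouring min_run values (replacement cascades can differ),
  # but the production extremes order: min_run 15 never exceeds min_run 3
  set.seed(303)
  pos <- (1:80) * 3e6 # spacing wide enough that distance-merging is inert
  for (rep_i in 1:100) {
    x <- sample(c("a", "b"), 80, replace = TRUE, prob = c(0.6, 0.4))
    c3 <- nrow(call_crossovers(make_vec(x, pos), smoothing_params(min_run = 3))$events)
    c15 <- nrow(call_crossovers(make_vec(x, pos), smoothing_params(min_run = 15))$events)
    expect_lte(c15, c3)
  }
})

test_that("min_run selection prefers the smallest admissible production value", {
  pos <- (1:100) * 6e5
  # clean two-block vector: every candidate yields 1 breakpoint -> 5 chosen
  clean <- make_vec(c(rep("a", 50), rep("b", 50)), pos)
  sel <- select_min_run(list(clean), "reduced")
  expect_equal(sel$chosen, 5L)
  expect_false(sel$qc_flag)

  # blocks of 6 markers survive min_run 5 (25 transitions, > 20) but
  # collapse at min_run 10 -> 10 chosen
  blocks6 <- rep(rep(c("a", "b"), 13), each = 6)
  pos6 <- seq_along(blocks6) * 4e5 # transitions 2.4 Mb apart
  counts5 <- nrow(call_crossovers(
    make_vec(blocks6, pos6), smoothing_params(min_run = 5)
  )$events)
  counts10 <- nrow(call_crossovers(
    make_vec(blocks6, pos6), smoothing_params(min_run = 10)
  )$events)
  expect_gt(counts5, 20)
  expect_lte(counts10, 20)
  sel2 <- select_min_run(list(make_vec(blocks6, pos6)), "reduced")
  expect_equal(sel2$chosen, 10L)
  expect_false(sel2$qc_flag)

  # adversarial vector with 22 runs of 15 markers: > 20 breakpoints at
  # every production value -> 15 used with a QC flag
  blocks15 <- rep(rep(c("a", "b"), 11), each = 15)
  pos15 <- seq_along(blocks15) * 2e5 # transitions 3 Mb apart
  sel3 <- select_min_run(list(make_vec(blocks15, pos15)), "reduced")
  expect_true(all(sel3$max_breakpoints[as.character(c(5, 10, 13, 15))] > 20))
  expect_equal(sel3$chosen, 15L)
  expect_true(sel3$qc_flag)
  expect_error(select_min_run(list(), character(0)), "empty population")
})

test_that("breakpoint counting aggregates per chromosome and individual", {
  ev <- rbind(
    data.frame(
      individual_id = "i1", chromosome = "A5",
      start_bp = c(1e6, 5e6, 9e6), end_bp = c(1.2e6, 5.2e6, 9.2e6),
      event_type = "crossover", subtype = "homologous", support = NA_integer_
    ),
    data.frame(
      individual_id = "i1", chromosome = "A5", start_bp = 2e6, end_bp = 2.2e6,
      event_type = "crossover", subtype = "excluded_nonhomologous",
      support = NA_integer_
    )
  )
  cb <- count_breakpoints(ev, c("i1", "i2"), paste0("A", 1:10))
  expect_equal(unname(cb$counts["i1", "A5"]), 3L) # excluded events not counted
  expect_equal(unname(cb$genome_total), c(3, 0))
  expect_equal(cb$population_mean, 1.5)
  cb0 <- count_breakpoints(empty_event_table(), c("i1", "i2"), "A1")
  expect_true(all(cb0$counts == 0))
})
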