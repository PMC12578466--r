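test_that("clean a/b mosaics with normal copy number yield no events", {
  pos <- (1:40) * 1e6
  vec <- make_vec(c(rep("a", 20), rep("b", 20)), pos)
  segs <- data.frame(
    start_bp = 1e6, end_bp = 40e6, start_index = 1, end_index = 40,
    n_markers = 40, mean_logr = 0, baf_state = "hom", cnv_class = "normal"
  )
  expect_equal(nrow(detect_nonhom_reduced(vec, segs)), 0L)
  # property: detector never fires on pure {a,b} vectors with normal CN
  set.seed(11)
  for (i in 1:20) {
    v <- make_vec(sample(c("a", "b"), 40, TRUE), pos)
    expect_equal(nrow(detect_nonhom_reduced(v, segs)), 0L)
  }
})

test_that("a terminal h run becomes a terminal translocation event", {
  pos <- (1:40) * 1e6
  vec <- make_vec(c(rep("a", 25), rep("h", 15)), pos)
  ev <- detect_nonhom_reduced(vec, NULL, smoothing_params(min_run = 10))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$subtype, "translocation")
  expect_equal(ev$evidence, "het_calls")
  expect_equal(ev$location_class, "terminal")
  expect_equal(ev$start_bp, 26e6)
  expect_equal(ev$end_bp, 40e6)

  # interior h run -> interstitial
  vec2 <- make_vec(c(rep("a", 12), rep("h", 15), rep("b", 13)), pos)
  ev2 <- detect_nonhom_reduced(vec2, NULL, smoothing_params(min_run = 10))
  expect_equal(ev2$location_class, "interstitial")
})

test_that("missing runs with CNV corroboration become deletion events", {
  pos <- (1:40) * 1e6
  vec <- make_vec(c(rep("a", 14), rep("missing", 12), rep("a", 14)), pos)
  del_seg <- data.frame(
    start_bp = 15e6, end_bp = 26e6, start_index = 15, end_index = 26,
    n_markers = 12, mean_logr = -2, baf_state = "hom", cnv_class = "deletion"
  )
  normal_seg <- data.frame(
    start_bp = 1e6, end_bp = 40e6, start_index = 1, end_index = 40,
    n_markers = 40, mean_logr = 0, baf_state = "hom", cnv_class = "normal"
  )
  ev <- detect_nonhom_reduced(vec, del_seg, smoothing_params(min_run = 10))
  expect_equal(ev$subtype, "deletion")
  expect_true(grepl("nc_calls", ev$evidence))
  # without corroborating CNV deletion, no deletion event is emitted
  ev2 <- detect_nonhom_reduced(vec, normal_seg, smoothing_params(min_run = 10))
  expect_equal(nrow(ev2), 0L)
})

test_that("unreduced events come from BAF third-ratios and CNV classes", {
  segs <- data.frame(
    start_bp = c(1e6, 20e6), end_bp = c(19e6, 40e6),
    start_index = c(1, 20), end_index = c(19, 40),
    n_markers = c(19, 21), mean_logr = c(0, 0.25),
    baf_state = c("het", "third_ratio"),
    cnv_class = c("normal", "duplication")
  )
  ev <- detect_nonhom_unreduced("i1", "A2", segs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$subtype, "translocation")
  expect_true(grepl("baf_third_ratio", ev$evidence))
  expect_true(grepl("logr_shift", ev$evidence))

  # balanced diploid: flat logR, het BAF -> nothing
  segs0 <- segs[1, ]
  expect_equal(nrow(detect_nonhom_unreduced("i1", "A2", segs0)), 0L)

  # NC-dominated deletion segment
  segs$cnv_class[2] <- "deletion"
  segs$baf_state[2] <- "hom"
  segs$mean_logr[2] <- -2
  g <- c(rep("AB", 19), rep("NC", 21))
  ev3 <- detect_nonhom_unreduced("i1", "A2", segs, g, (1:40) * 1e6)
  expect_equal(ev3$subtype, "deletion")
  expect_true(grepl("nc_calls", ev3$evidence))
})

test_that("crossovers at non-homologous boundaries are excluded, others kept", {
  cos <- data.frame(
    individual_id = "i1", chromosome = "A1",
    start_bp = c(5e6, 20e6), end_bp = c(5.4e6, 20.4e6),
    event_type = "crossover", subtype = "homologous", support = NA_integer_
  )
  expect_equal(
    exclude_nonhom_breakpoints(cos, empty_event_table())$subtype,
    c("homologous", "homologous")
  )
  nh <- data.frame(
    individual_id = "i1", chromosome = "A1", start_bp = 5.6e6, end_bp = 9e6,
    event_type = "nonhom", subtype = "translocation", support = 10L
  )
  out <- exclude_nonhom_breakpoints(cos, nh, margin_bp = 5e5)
  expect_equal(out$subtype, c("excluded_nonhomologous", "homologous"))
  # partition property: homologous + excluded = raw
  expect_equal(nrow(out), nrow(cos))
  expect_equal(
    sum(out$subtype == "homologous") +
      sum(out$subtype == "excluded_nonhomologous"),
    nrow(cos)
  )
  # other individuals are untouched
  nh2 <- nh
  nh2$individual_id <- "i2"
  expect_equal(
    exclude_nonhom_breakpoints(cos, nh2)$subtype,
    c("homologous", "homologous")
  )
})

test_that("simulated exchanges are detected and contain the true breakpoint", {
  cfg <- sim_config(
    markers_per_chromosome = 100L,
    p_nonhom_exchange = 1, p_whole_chrom_loss = 0, p_whole_chrom_gain = 0,
    interstitial_fraction = 0,
    noise_sd_logr = 0, noise_sd_baf = 0, missing_rate = 0,
    combinations = data.frame(
      combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
      n_reduced = 8L, n_unreduced = 8L, co_rate = 0
    ),
    seed = 31L
  )
  sim <- simulate_population(cfg)
  res <- run_pipeline_stages(
    sim$calls, sim$map, sim$arch, sim$meta,
    smoothing = smoothing_params(min_run = 5), select = FALSE, quiet = TRUE
  )
  truth_ex <- sim$truth[
    sim$truth$event_type == "nonhom_exchange" &
      startsWith(sim$truth$chromosome, "A"), , drop = FALSE
  ]
  # every gamete carries one exchange on a diploid-subgenome chromosome;
  # require detection overlapping the truth interval for ample events
  n_hit <- 0L
  for (j in seq_len(nrow(truth_ex))) {
    hit <- any(
      res$nonhom_events$individual_id == truth_ex$individual_id[j] &
        res$nonhom_events$chromosome == truth_ex$chromosome[j] &
        res$nonhom_events$start_bp <= truth_ex$end_bp[j] &
        res$nonhom_events$end_bp >= truth_ex$start_bp[j]
    )
    n_hit <- n_hit + hit
  }
  expect_equal(nrow(truth_ex), 16L)
  expect_gte(n_hit / nrow(truth_ex), 0.9)
})

test_that("non-homologous summaries tabulate fractions of individuals", {
  ev <- data.frame(
    individual_id = c("i1", "i3"), chromosome = "A7",
    start_bp = 1e6, end_bp = 5e6, event_type = "nonhom",
    subtype = c("translocation", "deletion"), support = 10L
  )
  s <- summarize_nonhom(ev, paste0("i", 1:4), paste0("A", 1:10))
  expect_equal(s$fraction_affected, 0.5)
  tr_a7 <- s$by_chromosome$n_individuals[
    s$by_chromosome$chromosome == "A7" &
      s$by_chromosome$subtype == "translocation"
  ]
  expect_equal(tr_a7, 1L)
  s0 <- summarize_nonhom(empty_event_table(), paste0("i", 1:4), "A1")
  expect_equal(s0$fraction_affected, 0)
})
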