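test_that("null meiosis returns unrecombined parental chromatids", {
  set.seed(1)
  pos <- (1:50) * 1e6
  biv <- simulate_bivalent(pos, 50e6, c(22e6, 26e6), co_rate = 0)
  expect_equal(nrow(biv$co), 0L)
  expect_equal(biv$chromatids[1:2, ], matrix("a", 2, 50))
  expect_equal(biv$chromatids[3:4, ], matrix("b", 2, 50))
})

test_that("crossover counts are Poisson and avoid the centromere", {
  set.seed(2)
  pos <- (1:50) * 1e6
  counts <- replicate(2000, {
    nrow(simulate_bivalent(pos, 50e6, c(22e6, 26e6), co_rate = 2)$co)
  })
  se <- sqrt(2 / 2000)
  expect_lt(abs(mean(counts) - 2), 3 * se)

  # suppression factor 0: no crossover position inside the centromere
  xs <- unlist(replicate(300, {
    simulate_bivalent(pos, 50e6, c(22e6, 26e6), co_rate = 3)$co$position_bp
  }))
  expect_false(any(xs >= 22e6 & xs <= 26e6))
  # suppression 1: uniform density, centromeric positions do occur
  set.seed(3)
  xs2 <- unlist(replicate(300, {
    simulate_bivalent(pos, 50e6, c(22e6, 26e6), co_rate = 3,
                      suppression = 1)$co$position_bp
  }))
  expect_true(any(xs2 >= 22e6 & xs2 <= 26e6))
  # obligate crossover: zero-truncated counts
  set.seed(4)
  n0 <- replicate(200, nrow(
    simulate_bivalent(pos, 50e6, c(22e6, 26e6), co_rate = 0.5,
                      obligate = TRUE)$co
  ))
  expect_true(all(n0 >= 1))
})

test_that("gamete sampling follows the reduced and FDR mechanisms", {
  set.seed(5)
  pos <- (1:60) * 1e6
  biv0 <- simulate_bivalent(pos, 60e6, c(27e6, 31e6), co_rate = 0)
  # reduced, no crossover: exactly one parental haplotype
  g <- sample_gamete(biv0, "reduced")
  expect_true(all(g == "a") || all(g == "b"))
  # FDR, no crossover: heterozygous at every marker
  g2 <- sample_gamete(biv0, "FDR_unreduced")
  expect_equal(nrow(g2), 2L)
  expect_true(all(meioscan:::gamete_states(g2) == "h"))
  expect_error(sample_gamete(biv0, "SDR"), "unknown gamete mechanism")
})

test_that("FDR gametes are het through the crossover then 50:50 het:hom", {
  # one crossover per bivalent on the long arm: proximal side stays het;
  # distal of the crossover, hom:het is 1:1 (one-sampled-chromatid events
  # toggle the state; two- or zero-chromatid events leave it het)
  set.seed(6)
  pos <- (1:60) * 1e6
  cen <- c(27e6, 31e6)
  n_hom_distal <- 0L
  n_total <- 0L
  for (i in 1:1200) {
    biv <- simulate_bivalent(pos, 60e6, cen, co_rate = 1, obligate = TRUE)
    if (nrow(biv$co) != 1L) next
    x <- biv$co$position_bp
    if (x < mean(cen)) next # use right-arm crossovers for a clean readout
    g <- sample_gamete(biv, "FDR_unreduced")
    s <- meioscan:::gamete_states(g)
    proximal <- pos > mean(cen) & pos < x
    distal <- pos > x
    if (!any(distal) || !any(proximal)) next
    expect_true(all(s[pos <= mean(cen)] == "h")) # centromere side always het
    expect_true(all(s[proximal] == "h"))
    st <- unique(s[distal])
    expect_length(st, 1L)
    n_total <- n_total + 1L
    if (st != "h") n_hom_distal <- n_hom_distal + 1L
  }
  expect_gt(n_total, 200L)
  p_hat <- n_hom_distal / n_total
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_total))
})

test_that("parental-allele transmission in reduced gametes is 50:50", {
  set.seed(7)
  pos <- (1:40) * 1e6
  locus <- 10L
  alleles <- replicate(2000, {
    biv <- simulate_bivalent(pos, 40e6, c(18e6, 21e6), co_rate = 2)
    sample_gamete(biv, "reduced")[1, locus]
  })
  p_a <- mean(alleles == "a")
  expect_lt(abs(p_a - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("structural events occur at the configured rates", {
  cfg0 <- sim_config(
    p_nonhom_exchange = 0, p_whole_chrom_loss = 0, p_whole_chrom_gain = 0,
    noise_sd_logr = 0, noise_sd_baf = 0, missing_rate = 0,
    markers_per_chromosome = 20L, n_chrom_a = 2L, n_chrom_c = 2L,
    chrom_lengths_bp = c(A1 = 30e6, A2 = 32e6, C1 = 40e6, C2 = 42e6),
    combinations = data.frame(
      combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
      n_reduced = 5L, n_unreduced = 5L, co_rate = NA_real_
    ),
    seed = 8L
  )
  sim0 <- simulate_population(cfg0)
  expect_equal(
    sum(sim0$truth$event_type %in%
          c("nonhom_exchange", "whole_loss", "whole_gain")), 0L
  )
  # forced exchange: every gamete has at least one exchange record
  cfg1 <- cfg0
  cfg1$p_nonhom_exchange <- 1
  sim1 <- simulate_population(cfg1)
  ex_by_ind <- table(
    sim1$truth$individual_id[sim1$truth$event_type == "nonhom_exchange"]
  )
  expect_equal(length(ex_by_ind), 10L)
  expect_true(all(ex_by_ind >= 1))

  # binomial rate check at p = 0.3 over 300 gametes
  cfg2 <- cfg0
  cfg2$p_nonhom_exchange <- 0.3
  cfg2$combinations$n_reduced <- 150L
  cfg2$combinations$n_unreduced <- 150L
  sim2 <- simulate_population(cfg2)
  frac <- length(unique(
    sim2$truth$individual_id[sim2$truth$event_type == "nonhom_exchange"]
  )) / 300
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 300))
})

test_that("noise-free signals take the closed-form dosage values", {
  cfg <- sim_config(
    p_nonhom_exchange = 0, p_whole_chrom_loss = 0, p_whole_chrom_gain = 0,
    noise_sd_logr = 0, noise_sd_baf = 0, missing_rate = 0,
    markers_per_chromosome = 30L, n_chrom_a = 2L, n_chrom_c = 2L,
    chrom_lengths_bp = c(A1 = 30e6, A2 = 32e6, C1 = 40e6, C2 = 42e6),
    combinations = data.frame(
      combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
      n_reduced = 3L, n_unreduced = 3L, co_rate = 1
    ),
    seed = 9L
  )
  sim <- simulate_population(cfg)
  prog <- sim$meta$individual_id
  expect_true(all(sim$calls$baf[, prog] %in% c(0, 0.5, 1)))
  expect_true(all(sim$calls$logr[, prog] == 0))
  # unreduced diploid-subgenome markers: AB wherever the two chromatids
  # disagree, with BAF exactly 0.5
  un <- sim$meta$individual_id[sim$meta$gamete_class == "unreduced"][1]
  a_markers <- sim$map$marker_id[sim$map$subgenome == "A"]
  het <- sim$calls$genotype[a_markers, un] == "AB"
  expect_true(any(het))
  expect_true(all(sim$calls$baf[a_markers, un][het] == 0.5))

  # a deleted (single-copy) region on a two-copy baseline reads logR -1:
  # force a whole-chromosome loss in an unreduced gamete
  cfg2 <- cfg
  cfg2$p_whole_chrom_loss <- 1
  sim2 <- simulate_population(cfg2)
  loss <- sim2$truth[sim2$truth$event_type == "whole_loss", ]
  un2 <- sim2$meta$individual_id[sim2$meta$gamete_class == "unreduced"]
  loss_un <- loss[loss$individual_id %in% un2 &
                    startsWith(loss$chromosome, "A"), ]
  if (nrow(loss_un)) {
    mk <- sim2$map$marker_id[sim2$map$chromosome == loss_un$chromosome[1]]
    expect_true(all(
      sim2$calls$logr[mk, loss_un$individual_id[1]] == -1
    ))
  }
  # zero-copy regions read the floor with NC calls: loss in a reduced gamete
  red2 <- sim2$meta$individual_id[sim2$meta$gamete_class == "reduced"]
  loss_red <- loss[loss$individual_id %in% red2, ]
  if (nrow(loss_red)) {
    mk <- sim2$map$marker_id[sim2$map$chromosome == loss_red$chromosome[1]]
    expect_true(all(
      sim2$calls$genotype[mk, loss_red$individual_id[1]] == "NC"
    ))
    expect_true(all(sim2$calls$logr[mk, loss_red$individual_id[1]] == -2))
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(
    markers_per_chromosome = 25L, n_chrom_a = 2L, n_chrom_c = 2L,
    chrom_lengths_bp = c(A1 = 30e6, A2 = 32e6, C1 = 40e6, C2 = 42e6),
    combinations = data.frame(
      combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
      n_reduced = 3L, n_unreduced = 3L, co_rate = NA_real_
    ),
    seed = 10L
  )
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$calls$genotype, s2$calls$genotype)
  expect_identical(s1$calls$logr, s2$calls$logr)
  expect_identical(s1$calls$baf, s2$calls$baf)
  expect_identical(s1$truth, s2$truth)
})

test_that("simulated datasets round-trip through the file readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(
    markers_per_chromosome = 25L, n_chrom_a = 2L, n_chrom_c = 2L,
    chrom_lengths_bp = c(A1 = 30e6, A2 = 32e6, C1 = 40e6, C2 = 42e6),
    combinations = data.frame(
      combination = "J1N1", parent1_id = "N1", parent2_id = "J1",
      n_reduced = 2L, n_unreduced = 2L, co_rate = NA_real_
    ),
    seed = 12L
  )
  sim <- simulate_population(cfg)
  paths <- write_simulated_dataset(sim, dir)
  cm <- read_call_matrices(paths[["genotype"]], paths[["logr"]], paths[["baf"]])
  expect_identical(cm$genotype, sim$calls$genotype)
  expect_lt(max(abs(cm$logr - sim$calls$logr)), 1e-12)
  map <- read_marker_map(paths[["map"]])
  expect_equal(map$marker_id, sim$map$marker_id)
  expect_equal(map$position_bp, sim$map$position_bp)
  arch <- read_architecture(paths[["arch"]])
  expect_equal(
    chromosome_lengths(arch)[names(cfg$chrom_lengths_bp)],
    cfg$chrom_lengths_bp
  )
  meta <- read_population_metadata(paths[["meta"]])
  expect_equal(as.data.frame(meta), as.data.frame(sim$meta))
})
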