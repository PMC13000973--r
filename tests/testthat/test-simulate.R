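test_that("founder spectrum respects bounds, seed and heterozygosity", {
  p <- draw_founder_spectrum(1e5, seed = 1)
  expect_true(all(p >= 0.1 & p <= 0.9))
  # uniform(0.1, 0.9) implies E[2p(1-p)] ~ 0.39, the ancestral-pool
  # expected heterozygosity the spectrum is meant to emulate
  expect_equal(mean(2 * p * (1 - p)), 0.3933,
               tolerance = 3 * sd(2 * p * (1 - p)) / sqrt(1e5) / 0.3933)
  expect_identical(draw_founder_spectrum(50, seed = 7),
                   draw_founder_spectrum(50, seed = 7))
  expect_error(draw_founder_spectrum(10, founder = list(maf_min = 0.5)),
               "maf_min")
  pb <- draw_founder_spectrum(2000,
                              founder = list(dist = "beta", shape1 = 0.5,
                                             shape2 = 0.5, maf_min = 0.1),
                              seed = 2)
  expect_true(all(pb >= 0.1 & pb <= 0.9))
})

test_that("wf_step keeps absorbing states and is drift-free at huge Ne", {
  expect_equal(wf_step(c(0, 1), ne = 50, s = 0.3), c(0, 1))
  withr::with_seed(3, {
    p <- runif(200)
    expect_true(all(abs(wf_step(p, ne = 1e6, s = 0) - p) < 0.01))
  })
})

test_that("wf_step drift variance matches the analytic formula", {
  withr::with_seed(4, {
    n <- 1e5
    p <- rep(0.5, n)
    for (g in 1:6) p <- wf_step(p, ne = 18, s = 0)
    dafsq <- (p - 0.5)^2
    expected <- drift_variance(0.5, rep(18, 6))
    se <- sd(dafsq) / sqrt(n)
    expect_lt(abs(mean(dafsq) - expected), 3 * se)
  })
})

test_that("monomorphic founders remain monomorphic through the generations", {
  p0 <- c(0, 1)
  p <- p0
  for (g in 1:6) p <- wf_step(p, ne = 18, s = 0.2)
  expect_equal(p, p0)
})

test_that("pool_read_counts follows the two-stage sampling model", {
  expect_equal(pool_read_counts(rep(0, 100), 25, seed = 1)$count,
               rep(0L, 100))
  rc <- pool_read_counts(rep(0.3, 1e4), n_individuals = 25,
                         depth_mean = 120, seed = 2)
  freq <- rc$count / rc$depth
  expect_lt(abs(mean(freq) - 0.3), 3 * sd(freq) / sqrt(1e4))
  expect_lt(abs(mean(rc$depth) - 120), 3 * sqrt(120 / 1e4))
  expect_error(pool_read_counts(0.5, 25, error_rate = 0.6), "error_rate")
})

test_that("one experiment per population: 2 treatments x 2 reps + G1 = 5 files", {
  cfg <- sim_config(design = tiny_design(), n_chromosomes = 1,
                    snps_per_chromosome = 20, chromosome_length = 1e5,
                    seed = 6)
  sim <- simulate_er_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- simulate_er_files(sim, dir)
  expect_length(paths$sync, 5L)
  expect_true(all(file.exists(paths$sync)))
})

test_that("selection pushes replicate frequencies in the configured direction", {
  # one locus favoured in ambient, disfavoured in hot
  deltas <- purrr::map_dfr(1:20, function(i) {
    cfg <- sim_config(design = tiny_design(ne = 100),
                      n_chromosomes = 1, snps_per_chromosome = 10,
                      chromosome_length = 1e5,
                      selected_loci = tibble::tibble(
                        locus = 5, s_ambient = 0.8, s_hot = -0.8),
                      seed = 100 + i)
    sim <- simulate_er_experiment(cfg)
    fr <- sites_to_frequencies(sim$sync, ancestral = "G1",
                               min_count = 1, min_cov = 1, max_cov = 1e4)
    sh <- allele_shifts(fr, cfg$design) |>
      dplyr::semi_join(sim$truth, by = c("chrom", "pos"))
    # daf is that of the G1-minor allele; reorient to the favoured allele
    orient <- sign(sim$founder$p0[sim$truth$locus] <= 0.5) * 2 - 1
    dplyr::summarise(dplyr::group_by(sh, temperature),
                     daf = mean(daf) * orient)
  })
  means <- tapply(deltas$daf, deltas$temperature, mean)
  expect_gt(means[["ambient"]], 0)
  expect_lt(means[["hot"]], 0)
})

test_that("no selection, huge Ne and deep reads give negligible shifts", {
  des <- tiny_design(ne = 1e6L, n_individuals = 10000L)
  cfg <- sim_config(design = des, n_chromosomes = 1,
                    snps_per_chromosome = 50, chromosome_length = 1e5,
                    depth_mean = 1e4, seed = 8)
  sim <- simulate_er_experiment(cfg)
  fr <- sites_to_frequencies(sim$sync, ancestral = "G1", max_cov = 1e6)
  sh <- allele_shifts(fr, des)
  expect_true(all(abs(sh$daf) < 0.05))
})

test_that("block-copy mode shares founder state within windows", {
  cfg <- sim_config(design = tiny_design(), n_chromosomes = 1,
                    snps_per_chromosome = 100, chromosome_length = 2e5,
                    block_width = 5e4, seed = 10)
  sim <- simulate_er_experiment(cfg)
  by_block <- split(sim$founder$p0, sim$founder$unit)
  expect_true(all(vapply(by_block, function(x) length(unique(x)) == 1L,
                         TRUE)))
  expect_lt(length(by_block), 100)
})

test_that("a fixed seed reproduces every emitted file byte-for-byte", {
  run <- function() {
    cfg <- sim_config(design = tiny_design(), n_chromosomes = 1,
                      snps_per_chromosome = 25, chromosome_length = 1e5,
                      selected_loci = tibble::tibble(
                        locus = 3, s_ambient = 0.5, s_hot = 0.5),
                      seed = 99)
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    paths <- simulate_er_files(simulate_er_experiment(cfg), dir)
    lapply(unlist(paths), readLines)
  }
  expect_identical(run(), run())
})

test_that("truth table carries the expected classification", {
  cfg <- sim_config(
    design = tiny_design(), n_chromosomes = 1, snps_per_chromosome = 30,
    chromosome_length = 1e5,
    selected_loci = tibble::tibble(
      locus = c(1, 5, 10, 15, 20),
      s_ambient = c(0, 0.5, 0.5, 0.5, 0),
      s_hot = c(0, 0.5, -0.5, 0, 0.5)),
    seed = 12)
  sim <- simulate_er_experiment(cfg)
  expect_equal(sim$truth$expected_class,
               c("background", "global_adaptation",
                 "antagonistic_pleiotropy", "conditional_ambient",
                 "conditional_hot"))
  expect_error(
    sim_config(design = tiny_design(), n_chromosomes = 1,
               snps_per_chromosome = 10, chromosome_length = 1e5,
               selected_loci = tibble::tibble(locus = 11, s_ambient = 0.5,
                                              s_hot = 0)),
    "out of range")
})
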