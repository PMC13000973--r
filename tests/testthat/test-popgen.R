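test_that("site_pi applies the unbiased biallelic form", {
  expect_equal(site_pi(0, 20), 0)
  expect_equal(site_pi(0.5, 20), 0.5 * 20 / 19)
  expect_equal(site_pi(0.5, 1e9), 0.5, tolerance = 1e-8)
  expect_error(site_pi(0.5, 1), "sample size")
})

test_that("watterson_theta divides by the harmonic number", {
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(5, 10), 5 / sum(1 / 1:9))
  expect_equal(watterson_theta(5, 10), 1.7674, tolerance = 1e-4)
  expect_equal(watterson_theta(7, 2), 7)   # a1 = 1
  expect_error(watterson_theta(-1, 10), "S")
})

test_that("tajimas_d matches an independent constants computation", {
  # balanced case: numerator exactly zero
  a1 <- sum(1 / 1:9)
  expect_equal(tajimas_d(5 / a1, 5, 10), 0)
  expect_true(is.na(tajimas_d(1, 1, 10)))

  # toy (n = 10, S = 5, pi = 2.0) against Tajima's constants written out
  # independently below
  n <- 10; S <- 5; pi_sum <- 2
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  expected <- (pi_sum - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  expect_equal(tajimas_d(2, 5, 10), expected)
  # excess of rare variants (pi below theta_w) gives a negative D
  expect_lt(tajimas_d(1, 5, 10), 0)
})

test_that("expected heterozygosity is the mean corrected site diversity", {
  expect_equal(expected_het(rep(0, 10), 50), 0)
  expect_equal(expected_het(0.5, 1e9), 0.5, tolerance = 1e-8)
  expect_error(expected_het(numeric(0), 50), "no SNP")
  # uniform(0.1, 0.9) founder spectrum reproduces He ~ 0.39 at large n
  p <- draw_founder_spectrum(2e4, seed = 3)
  expect_equal(expected_het(p, 2000), 0.39, tolerance = 0.02)
})

test_that("Hudson per-SNP estimator matches hand evaluations", {
  fixed <- hudson_fst_snp(1, 0, 40, 40)
  expect_equal(fixed$ratio, 1)
  eq <- hudson_fst_snp(0.5, 0.5, 40, 40)
  expect_equal(eq$numerator, -2 * 0.25 / 39)
  expect_lt(eq$ratio, 0)
  ex <- hudson_fst_snp(0.9, 0.1, 40, 40)
  expect_equal(ex$numerator, 0.64 - 2 * 0.09 / 39)
  expect_equal(ex$denominator, 0.82)
  expect_equal(ex$ratio, 0.775, tolerance = 1e-3)
  expect_error(hudson_fst_snp(0.5, 0.5, 1, 40), "sample sizes")
})

test_that("genome-wide FST is symmetric and allele-label invariant", {
  withr::with_seed(8, {
    p1 <- runif(200); p2 <- runif(200)
    a <- hudson_fst_snp(p1, p2, 50, 44)
    b <- hudson_fst_snp(p2, p1, 44, 50)
    expect_equal(genome_fst(a$numerator, a$denominator),
                 genome_fst(b$numerator, b$denominator))
    flipped <- hudson_fst_snp(1 - p1, 1 - p2, 50, 44)
    expect_equal(genome_fst(flipped$numerator, flipped$denominator),
                 genome_fst(a$numerator, a$denominator))
  })
  # a SNP fixed in both pools contributes nothing
  z <- hudson_fst_snp(c(1, 0.3), c(1, 0.6), 40, 40)
  expect_equal(genome_fst(z$numerator, z$denominator),
               z$numerator[2] / z$denominator[2])
})

test_that("windowed diversity follows the valid-snps averaging policy", {
  cfg <- sim_config(design = tiny_design(), n_chromosomes = 1,
                    snps_per_chromosome = 200, chromosome_length = 2e5,
                    seed = 13)
  fr <- sites_to_frequencies(simulate_er_experiment(cfg)$sync,
                             ancestral = "G1")
  des <- tiny_design()
  w_big <- window_diversity(fr, des, window_width = 2e5)
  w_small <- window_diversity(fr, des, window_width = 1e5)
  expect_true(all(w_big$pi >= 0) && all(w_big$theta_w >= 0))
  expect_true(all(is.na(w_big$tajimas_d) | is.finite(w_big$tajimas_d)))
  # splitting a window and recombining by valid-SNP weights reproduces it
  combined <- w_small |>
    dplyr::group_by(pool_id, chrom) |>
    dplyr::summarise(pi = sum(pi * S) / sum(S), S = sum(S),
                     .groups = "drop")
  merged <- dplyr::inner_join(combined,
                              w_big[, c("pool_id", "chrom", "pi", "S")],
                              by = c("pool_id", "chrom"))
  expect_equal(merged$pi.x, merged$pi.y)
  expect_equal(merged$S.x, merged$S.y)

  # all-sites denominator: summed site diversity per bp of window
  w_all <- window_diversity(fr, des, window_width = 2e5,
                            denominator = "width")
  expect_equal(w_all$pi, w_big$pi * w_big$S / 2e5)
})

test_that("PCA matches an eigendecomposition and flags degeneracy", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4,
                0.5, 0.1, 0.9, 0.2,
                0.3, 0.8, 0.2, 0.6), nrow = 3, byrow = TRUE)
  rownames(m) <- c("p1", "p2", "p3")
  pc <- allele_freq_pca(m)
  centred <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(centred %*% t(centred) / (nrow(m) - 1))
  expect_equal(pc$var_frac[1:2], ev$values[1:2] / sum(ev$values),
               tolerance = 1e-8)
  expect_equal(abs(pc$scores$PC1),
               abs(as.numeric(centred %*% svd(centred)$v[, 1])),
               tolerance = 1e-8)

  same <- matrix(0.4, nrow = 3, ncol = 5)
  pc0 <- allele_freq_pca(same)
  expect_true(pc0$degenerate)
  expect_equal(pc0$var_frac, rep(0, length(pc0$var_frac)))
  expect_true(all(abs(pc0$scores$PC1) < 1e-12))

  two <- matrix(c(0.1, 0.2, 0.3, 0.8, 0.7, 0.9), nrow = 2, byrow = TRUE)
  pc2 <- allele_freq_pca(two)
  expect_equal(pc2$var_frac[1], 1)
})

test_that("bootstrap CI is a percentile interval containing the mean", {
  expect_equal(bootstrap_ci(rep(0.2, 10), n_boot = 200, seed = 1)$low, 0.2)
  expect_equal(bootstrap_ci(rep(0.2, 10), n_boot = 200, seed = 1)$high, 0.2)
  withr::with_seed(2, {
    x <- rnorm(30, mean = 5)
    ci <- bootstrap_ci(x, n_boot = 2000, seed = 3)
    expect_lt(ci$low, mean(x))
    expect_gt(ci$high, mean(x))
    # independent resampling oracle
    ref <- withr::with_seed(99, {
      means <- replicate(1e4, mean(sample(x, replace = TRUE)))
      quantile(means, c(0.025, 0.975))
    })
    expect_equal(ci$low, unname(ref[1]), tolerance = 0.05)
    expect_equal(ci$high, unname(ref[2]), tolerance = 0.05)
  })
  expect_error(bootstrap_ci(1), "at least 2")
  expect_error(bootstrap_ci(c(1, 2), n_boot = 10), "n_boot")
})
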