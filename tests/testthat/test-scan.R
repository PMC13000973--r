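test_that("delta_af is a checked signed difference", {
  expect_equal(delta_af(0.7, 0.7), 0)
  expect_equal(delta_af(1, 0), 1)
  expect_equal(delta_af(0.62, 0.30), 0.32)
  expect_error(delta_af(1.3, 0.5), "final_freq")
})

test_that("classify_snp implements the four-class scheme", {
  thr <- 0.345
  expect_equal(classify_snp(0.40, 0.40, thr, thr), "global_adaptation")
  expect_equal(classify_snp(0.40, -0.40, thr, thr),
               "antagonistic_pleiotropy")
  expect_equal(classify_snp(0.10, -0.05, thr, thr), "background")
  expect_equal(classify_snp(0.40, 0.05, thr, thr), "conditional_ambient")
  expect_equal(classify_snp(0.05, -0.40, thr, thr), "conditional_hot")
  expect_error(classify_snp(0.1, 0.1, 1.5, thr), "thr_ambient")
})

test_that("classification is symmetric under swapping the regimes", {
  withr::with_seed(21, {
    daf_a <- runif(500, -1, 1)
    daf_h <- runif(500, -1, 1)
    orig <- classify_snp(daf_a, daf_h, 0.3, 0.4)
    swap <- classify_snp(daf_h, daf_a, 0.4, 0.3)
    map <- c(background = "background",
             global_adaptation = "global_adaptation",
             antagonistic_pleiotropy = "antagonistic_pleiotropy",
             conditional_ambient = "conditional_hot",
             conditional_hot = "conditional_ambient")
    expect_equal(swap, unname(map[orig]))
  })
})

test_that("concordance filter applies the three steps in order", {
  daf <- rbind(c(0.4, -0.4),   # direction
               c(0.4, 0.4),    # fst (one replicate below)
               c(0.4, 0.2),    # daf
               c(0.4, 0.4))    # pass
  fst <- rbind(c(0.5, 0.5),
               c(0.5, 0.1),
               c(0.5, 0.5),
               c(0.5, 0.5))
  out <- concordance_filter(daf, fst, daf_thresholds = 0.3,
                            fst_thresholds = 0.2)
  expect_equal(out$reason, c("direction", "fst", "daf", NA))
  expect_equal(out$pass, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(concordance_filter(matrix(0.4), matrix(0.5), 0.3, 0.2),
               "2 replicates")
})

test_that("the concordance pass-set shrinks as thresholds grow", {
  withr::with_seed(22, {
    daf <- matrix(runif(400, -1, 1), ncol = 2)
    fst <- matrix(runif(400, 0, 1), ncol = 2)
    passes <- vapply(seq(0, 1, by = 0.2), function(thr) {
      sum(concordance_filter(daf, fst, thr, thr)$pass)
    }, 0L)
    expect_true(all(diff(passes) <= 0))
  })
})

test_that("CMH statistic matches hand evaluation and mantelhaen.test", {
  # two identical no-change strata: continuity floor gives exactly 0
  no_change <- cmh_test(g1_minor = matrix(c(10, 10), 1),
                        g1_depth = matrix(c(20, 20), 1),
                        ev_minor = matrix(c(10, 10), 1),
                        ev_depth = matrix(c(20, 20), 1))
  expect_equal(no_change$statistic, 0)
  expect_equal(no_change$p, 1)

  # single stratum (20,0,0,20)
  one <- cmh_from_tables(array(c(20, 0, 0, 20), dim = c(2, 2, 1)))
  expect_equal(one$statistic, 9.5^2 / (20 * 20 * 20 * 20 / (40^2 * 39)),
               tolerance = 1e-12)
  expect_equal(one$statistic, 35.2, tolerance = 1e-2)
  expect_lt(one$p, 1e-8)

  # random strata against stats::mantelhaen.test (continuity corrected)
  withr::with_seed(23, {
    for (rep in 1:10) {
      tbl <- array(rpois(8, 30) + 1, dim = c(2, 2, 2))
      mine <- cmh_from_tables(tbl)
      ref <- stats::mantelhaen.test(tbl, correct = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic),
                   tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("drift adjustment vanishes at huge Ne and handles bad strata", {
  tbl <- array(c(25, 15, 12, 30, 18, 20, 22, 19), dim = c(2, 2, 2))
  classic <- cmh_from_tables(tbl)
  huge_ne <- cmh_from_tables(tbl, ne_trajectory = rep(1e12, 6),
                             drift_adjust = TRUE)
  expect_equal(huge_ne$statistic, classic$statistic, tolerance = 1e-9)

  # drift inflation strictly reduces the statistic
  adj <- cmh_from_tables(tbl, ne_trajectory = rep(50, 6),
                         drift_adjust = TRUE)
  expect_lt(adj$statistic, classic$statistic)

  # no usable stratum at all: NA with a warning
  expect_warning(dropped <- cmh_from_tables(array(0, dim = c(2, 2, 2))),
                 "usable")
  expect_true(is.na(dropped$statistic))
  # an all-zero stratum is silently dropped when another remains
  one_ok <- array(c(tbl[, , 1], 0, 0, 0, 0), dim = c(2, 2, 2))
  both <- cmh_from_tables(one_ok)
  expect_equal(both$n_strata, 1L)
  expect_equal(both$statistic,
               cmh_from_tables(tbl[, , 1, drop = FALSE])$statistic)
})

test_that("bh_fdr reproduces the step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.0533, 0.8), tolerance = 1e-3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  withr::with_seed(24, {
    p <- runif(100)
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "p")
})

test_that("scan_selection agrees with the matrix concordance filter", {
  cfg <- sim_config(design = one_treatment_design(ne = 50),
                    n_chromosomes = 1, snps_per_chromosome = 150,
                    chromosome_length = 5e5, depth_mean = 100, seed = 25)
  des <- cfg$design
  fr <- sites_to_frequencies(simulate_er_experiment(cfg)$sync,
                             ancestral = "G1")
  thr <- calibrate_thresholds(des, n_snps = 3000, seed = 26)
  sc <- scan_selection(fr, des, thr)

  sh <- allele_shifts(fr, des) |> dplyr::arrange(chrom, pos, replicate)
  daf <- matrix(sh$daf, ncol = 2, byrow = TRUE)
  fst <- matrix(sh$fst, ncol = 2, byrow = TRUE)
  thr_by_pool <- thr[match(c("repA", "repB"), thr$pool_id), ]
  ref <- concordance_filter(daf, fst, thr_by_pool$daf_effective,
                            thr_by_pool$fst_effective)
  tests <- dplyr::arrange(sc$tests, chrom, pos)
  expect_equal(tests$filter_pass, ref$pass)
  expect_equal(tests$filter_reason, ref$reason)
  # q is the BH adjustment of p within the treatment
  expect_equal(tests$q, bh_fdr(tests$p))
})

test_that("classification requires replicate concordance under 'both'", {
  des <- tiny_design()
  thr <- tibble::tibble(pool_id = c("aA", "aB", "hA", "hB"),
                        daf_effective = 0.3, fst_effective = 0.2)
  shifts <- tibble::tibble(
    chrom = "A01", pos = rep(c(1L, 2L), each = 4),
    pool_id = rep(c("aA", "aB", "hA", "hB"), 2),
    temperature = rep(c("ambient", "ambient", "hot", "hot"), 2),
    pollination = "bumblebee",
    replicate = rep(c("A", "B", "A", "B"), 2),
    g1_freq = 0.5, freq = 0.5,
    # pos 1: concordant above in both regimes, same sign -> global
    # pos 2: ambient replicates disagree in direction -> not "above"
    daf = c(0.4, 0.5, 0.4, 0.45, 0.4, -0.4, 0.4, 0.45),
    fst_num = 0.1, fst_den = 0.5, fst = 0.2)
  cls <- classify_shifts(shifts, thr, rule = "both")
  expect_equal(cls$class[cls$pos == 1], "global_adaptation")
  expect_equal(cls$class[cls$pos == 2], "conditional_hot")
})
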