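#' Analytic variance of allele-frequency change under drift
#'
#' For a neutral locus with ancestral frequency `p0` drifting through
#' per-generation effective sizes `Ne_1 ... Ne_t`, the variance of the final
#' frequency is
#' `Var(p_t) = p0 (1 - p0) * (1 - prod_g (1 - 1 / (2 Ne_g)))`.
#' Each factor describes one generation of binomial sampling; multiplying
#' them chains drift across generations. An empty trajectory returns 0.
#'
#' @param p0 Ancestral allele frequency (vectorised).
#' @param ne_trajectory Integer vector of per-generation effective sizes.
#' @return Variance of `p_t` around `p0`.
#' @export
drift_variance <- function(p0, ne_trajectory) {
  check_range(p0, 0, 1, "p0")
  p0 * (1 - p0) * drift_attenuation(ne_trajectory)
}

#' @rdname drift_variance
#' @details `drift_attenuation()` returns the shared factor
#'   `d = 1 - prod_g (1 - 1/(2 Ne_g))`, the fraction of heterozygosity
#'   converted to between-replicate variance after `t` generations.
#' @export
drift_attenuation <- function(ne_trajectory) {
  if (length(ne_trajectory) == 0L) return(0)
  if (any(ne_trajectory < 1)) abort("every Ne_g must be >= 1")
  1 - prod(1 - 1 / (2 * ne_trajectory))
}

#' Simulate the neutral null distribution of |dAF| and FST
#'
#' Draws founder frequencies from a surrogate spectrum, propagates each SNP
#' through the Wright-Fisher step with `s = 0` for the full `ne_trajectory`,
#' and records the absolute allele-frequency change and the per-SNP Hudson
#' FST of the final against the initial state. In `"drift"` mode the true
#' population frequencies are compared (the analytic formula's setting); in
#' `"drift_sampling"` mode both endpoints additionally pass through pool
#' sampling and Poisson read depth.
#'
#' @param ne_trajectory Per-generation effective sizes.
#' @param n_snps Number of neutral SNPs to simulate (default 1e5).
#' @param founder Founder spectrum as in [sim_config()].
#' @param mode `"drift"` (default) or `"drift_sampling"`.
#' @param n_individuals Pool size used for the FST sample-size correction
#'   (haploid size `2 * n_individuals`) and, in sampling mode, the evolved
#'   pool sampling.
#' @param n_ancestral Ancestral pool size; defaults to `n_individuals`.
#' @param depth_mean,error_rate Read model for `"drift_sampling"` mode.
#' @param seed Optional seed.
#' @param pop_id Optional label carried into the result.
#'
#' @return A `driftscan_null` object with numeric samples `$daf` and `$fst`.
#' @export
simulate_neutral_null <- function(ne_trajectory, n_snps = 1e5,
                                  founder = list(dist = "uniform",
                                                 maf_min = 0.1),
                                  mode = c("drift", "drift_sampling"),
                                  n_individuals = 25, n_ancestral = NULL,
                                  depth_mean = 120, error_rate = 0,
                                  seed = NULL, pop_id = NULL) {
  mode <- match.arg(mode)
  if (n_snps < 1) abort("n_snps must be >= 1")
  n_ancestral <- n_ancestral %||% n_individuals
  with_seed_if(seed, {
    p0 <- draw_founder_spectrum(n_snps, founder)
    p <- p0
    for (ne_g in ne_trajectory) p <- wf_step(p, ne_g, 0)
    if (mode == "drift_sampling") {
      anc <- pool_read_counts(p0, n_ancestral, depth_mean, error_rate)
      evo <- pool_read_counts(p, n_individuals, depth_mean, error_rate)
      p0_obs <- ifelse(anc$depth > 0, anc$count / anc$depth, NA_real_)
      p_obs <- ifelse(evo$depth > 0, evo$count / evo$depth, NA_real_)
    } else {
      p0_obs <- p0
      p_obs <- p
    }
    fst <- hudson_fst_snp(p0_obs, p_obs, 2 * n_ancestral, 2 * n_individuals)
    structure(
      list(pop_id = pop_id, mode = mode, daf = abs(p_obs - p0_obs),
           fst = fst$ratio, ne_trajectory = ne_trajectory,
           n_snps = n_snps, seed = seed),
      class = "driftscan_null"
    )
  })
}

#' Empirical quantile of a neutral null distribution
#'
#' Uses the type-7 (linear interpolation) quantile convention.
#'
#' @param null A `driftscan_null` object, or a numeric sample vector.
#' @param q Probability level (default 0.95).
#' @param measure `"daf"` or `"fst"` when `null` is a `driftscan_null`.
#' @return The empirical quantile.
#' @export
neutral_quantile <- function(null, q = 0.95, measure = c("daf", "fst")) {
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)")
  x <- if (inherits(null, "driftscan_null")) {
    null[[match.arg(measure)]]
  } else {
    null
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("empty null distribution")
  unname(quantile(x, q, type = 7))
}

#' Empirical control baseline for |dAF|
#'
#' The 95th percentile of observed absolute allele-frequency change pooled
#' across the control (hand-pollinated) replicates of a temperature regime:
#' the background genomic change a treatment must exceed over and above the
#' drift expectation.
#'
#' @param control_daf Numeric vector of |dAF| samples from the control pools.
#' @param q Probability level (default 0.95).
#' @return The empirical quantile.
#' @export
control_baseline <- function(control_daf, q = 0.95) {
  control_daf <- control_daf[is.finite(control_daf)]
  if (length(control_daf) == 0L) abort("no control |dAF| samples supplied")
  check_range(control_daf, 0, 1, "control_daf")
  neutral_quantile(control_daf, q)
}

#' Effective threshold: the larger of the neutral and control bounds
#'
#' @param neutral Neutral-simulation 95th percentile.
#' @param control Control-baseline 95th percentile (may be `NA` when no
#'   control pools exist, in which case the neutral bound is used).
#' @return One-row tibble with `threshold` and `source`
#'   (`"neutral"`, `"control"` or `"tie"`).
#' @export
effective_threshold <- function(neutral, control) {
  if (!is.finite(neutral) || neutral < 0) abort("neutral bound must be >= 0")
  if (is.na(control)) {
    return(tibble::tibble(threshold = neutral, source = "neutral"))
  }
  if (control < 0) abort("control bound must be >= 0")
  tibble::tibble(
    threshold = max(neutral, control),
    source = dplyr::case_when(neutral > control ~ "neutral",
                              control > neutral ~ "control",
                              TRUE ~ "tie")
  )
}

#' Calibrate per-population significance thresholds
#'
#' For every evolved pool, simulates its neutral null (from the pool's `ne`
#' trajectory), takes 95th percentiles of |dAF| and per-SNP Hudson FST, adds
#' the empirical control baseline of the matching temperature regime when
#' control pools and observed frequencies are available, and records the
#' effective |dAF| threshold (the larger bound) with its provenance.
#'
#' @param design Design tibble.
#' @param freqs Optional frequency tibble from [sites_to_frequencies()],
#'   used to compute the empirical control baselines.
#' @param n_snps Neutral SNPs per pool (default 1e5).
#' @param q Quantile level (default 0.95).
#' @param mode,founder,depth_mean,error_rate Passed to
#'   [simulate_neutral_null()].
#' @param seed Optional base seed; pool `i` uses `seed + i`.
#'
#' @return A tibble with one row per evolved pool: `pool_id`,
#'   `daf95_neutral`, `fst95_neutral`, `daf95_control`, `daf_effective`,
#'   `daf_source`, `fst_effective`.
#' @export
calibrate_thresholds <- function(design, freqs = NULL, n_snps = 1e5,
                                 q = 0.95,
                                 mode = c("drift", "drift_sampling"),
                                 founder = list(dist = "uniform",
                                                maf_min = 0.1),
                                 depth_mean = 120, error_rate = 0,
                                 seed = NULL) {
  mode <- match.arg(mode)
  validate_design(design)
  anc_id <- ancestral_pool(design)
  anc_n <- design$n_individuals[design$pool_id == anc_id]
  evolved <- dplyr::filter(design, !is.na(.data$pollination))

  control_q <- NULL
  if (!is.null(freqs) && any(evolved$pollination == "control")) {
    shifts <- allele_shifts(freqs, design)
    control_q <- shifts |>
      dplyr::filter(.data$pollination == "control") |>
      dplyr::group_by(.data$temperature) |>
      dplyr::summarise(daf95_control = control_baseline(abs(.data$daf), q),
                       .groups = "drop")
  }

  rows <- purrr::map(seq_len(nrow(evolved)), function(i) {
    pool <- evolved[i, ]
    null <- simulate_neutral_null(
      pool$ne[[1]], n_snps = n_snps, founder = founder, mode = mode,
      n_individuals = pool$n_individuals, n_ancestral = anc_n,
      depth_mean = depth_mean, error_rate = error_rate,
      seed = if (is.null(seed)) NULL else seed + i, pop_id = pool$pool_id
    )
    ctrl <- NA_real_
    if (!is.null(control_q) && pool$pollination != "control" &&
        pool$temperature %in% control_q$temperature) {
      ctrl <- control_q$daf95_control[
        control_q$temperature == pool$temperature]
    }
    daf95 <- neutral_quantile(null, q, "daf")
    fst95 <- neutral_quantile(null, q, "fst")
    eff <- effective_threshold(daf95, ctrl)
    tibble::tibble(
      pool_id = pool$pool_id,
      temperature = pool$temperature,
      pollination = pool$pollination,
      replicate = pool$replicate,
      daf95_neutral = daf95,
      fst95_neutral = fst95,
      daf95_control = ctrl,
      daf_effective = eff$threshold,
      daf_source = eff$source,
      fst_effective = fst95
    )
  })
  dplyr::bind_rows(rows)
}
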