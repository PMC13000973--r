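#' Signed allele-frequency change
#'
#' `delta_af = af_final - af_ancestral` for the same polarised allele.
#'
#' @param final_freq,g1_freq Frequencies in `[0, 1]` of the same allele.
#' @return Signed difference in `[-1, 1]`.
#' @export
delta_af <- function(final_freq, g1_freq) {
  check_range(final_freq, 0, 1, "final_freq")
  check_range(g1_freq, 0, 1, "g1_freq")
  final_freq - g1_freq
}

#' Per-SNP allele-frequency shifts and FST against the ancestral pool
#'
#' For every evolved pool, computes the signed frequency change of the
#' polarised minor allele relative to the ancestral pool and the per-SNP
#' Hudson FST (with haploid pool sizes from the design).
#'
#' @param freqs Frequency tibble from [sites_to_frequencies()].
#' @param design Design tibble.
#' @return Tibble with one row per SNP per evolved pool: design columns,
#'   `g1_freq`, `freq`, `daf`, `fst_num`, `fst_den`, `fst`.
#' @export
allele_shifts <- function(freqs, design) {
  validate_design(design)
  anc_id <- ancestral_pool(design)
  anc_n <- design$n_individuals[design$pool_id == anc_id]
  g1 <- freqs |>
    dplyr::filter(.data$pool_id == anc_id) |>
    dplyr::select("chrom", "pos", g1_freq = "freq")
  out <- freqs |>
    dplyr::filter(.data$pool_id != anc_id) |>
    dplyr::inner_join(g1, by = c("chrom", "pos")) |>
    dplyr::inner_join(
      design[, c("pool_id", "temperature", "pollination", "replicate",
                 "n_individuals")],
      by = "pool_id")
  comp <- hudson_fst_snp(out$g1_freq, out$freq, 2 * anc_n,
                         2 * out$n_individuals)
  out |>
    dplyr::mutate(daf = delta_af(.data$freq, .data$g1_freq),
                  fst_num = comp$numerator, fst_den = comp$denominator,
                  fst = comp$ratio) |>
    dplyr::select("chrom", "pos", "pool_id", "temperature", "pollination",
                  "replicate", "g1_freq", "freq", "daf", "fst_num",
                  "fst_den", "fst")
}

#' Four-class temperature-by-regime classification of a SNP
#'
#' Given regime-level frequency shifts in the two temperature regimes and
#' the calibrated thresholds, assigns each SNP to one of: `background`
#' (below threshold in both), `global_adaptation` (above in both, same
#' sign), `conditional_ambient` / `conditional_hot` (above in exactly one),
#' or `antagonistic_pleiotropy` (above in both, opposite signs).
#'
#' @param daf_ambient,daf_hot Regime-level signed shifts (vectorised).
#' @param thr_ambient,thr_hot Calibrated |dAF| thresholds in `[0, 1]`.
#' @return Character vector of class labels.
#' @export
classify_snp <- function(daf_ambient, daf_hot, thr_ambient, thr_hot) {
  check_range(thr_ambient, 0, 1, "thr_ambient")
  check_range(thr_hot, 0, 1, "thr_hot")
  above_a <- abs(daf_ambient) >= thr_ambient
  above_h <- abs(daf_hot) >= thr_hot
  class_from_flags(above_a, above_h, sign(daf_ambient), sign(daf_hot))
}

class_from_flags <- function(above_a, above_h, sign_a, sign_h) {
  dplyr::case_when(
    !above_a & !above_h ~ "background",
    above_a & !above_h ~ "conditional_ambient",
    !above_a & above_h ~ "conditional_hot",
    sign_a == sign_h ~ "global_adaptation",
    TRUE ~ "antagonistic_pleiotropy"
  )
}

#' Three-step replicate-concordance filter
#'
#' A SNP passes for a treatment only when (1) all replicate shifts share one
#' direction, (2) every replicate's |dAF| exceeds its population's effective
#' threshold, and (3) every replicate's per-SNP FST exceeds its population's
#' neutral 95th percentile. The first failed step is reported as the reason.
#'
#' @param daf Matrix of signed shifts, SNPs by replicates (>= 2 columns).
#' @param fst Matrix of per-SNP Hudson FST, same shape.
#' @param daf_thresholds Effective |dAF| threshold per replicate pool
#'   (length 1 or `ncol(daf)`).
#' @param fst_thresholds Neutral FST 95th percentile per replicate pool.
#' @return Tibble with logical `pass` and `reason`
#'   (`"direction"`, `"daf"`, `"fst"`, or `NA` when passing).
#' @export
concordance_filter <- function(daf, fst, daf_thresholds, fst_thresholds) {
  daf <- as.matrix(daf)
  fst <- as.matrix(fst)
  if (ncol(daf) < 2L) abort("concordance requires >= 2 replicates")
  stopifnot(all(dim(daf) == dim(fst)))
  daf_thresholds <- rep_len(daf_thresholds, ncol(daf))
  fst_thresholds <- rep_len(fst_thresholds, ncol(daf))
  same_dir <- rowSums(daf > 0) == ncol(daf) | rowSums(daf < 0) == ncol(daf)
  daf_ok <- rowSums(sweep(abs(daf), 2, daf_thresholds, `>=`)) == ncol(daf)
  fst_ok <- rowSums(sweep(fst, 2, fst_thresholds, `>`)) == ncol(fst)
  fst_ok[is.na(fst_ok)] <- FALSE
  reason <- dplyr::case_when(
    !same_dir ~ "direction",
    !daf_ok ~ "daf",
    !fst_ok ~ "fst",
    TRUE ~ NA_character_
  )
  tibble::tibble(pass = is.na(reason), reason = reason)
}

#' Replicated Cochran-Mantel-Haenszel test with drift-inflated variance
#'
#' Stratified 2x2 association test of ancestral-versus-evolved allele counts
#' with one stratum per replicate:
#' `statistic = (max(|sum_r (a_r - E_r)| - 1/2, 0))^2 / V`, with `E_r` and
#' the classic `V_r` the stratum hypergeometric mean and variance, compared
#' against a chi-square with 1 df. With `drift_adjust = TRUE` each stratum
#' variance is inflated by the extra count-space variance of the
#' experiment's noise that read counts cannot see: drift over the `ne`
#' trajectory (attenuation `d`, see [drift_attenuation()]) and, when pool
#' sizes are supplied, the binomial sampling of pool individuals. With
#' `g1_shared = TRUE` a cross-stratum covariance accounts for the ancestral
#' pool having been sequenced once and duplicated across replicates. With
#' the defaults (no pool sizes, `g1_shared = FALSE`) the statistic reduces
#' exactly to the classic continuity-corrected CMH test when `d = 0`.
#'
#' @param g1_minor,g1_depth Matrices (SNPs by replicates) of ancestral-pool
#'   minor-allele read counts and total biallelic depths; vectors are
#'   treated as single-SNP rows.
#' @param ev_minor,ev_depth Same for the evolved pools.
#' @param ne_trajectory Per-generation effective sizes (used when
#'   `drift_adjust = TRUE`).
#' @param drift_adjust Inflate the stratum variance for drift (and pool
#'   sampling when pool sizes are given)?
#' @param n_pool,n_ancestral Optional pool sizes (individuals) of the
#'   evolved pools (scalar or per-replicate) and the ancestral pool, adding
#'   `1/(2 n)` terms to the variance inflation.
#' @param g1_shared Add the covariance between strata induced by the
#'   duplicated ancestral counts?
#' @param continuity Apply the 1/2 continuity correction (default `TRUE`)?
#'
#' @return Tibble with `statistic`, `p` and `n_strata` per SNP.
#' @export
cmh_test <- function(g1_minor, g1_depth, ev_minor, ev_depth,
                     ne_trajectory = NULL, drift_adjust = FALSE,
                     n_pool = NULL, n_ancestral = NULL,
                     g1_shared = FALSE, continuity = TRUE) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  a_m <- as_mat(g1_minor)
  d1_m <- as_mat(g1_depth)
  b_m <- as_mat(ev_minor)
  d2_m <- as_mat(ev_depth)
  stopifnot(all(dim(a_m) == dim(d1_m)), all(dim(a_m) == dim(b_m)),
            all(dim(a_m) == dim(d2_m)))
  if (any(c(a_m, b_m) < 0, na.rm = TRUE)) abort("counts must be non-negative")
  R <- ncol(a_m)
  n_snp <- nrow(a_m)
  d <- if (drift_adjust && !is.null(ne_trajectory)) {
    drift_attenuation(ne_trajectory)
  } else 0
  n_pool <- if (is.null(n_pool)) rep(NA_real_, R) else rep_len(n_pool, R)

  num <- matrix(0, n_snp, R)
  V <- matrix(0, n_snp, R)
  w <- matrix(0, n_snp, R)
  usable <- matrix(FALSE, n_snp, R)
  pbar_num <- 0
  pbar_den <- 0
  for (r in seq_len(R)) {
    a <- a_m[, r]; D1 <- d1_m[, r]; b <- b_m[, r]; D2 <- d2_m[, r]
    N <- D1 + D2
    ok <- is.finite(N) & N >= 2 & D1 > 0 & D2 > 0
    col1 <- a + b
    E <- D1 * col1 / N
    wr <- D1 * D2 / N
    Vr <- D1 * D2 * col1 * (N - col1) / (N^2 * (N - 1))
    if (drift_adjust) {
      pt <- col1 / N
      cw <- d +
        (if (!is.na(n_pool[r])) 1 / (2 * n_pool[r]) else 0) +
        (if (!is.null(n_ancestral)) 1 / (2 * n_ancestral) else 0)
      Vr <- Vr + wr^2 * pt * (1 - pt) * cw
    }
    num[, r] <- ifelse(ok, a - E, 0)
    V[, r] <- ifelse(ok, Vr, 0)
    w[, r] <- ifelse(ok, wr, 0)
    usable[, r] <- ok
    pbar_num <- pbar_num + ifelse(ok, col1, 0)
    pbar_den <- pbar_den + ifelse(ok, N, 0)
  }
  n_strata <- rowSums(usable)
  if (any(n_strata == 0L)) {
    warn(sprintf("%d SNP(s) had no usable stratum; returning NA",
                 sum(n_strata == 0L)))
  }
  tot_num <- rowSums(num)
  tot_V <- rowSums(V)
  if (drift_adjust && g1_shared && R >= 2L) {
    pbar <- ifelse(pbar_den > 0, pbar_num / pbar_den, NA_real_)
    shared <- 1 / d1_m[, 1] +
      (if (!is.null(n_ancestral)) 1 / (2 * n_ancestral) else 0)
    for (r in seq_len(R - 1L)) {
      for (r2 in seq((r + 1L), R)) {
        tot_V <- tot_V +
          2 * w[, r] * w[, r2] * pbar * (1 - pbar) * shared
      }
    }
  }
  cc <- if (continuity) 0.5 else 0
  stat <- pmax(abs(tot_num) - cc, 0)^2 / tot_V
  stat[n_strata == 0L | tot_V <= 0] <- NA_real_
  tibble::tibble(statistic = stat,
                 p = pchisq(stat, df = 1, lower.tail = FALSE),
                 n_strata = n_strata)
}

#' CMH test from a 2x2xK table array
#'
#' Convenience wrapper for a single SNP given per-replicate 2x2 tables with
#' rows = pools (ancestral, evolved) and columns = alleles (minor, major).
#'
#' @param tables Numeric array of dimension `c(2, 2, K)`.
#' @param ... Passed to [cmh_test()].
#' @return One-row tibble from [cmh_test()].
#' @export
cmh_from_tables <- function(tables, ...) {
  stopifnot(length(dim(tables)) == 3L, all(dim(tables)[1:2] == 2L))
  cmh_test(
    g1_minor = matrix(tables[1, 1, ], nrow = 1),
    g1_depth = matrix(tables[1, 1, ] + tables[1, 2, ], nrow = 1),
    ev_minor = matrix(tables[2, 1, ], nrow = 1),
    ev_depth = matrix(tables[2, 1, ] + tables[2, 2, ], nrow = 1),
    ...
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]); input order preserved.
#'
#' @param p P-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  check_range(p[!is.na(p)], 0, 1, "p")
  p.adjust(p, method = "BH")
}

#' Per-treatment replicated CMH scan
#'
#' Runs [cmh_test()] for every treatment (temperature by pollination) in the
#' design, with replicates as strata and the ancestral pool's read counts
#' duplicated across strata, then adjusts p-values per treatment with
#' [bh_fdr()].
#'
#' @param freqs Frequency tibble from [sites_to_frequencies()].
#' @param design Design tibble.
#' @param drift_adjust Inflate the variance for drift and pool sampling
#'   (default `TRUE`; uses each treatment's `ne` trajectory and the design's
#'   pool sizes, with the shared-ancestral covariance).
#' @return Tibble with one row per SNP per treatment: `chrom`, `pos`,
#'   `temperature`, `pollination`, `cmh_stat`, `p`, `q`, `n_strata`.
#' @export
cmh_scan <- function(freqs, design, drift_adjust = TRUE) {
  validate_design(design)
  anc_id <- ancestral_pool(design)
  anc_n <- design$n_individuals[design$pool_id == anc_id]
  g1 <- freqs |>
    dplyr::filter(.data$pool_id == anc_id) |>
    dplyr::arrange(.data$chrom, .data$pos)
  treatments <- design |>
    dplyr::filter(!is.na(.data$pollination)) |>
    dplyr::distinct(.data$temperature, .data$pollination)

  purrr::map_dfr(seq_len(nrow(treatments)), function(i) {
    tr <- treatments[i, ]
    pools <- design |>
      dplyr::filter(.data$temperature == tr$temperature,
                    .data$pollination == tr$pollination)
    ev <- freqs |>
      dplyr::filter(.data$pool_id %in% pools$pool_id) |>
      dplyr::arrange(.data$chrom, .data$pos)
    cnt <- ev |>
      dplyr::select("chrom", "pos", "pool_id", "count") |>
      tidyr::pivot_wider(names_from = "pool_id", values_from = "count")
    dep <- ev |>
      dplyr::select("chrom", "pos", "pool_id", "depth") |>
      tidyr::pivot_wider(names_from = "pool_id", values_from = "depth")
    sites <- cnt[, c("chrom", "pos")]
    g1_here <- dplyr::semi_join(g1, sites, by = c("chrom", "pos"))
    stopifnot(nrow(g1_here) == nrow(sites))
    R <- nrow(pools)
    res <- cmh_test(
      g1_minor = matrix(g1_here$count, nrow(sites), R),
      g1_depth = matrix(g1_here$depth, nrow(sites), R),
      ev_minor = as.matrix(cnt[, pools$pool_id]),
      ev_depth = as.matrix(dep[, pools$pool_id]),
      ne_trajectory = pools$ne[[1]],
      drift_adjust = drift_adjust,
      n_pool = if (drift_adjust) pools$n_individuals else NULL,
      n_ancestral = if (drift_adjust) anc_n else NULL,
      g1_shared = drift_adjust
    )
    tibble::tibble(
      chrom = sites$chrom, pos = sites$pos,
      temperature = tr$temperature, pollination = tr$pollination,
      cmh_stat = res$statistic, p = res$p, q = bh_fdr(res$p),
      n_strata = res$n_strata
    )
  })
}

#' Classify SNP shifts across temperature regimes
#'
#' Aggregates per-replicate shifts to the regime level and applies the
#' four-class scheme for each pollination regime with both temperatures
#' present. Under the default `"both"` rule a regime counts as above
#' threshold only when both of its replicates shift in the same direction
#' and each exceeds its population's effective threshold (the replicated
#' version of the scheme); under `"mean"` the replicate-mean |dAF| is simply
#' compared with the mean threshold.
#'
#' @param shifts Output of [allele_shifts()].
#' @param thresholds Output of [calibrate_thresholds()].
#' @param rule `"both"` (default) or `"mean"`.
#' @return Tibble with one row per SNP per pollination regime:
#'   `daf_ambient`, `daf_hot` (replicate means) and `class`.
#' @export
classify_shifts <- function(shifts, thresholds, rule = c("both", "mean")) {
  rule <- match.arg(rule)
  regime <- shifts |>
    dplyr::inner_join(
      thresholds[, c("pool_id", "daf_effective")], by = "pool_id") |>
    dplyr::group_by(.data$chrom, .data$pos, .data$temperature,
                    .data$pollination) |>
    dplyr::summarise(
      mean_daf = mean(.data$daf),
      above = if (rule == "both") {
        (all(.data$daf > 0) || all(.data$daf < 0)) &&
          all(abs(.data$daf) >= .data$daf_effective)
      } else {
        abs(mean(.data$daf)) >= mean(.data$daf_effective)
      },
      .groups = "drop"
    )
  both <- regime |>
    tidyr::pivot_wider(names_from = "temperature",
                       values_from = c("mean_daf", "above")) |>
    tidyr::drop_na()
  if (!all(c("mean_daf_ambient", "mean_daf_hot") %in% names(both)) ||
      nrow(both) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          pollination = character(), daf_ambient = double(),
                          daf_hot = double(), class = character()))
  }
  both |>
    dplyr::mutate(
      class = class_from_flags(.data$above_ambient, .data$above_hot,
                               sign(.data$mean_daf_ambient),
                               sign(.data$mean_daf_hot))
    ) |>
    dplyr::select("chrom", "pos", "pollination",
                  daf_ambient = "mean_daf_ambient",
                  daf_hot = "mean_daf_hot", "class")
}

#' Full per-SNP selection scan
#'
#' Combines [allele_shifts()], the three-step [concordance_filter()] per
#' treatment, the replicated [cmh_scan()] and [classify_shifts()] into one
#' result object.
#'
#' @param freqs Frequency tibble from [sites_to_frequencies()].
#' @param design Design tibble.
#' @param thresholds Threshold tibble from [calibrate_thresholds()].
#' @param drift_adjust Passed to [cmh_scan()].
#' @param class_rule Passed to [classify_shifts()].
#' @return A `driftscan_scan` list with tibbles `$shifts`, `$tests`
#'   (per treatment: CMH statistic, p, q, filter pass/reason) and
#'   `$classes`.
#' @export
scan_selection <- function(freqs, design, thresholds, drift_adjust = TRUE,
                           class_rule = "both") {
  shifts <- allele_shifts(freqs, design)
  cmh <- cmh_scan(freqs, design, drift_adjust = drift_adjust)

# vectorised equivalent of concordance_filter() applied per treatment
  # (agreement between the two is covered by tests)
  filt <- shifts |>
    dplyr::inner_join(
      thresholds[, c("pool_id", "daf_effective", "fst_effective")],
      by = "pool_id") |>
    dplyr::group_by(.data$chrom, .data$pos, .data$temperature,
                    .data$pollination) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      same_dir = all(.data$daf > 0) || all(.data$daf < 0),
      daf_ok = all(abs(.data$daf) >= .data$daf_effective),
      fst_ok = all(!is.na(.data$fst) & .data$fst > .data$fst_effective),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_reps < 2L ~ "single_replicate",
        !.data$same_dir ~ "direction",
        !.data$daf_ok ~ "daf",
        !.data$fst_ok ~ "fst",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$reason)
    ) |>
    dplyr::select("chrom", "pos", "temperature", "pollination", "pass",
                  "reason")

  tests <- dplyr::left_join(
    cmh, filt,
    by = c("chrom", "pos", "temperature", "pollination")) |>
    dplyr::rename(filter_pass = "pass", filter_reason = "reason")

  classes <- classify_shifts(shifts, thresholds, rule = class_rule)
  structure(
    list(shifts = shifts, tests = tests, classes = classes,
         thresholds = thresholds),
    class = "driftscan_scan"
  )
}

#' @export
print.driftscan_scan <- function(x, ...) {
  cat(sprintf(
    "Selection scan: %d SNPs, %d treatment(s); %d filter-pass, %d CMH q<0.05\n",
    dplyr::n_distinct(x$tests[, c("chrom", "pos")]),
    dplyr::n_distinct(x$tests[, c("temperature", "pollination")]),
    sum(x$tests$filter_pass, na.rm = TRUE),
    sum(x$tests$q < 0.05, na.rm = TRUE)))
  invisible(x)
}
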