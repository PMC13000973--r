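#' Per-site nucleotide diversity (heterozygosity)
#'
#' Unbiased biallelic form `2 p (1 - p) * n / (n - 1)`, where `n` is the
#' (haploid) sample size of the pool — here `2 * n_individuals`, not read
#' depth.
#'
#' @param p Minor-allele frequency (vectorised).
#' @param n Haploid sample size (>= 2).
#' @return Per-site diversity.
#' @export
site_pi <- function(p, n) {
  check_range(p, 0, 1, "p")
  if (any(n < 2)) abort("sample size n must be >= 2")
  2 * p * (1 - p) * n / (n - 1)
}

#' Watterson's theta for a window
#'
#' `theta_w = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S Number of segregating sites (>= 0).
#' @param n Haploid sample size (>= 2).
#' @return Watterson's estimator for the window.
#' @export
watterson_theta <- function(S, n) {
  if (any(S < 0)) abort("S must be >= 0")
  if (any(n < 2)) abort("sample size n must be >= 2")
  a1 <- vapply(n, function(nn) sum(1 / seq_len(nn - 1)), 0)
  S / a1
}

#' Tajima's D for a window
#'
#' Standardised difference between pairwise diversity and Watterson's
#' estimator using Tajima's constants. Returns `NA` (undefined, not an
#' error) when `S < 2`.
#'
#' @param pi_sum Sum of per-site pairwise diversity over the window
#'   (average number of pairwise differences).
#' @param S Number of segregating sites.
#' @param n Haploid sample size.
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajimas_d <- function(pi_sum, S, n) {
  if (n < 2) abort("sample size n must be >= 2")
  if (S < 2) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Genome-wide expected heterozygosity of a pool
#'
#' Mean over SNPs of the small-sample-corrected per-site heterozygosity
#' `1 - Q1`, with `Q1` the probability of identity-in-state within the pool:
#' `He = mean( 2 p (1-p) * n/(n-1) )`.
#'
#' @param p Minor-allele frequencies of the pool's SNPs (non-empty).
#' @param n Haploid sample size.
#' @return Scalar expected heterozygosity.
#' @export
expected_het <- function(p, n) {
  if (length(p) == 0L) abort("no SNP frequencies supplied")
  mean(site_pi(p, n))
}

#' Windowed diversity statistics per pool
#'
#' Computes, in non-overlapping windows of fixed width, the number of valid
#' SNPs `S`, mean per-SNP diversity `pi` (valid-SNPs averaging policy),
#' Watterson's `theta_w = S/a1` and Tajima's D (undefined below `S = 2`).
#' Sample size is the haploid pool size from the design.
#'
#' @param freqs Frequency tibble from [sites_to_frequencies()].
#' @param design Design tibble (for `n_individuals`).
#' @param window_width Window width in bp (default 50000).
#' @param denominator `"valid_snps"` (default) divides the summed site
#'   diversity by the number of SNPs in the window (SNP-based pi);
#'   `"width"` divides by the window width, treating every non-SNP
#'   position as zero heterozygosity — a per-site pi comparable with
#'   all-sites estimates when the windows are fully callable.
#' @return Tibble with one row per pool per non-empty window.
#' @export
window_diversity <- function(freqs, design, window_width = 5e4,
                             denominator = c("valid_snps", "width")) {
  denominator <- match.arg(denominator)
  validate_design(design)
  freqs |>
    dplyr::inner_join(design[, c("pool_id", "n_individuals")],
                      by = "pool_id") |>
    dplyr::mutate(
      win_start = ((.data$pos - 1L) %/% window_width) * window_width + 1L,
      n = 2L * .data$n_individuals
    ) |>
    dplyr::group_by(.data$pool_id, .data$chrom, .data$win_start, .data$n) |>
    dplyr::summarise(
      S = dplyr::n(),
      pi_sum = sum(site_pi(.data$freq, .data$n[1])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pi = .data$pi_sum /
        (if (denominator == "width") window_width else .data$S),
      win_end = .data$win_start + window_width - 1L,
      theta_w = watterson_theta(.data$S, .data$n),
      tajimas_d = purrr::pmap_dbl(
        list(.data$pi_sum, .data$S, .data$n), tajimas_d)
    ) |>
    dplyr::select("pool_id", "chrom", "win_start", "win_end", "S", "pi",
                  "theta_w", "tajimas_d", "n")
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples window-level values with replacement and returns the percentile
#' interval of the bootstrap distribution of the mean.
#'
#' @param x Numeric vector of window values (length >= 2).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return One-row tibble with `mean`, `low`, `high`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000, level = 0.95, seed = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) abort("need at least 2 values to bootstrap")
  if (n_boot < 100) abort("n_boot must be >= 100")
  with_seed_if(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                  ncol = n_boot)
    means <- colMeans(matrix(x[idx], ncol = n_boot))
    alpha <- (1 - level) / 2
    tibble::tibble(
      mean = mean(x),
      low = unname(quantile(means, alpha)),
      high = unname(quantile(means, 1 - alpha))
    )
  })
}
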