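#' Tidy a neutral null distribution
#'
#' @param x A `driftscan_null` object.
#' @param ... Unused.
#' @return One row per quantile of |dAF| and FST.
#' @export
tidy.driftscan_null <- function(x, ...) {
  probs <- c(0.5, 0.9, 0.95, 0.99)
  tibble::tibble(
    measure = rep(c("daf", "fst"), each = length(probs)),
    quantile = rep(probs, 2),
    value = c(quantile(x$daf, probs, na.rm = TRUE),
              quantile(x$fst, probs, na.rm = TRUE))
  )
}

#' @rdname tidy.driftscan_null
#' @export
glance.driftscan_null <- function(x, ...) {
  tibble::tibble(
    pop_id = x$pop_id %||% NA_character_, mode = x$mode,
    n_snps = x$n_snps, generations = length(x$ne_trajectory),
    daf95 = neutral_quantile(x, 0.95, "daf"),
    fst95 = neutral_quantile(x, 0.95, "fst")
  )
}

#' Tidy a local-score Gumbel fit
#'
#' @param x A `driftscan_gumbel` object.
#' @param ... Unused.
#' @export
tidy.driftscan_gumbel <- function(x, ...) {
  tibble::tibble(term = c("mu", "beta", "threshold"),
                 estimate = c(x$mu, x$beta, x$threshold))
}

#' @rdname tidy.driftscan_gumbel
#' @export
glance.driftscan_gumbel <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, alpha = x$alpha,
                 n_resample = x$n_resample, degenerate = x$degenerate)
}

#' Tidy an allele-frequency PCA
#'
#' @param x A `driftscan_pca` object.
#' @param ... Unused.
#' @return The per-pool score table.
#' @export
tidy.driftscan_pca <- function(x, ...) x$scores

#' @rdname tidy.driftscan_pca
#' @export
glance.driftscan_pca <- function(x, ...) {
  tibble::tibble(n_pools = nrow(x$scores), n_snps = x$n_snps,
                 pc1_var = x$var_frac[1],
                 pc2_var = if (length(x$var_frac) > 1) x$var_frac[2] else NA,
                 degenerate = x$degenerate)
}

#' Tidy a pipeline run
#'
#' @param x A `driftscan_pipeline` object.
#' @param ... Unused.
#' @return The per-treatment summary (Table-2-shaped counts).
#' @export
tidy.driftscan_pipeline <- function(x, ...) x$summary

#' @rdname tidy.driftscan_pipeline
#' @export
glance.driftscan_pipeline <- function(x, ...) {
  tibble::tibble(
    n_sites = dplyr::n_distinct(x$freqs[, c("chrom", "pos")]),
    n_treatments = nrow(x$summary),
    n_consensus_intervals = nrow(x$consensus)
  )
}
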