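#' Principal component analysis of pool allele frequencies
#'
#' Column-centres the pools-by-SNPs frequency matrix and decomposes it by
#' singular values. SNPs missing in any pool are dropped first. A constant
#' matrix is flagged degenerate (all variance fractions zero) rather than
#' raising an error.
#'
#' @param freqs Either a frequency tibble from [sites_to_frequencies()] or a
#'   numeric matrix with pools in rows and SNPs in columns.
#' @return A `driftscan_pca` object with `$scores` (tibble: `pool_id`,
#'   `PC1`, ...), `$var_frac` and `$degenerate`. Supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
allele_freq_pca <- function(freqs) {
  if (is.data.frame(freqs)) {
    wide <- freqs |>
      dplyr::select("chrom", "pos", "pool_id", "freq") |>
      tidyr::pivot_wider(names_from = "pool_id", values_from = "freq") |>
      tidyr::drop_na()
    m <- t(as.matrix(wide[, -(1:2)]))
  } else {
    m <- as.matrix(freqs)
    m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) abort("need >= 2 pools and >= 2 SNPs")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  degenerate <- total == 0
  var_frac <- if (degenerate) rep(0, length(pc$sdev)) else pc$sdev^2 / total
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(
    tibble::tibble(pool_id = rownames(m) %||% paste0("pool", seq_len(nrow(m)))),
    scores
  )
  structure(
    list(scores = scores, var_frac = var_frac, degenerate = degenerate,
         n_snps = ncol(m)),
    class = "driftscan_pca"
  )
}

#' @export
print.driftscan_pca <- function(x, ...) {
  cat(sprintf("Allele-frequency PCA: %d pools x %d SNPs\n",
              nrow(x$scores), x$n_snps))
  if (x$degenerate) cat("  (degenerate: no variance among pools)\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$var_frac[1],
              100 * (if (length(x$var_frac) > 1) x$var_frac[2] else 0)))
  invisible(x)
}
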