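#' Hudson's FST for a single SNP
#'
#' Sample-size-corrected Hudson estimator:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`. Genome-wide values should aggregate
#' the components as a ratio of averages (see [genome_fst()]), not average
#' the per-SNP ratios.
#'
#' @param p1,p2 Allele frequencies in the two populations (vectorised; the
#'   same polarised allele in both).
#' @param n1,n2 Haploid sample sizes (>= 2).
#' @return Tibble with `numerator`, `denominator` and per-SNP `ratio`
#'   (`NA` where the denominator is zero: both pools fixed for one allele).
#' @export
hudson_fst_snp <- function(p1, p2, n1, n2) {
  if (any(c(n1, n2) < 2)) abort("sample sizes must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble::tibble(
    numerator = num,
    denominator = den,
    ratio = ifelse(den > 0, num / den, NA_real_)
  )
}

#' Genome-wide Hudson FST as a ratio of averages
#'
#' @param numerator,denominator Per-SNP Hudson components; SNPs with a zero
#'   (or missing) denominator are excluded from both sums.
#' @return Scalar genome-wide FST.
#' @export
genome_fst <- function(numerator, denominator) {
  keep <- is.finite(numerator) & is.finite(denominator) & denominator > 0
  if (!any(keep)) return(NA_real_)
  sum(numerator[keep]) / sum(denominator[keep])
}

#' Pairwise genome-wide FST between all pools
#'
#' Computes Hudson's FST (ratio of averages over shared SNPs) for every pair
#' of pools in the frequency table, using haploid pool sizes from the design.
#'
#' @param freqs Frequency tibble from [sites_to_frequencies()].
#' @param design Design tibble.
#' @return Tibble with `pool1`, `pool2`, `n_snps`, `fst`.
#' @export
pairwise_fst <- function(freqs, design) {
  validate_design(design)
  wide <- freqs |>
    dplyr::select("chrom", "pos", "pool_id", "freq") |>
    tidyr::pivot_wider(names_from = "pool_id", values_from = "freq")
  pools <- intersect(design$pool_id, names(wide))
  n_by_pool <- setNames(2L * design$n_individuals, design$pool_id)
  pairs <- utils::combn(pools, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    ok <- !is.na(wide[[a]]) & !is.na(wide[[b]])
    comp <- hudson_fst_snp(wide[[a]][ok], wide[[b]][ok],
                           n_by_pool[[a]], n_by_pool[[b]])
    tibble::tibble(pool1 = a, pool2 = b, n_snps = sum(ok),
                   fst = genome_fst(comp$numerator, comp$denominator))
  })
}
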