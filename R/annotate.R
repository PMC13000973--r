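#' Consensus candidate intervals across the three evidence layers
#'
#' A local-score segment becomes a candidate interval only when it contains
#' at least `min_fst_snps` SNPs passing the three-step concordance filter
#' and at least `min_cmh_snps` SNPs significant in the replicated CMH test
#' (BH q below `fdr`). Segments and SNPs are matched within treatment.
#'
#' @param segments Local-score segments from [local_score_scan()].
#' @param tests Per-SNP test tibble from [scan_selection()] (needs
#'   `filter_pass` and `q`).
#' @param fdr CMH significance level on q (default 0.05).
#' @param min_fst_snps,min_cmh_snps Minimum supporting SNPs of each evidence
#'   type (default 1).
#' @return Tibble of retained intervals with `length_bp`, `n_fst_pass_snps`
#'   and `n_cmh_sig_snps`.
#' @export
consensus_intervals <- function(segments, tests, fdr = 0.05,
                                min_fst_snps = 1, min_cmh_snps = 1) {
  empty <- tibble::tibble(
    temperature = character(), pollination = character(),
    chrom = character(), start = double(), end = double(),
    length_bp = double(), peak = double(), n_fst_pass_snps = integer(),
    n_cmh_sig_snps = integer())
  if (is.null(segments) || nrow(segments) == 0L) return(empty)
  seg <- dplyr::mutate(segments, segment_id = dplyr::row_number())
  counts <- seg |>
    dplyr::inner_join(
      tests, by = c("temperature", "pollination", "chrom"),
      relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      n_fst_pass_snps = sum(.data$filter_pass, na.rm = TRUE),
      n_cmh_sig_snps = sum(.data$q < fdr, na.rm = TRUE),
      .groups = "drop")
  seg |>
    dplyr::left_join(counts, by = "segment_id") |>
    dplyr::mutate(
      n_fst_pass_snps = dplyr::coalesce(.data$n_fst_pass_snps, 0L),
      n_cmh_sig_snps = dplyr::coalesce(.data$n_cmh_sig_snps, 0L),
      length_bp = .data$end - .data$start + 1
    ) |>
    dplyr::filter(.data$n_fst_pass_snps >= min_fst_snps,
                  .data$n_cmh_sig_snps >= min_cmh_snps) |>
    dplyr::select("temperature", "pollination", "chrom", "start", "end",
                  "length_bp", "peak", "n_fst_pass_snps", "n_cmh_sig_snps") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Genes overlapping candidate intervals
#'
#' Assigns a gene to an interval when their 1-based inclusive spans overlap
#' by at least one bp (so a gene ending exactly at the interval start is
#' included).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param gene_models Gene tibble from [read_gff()].
#' @return The intervals with an `n_genes` count and a `genes` list-column;
#'   long pairs are in `attr(, "pairs")`. Intervals on chromosomes absent
#'   from the gene models get empty lists with a warning.
#' @export
genes_in_intervals <- function(intervals, gene_models) {
  if (nrow(intervals) == 0L) {
    out <- dplyr::mutate(intervals, n_genes = integer(0))
    out$genes <- list()
    attr(out, "pairs") <- tibble::tibble(gene_id = character())
    return(out)
  }
  missing_chr <- setdiff(unique(intervals$chrom), unique(gene_models$chrom))
  if (length(missing_chr)) {
    warn(paste0("no gene models on chromosome(s): ",
                paste(missing_chr, collapse = ", ")))
  }
  iv <- dplyr::mutate(intervals, .interval = dplyr::row_number())
  pairs <- dplyr::inner_join(
    iv[, c(".interval", "chrom", "start", "end")],
    gene_models[, c("gene_id", "chrom", "start", "end")],
    by = dplyr::join_by("chrom",
                        overlaps(x$start, x$end, y$start, y$end))
  )
  by_iv <- split(pairs$gene_id, factor(pairs$.interval,
                                       levels = iv$.interval))
  out <- iv |>
    dplyr::mutate(genes = unname(by_iv),
                  n_genes = lengths(.data$genes)) |>
    dplyr::select(-".interval")
  attr(out, "pairs") <- pairs
  out
}

#' GO-term enrichment of candidate genes
#'
#' One-sided (upper-tail) hypergeometric test per GO term — the classic
#' Fisher test without use of the term hierarchy — with BH adjustment
#' across tested terms. The gene universe defaults to all genes carrying at
#' least one GO annotation in the map.
#'
#' @param candidate_genes Character vector of candidate gene ids.
#' @param go_map Tibble with `gene_id`, `go_id` (one annotation per row).
#' @param universe_genes Optional explicit universe; must contain all
#'   candidates.
#' @return Tibble per term: `go_id`, `n_term` (term size in the universe),
#'   `n_overlap`, `p`, `q`; terms without candidate overlap get `p = 1`.
#' @export
go_enrichment <- function(candidate_genes, go_map, universe_genes = NULL) {
  if (length(candidate_genes) == 0L) abort("empty candidate gene set")
  universe_genes <- universe_genes %||% unique(go_map$gene_id)
  if (!all(candidate_genes %in% universe_genes)) {
    abort("all candidate genes must be in the universe")
  }
  candidate_genes <- unique(candidate_genes)
  map <- go_map |>
    dplyr::filter(.data$gene_id %in% universe_genes) |>
    dplyr::distinct(.data$gene_id, .data$go_id)
  N <- length(unique(universe_genes))
  n_cand <- length(candidate_genes)
  res <- map |>
    dplyr::group_by(.data$go_id) |>
    dplyr::summarise(
      n_term = dplyr::n_distinct(.data$gene_id),
      n_overlap = sum(unique(.data$gene_id) %in% candidate_genes),
      .groups = "drop") |>
    dplyr::mutate(
      p = phyper(.data$n_overlap - 1, .data$n_term, N - .data$n_term,
                 n_cand, lower.tail = FALSE),
      p = ifelse(.data$n_overlap == 0, 1, .data$p),
      q = bh_fdr(.data$p)
    ) |>
    dplyr::arrange(.data$p)
  res
}
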