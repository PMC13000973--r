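#' Run the full drift-calibrated selection-scan pipeline
#'
#' Orchestrates every stage on a sync table plus design:
#' site filtering and polarisation, threshold calibration against the
#' neutral drift null (and empirical controls when present), windowed
#' diversity statistics with pairwise FST and PCA, the per-SNP selection
#' scan (shifts, three-step filter, replicated CMH, classification), the
#' Lindley local-score segment calling, consensus candidate intervals, and
#' (when gene models are supplied) gene intersection and GO enrichment.
#' A failing stage aborts with an error naming the stage; stages already
#' written to `out_dir` are retained.
#'
#' @param sync Tidy sync tibble ([read_sync()] or
#'   [simulate_er_experiment()]`$sync`).
#' @param design Design tibble.
#' @param gene_models,go_map Optional annotation inputs ([read_gff()],
#'   [read_go_map()]).
#' @param thresholds Optional precomputed thresholds; calibrated when
#'   `NULL`.
#' @param min_count,min_cov,max_cov Site filters for
#'   [sites_to_frequencies()].
#' @param calib_n_snps,calib_mode Neutral-null size and mode for
#'   [calibrate_thresholds()].
#' @param drift_adjust Passed to [cmh_scan()].
#' @param xi,score,n_resample,window_range,alpha Local-score settings
#'   (see [local_score_scan()]).
#' @param fdr CMH significance level for consensus calling.
#' @param window_width Diversity window width (bp).
#' @param seed Base seed for the stochastic stages.
#' @param out_dir Optional directory for per-stage TSV outputs and a run
#'   log.
#'
#' @return A `driftscan_pipeline` list: `freqs`, `thresholds`, `diversity`,
#'   `pairwise_fst`, `pca`, `scan`, `segments`, `consensus`, `genes`, `go`,
#'   `summary`.
#' @export
run_pipeline <- function(sync, design, gene_models = NULL, go_map = NULL,
                         thresholds = NULL, min_count = 12, min_cov = 18,
                         max_cov = 150, calib_n_snps = 1e5,
                         calib_mode = "drift", drift_adjust = TRUE,
                         xi = 1, score = "p", n_resample = 5000,
                         window_range = c(1e4, 7e4), alpha = 0.05,
                         fdr = 0.05, window_width = 5e4, seed = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  emit <- function(x, file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(x, file.path(out_dir, file))
    }
  }

  validate_design(design)
  anc_id <- ancestral_pool(design)

  freqs <- stage("frequencies", sites_to_frequencies(
    sync, ancestral = anc_id, min_count = min_count, min_cov = min_cov,
    max_cov = max_cov))
  if (nrow(freqs) == 0L) abort("pipeline stage 'frequencies': no sites pass")

  if (is.null(thresholds)) {
    thresholds <- stage("calibration", calibrate_thresholds(
      design, freqs = freqs, n_snps = calib_n_snps, mode = calib_mode,
      seed = if (is.null(seed)) NULL else seed + 1000L))
  }
  emit(thresholds, "thresholds.tsv")

  diversity <- stage("diversity",
                     window_diversity(freqs, design,
                                      window_width = window_width))
  emit(diversity, "diversity_windows.tsv")
  fst_pairs <- stage("diversity", pairwise_fst(freqs, design))
  emit(fst_pairs, "pairwise_fst.tsv")
  pca <- stage("diversity", allele_freq_pca(freqs))
  emit(pca$scores, "pca_scores.tsv")

  scan <- stage("scan", scan_selection(
    freqs, design, thresholds, drift_adjust = drift_adjust))
  emit(scan$tests, "scan_tests.tsv")
  emit(scan$shifts, "scan_shifts.tsv")
  emit(scan$classes, "scan_classes.tsv")

  segments <- stage("local_score", local_score_scan(
    scan$tests, xi = xi, score = score, n_resample = n_resample,
    window_range = window_range, alpha = alpha,
    seed = if (is.null(seed)) NULL else seed + 2000L))
  emit(segments, "local_score_segments.tsv")

  consensus <- stage("consensus",
                     consensus_intervals(segments, scan$tests, fdr = fdr))
  emit(consensus, "consensus_intervals.tsv")

  genes <- NULL
  go <- NULL
  if (!is.null(gene_models) && nrow(consensus) > 0L) {
    genes <- stage("annotation", genes_in_intervals(consensus, gene_models))
    emit(dplyr::select(genes, -"genes"), "consensus_genes.tsv")
    candidate <- unique(attr(genes, "pairs")$gene_id)
    if (!is.null(go_map) && length(candidate) > 0L) {
      in_univ <- intersect(candidate, unique(go_map$gene_id))
      if (length(in_univ) > 0L) {
        go <- stage("annotation", go_enrichment(in_univ, go_map))
        emit(go, "go_enrichment.tsv")
      }
    }
  }

  summary_tbl <- stage("summary", {
    per_tr <- scan$tests |>
      dplyr::group_by(.data$temperature, .data$pollination) |>
      dplyr::summarise(
        n_snps = dplyr::n(),
        n_fst_pass = sum(.data$filter_pass, na.rm = TRUE),
        n_cmh_sig = sum(.data$q < fdr, na.rm = TRUE),
        .groups = "drop")
    n_int <- consensus |>
      dplyr::count(.data$temperature, .data$pollination,
                   name = "n_consensus_intervals")
    dplyr::left_join(per_tr, n_int,
                     by = c("temperature", "pollination")) |>
      dplyr::mutate(n_consensus_intervals = dplyr::coalesce(
        .data$n_consensus_intervals, 0L))
  })
  emit(summary_tbl, "summary.tsv")

  if (!is.null(out_dir)) {
    writeLines(c(
      sprintf("driftscan %s",
              as.character(utils::packageVersion("driftscan"))),
      sprintf("seed: %s", seed %||% "none"),
      sprintf("filters: min_count=%d min_cov=%d max_cov=%d",
              min_count, min_cov, max_cov),
      sprintf("calibration: n_snps=%d mode=%s", calib_n_snps, calib_mode),
      sprintf("local score: xi=%g n_resample=%d window=%g-%g alpha=%g",
              xi, n_resample, window_range[1], window_range[2], alpha),
      sprintf("fdr: %g", fdr)
    ), file.path(out_dir, "run_log.txt"))
  }

  structure(
    list(freqs = freqs, thresholds = thresholds, diversity = diversity,
         pairwise_fst = fst_pairs, pca = pca, scan = scan,
         segments = segments, consensus = consensus, genes = genes,
         go = go, summary = summary_tbl),
    class = "driftscan_pipeline"
  )
}

#' @export
print.driftscan_pipeline <- function(x, ...) {
  cat("Drift-calibrated selection scan\n")
  print(x$summary)
  invisible(x)
}
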