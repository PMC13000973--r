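#' Read a PoPoolation2-style sync file
#'
#' Parses the synchronised allele-count exchange format: one line per genomic
#' site with `chrom`, `pos`, `ref` and then one colon-separated
#' `A:T:C:G:N:del` count field per pool. The result is tidy (long): one row
#' per site per pool.
#'
#' @param path Path to a sync file (tab separated, no header).
#' @param design Optional experiment design tibble (see [read_design()]).
#'   When supplied, the number of count columns must equal `nrow(design)` and
#'   pools are labelled with `design$pool_id` in file column order.
#' @param pool_ids Optional character vector of pool names; an alternative to
#'   `design` when only labels are needed.
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `pool_id` and integer
#'   count columns `A`, `T`, `C`, `G`, `N`, `del`.
#' @seealso [write_sync()], [sites_to_frequencies()]
#' @export
read_sync <- function(path, design = NULL, pool_ids = NULL) {
  if (!file.exists(path)) abort(sprintf("sync file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!is.null(design)) pool_ids <- design$pool_id
  if (length(lines) == 0L) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      pool_id = character(), A = integer(), T = integer(), C = integer(),
      G = integer(), N = integer(), del = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    abort(sprintf("sync parse error at line %d: expected %d columns, found %d",
                  bad, ncols[1], ncols[bad]))
  }
  n_pools <- ncols[1] - 3L
  if (n_pools < 1L) abort("sync parse error: fewer than 4 columns")
  if (!is.null(pool_ids) && length(pool_ids) != n_pools) {
    abort(sprintf(
      "design lists %d pools but sync file has %d count columns",
      length(pool_ids), n_pools))
  }
  if (is.null(pool_ids)) pool_ids <- paste0("pool", seq_len(n_pools))

  m <- matrix(unlist(fields), ncol = ncols[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    abort(sprintf("sync parse error at line %d: non-integer position",
                  which(is.na(pos))[1]))
  }
  if (any(pos < 1L)) abort("sync positions must be >= 1")

  counts <- m[, -(1:3), drop = FALSE]
  parts <- strsplit(as.vector(counts), ":", fixed = TRUE)
  if (any(lengths(parts) != 6L)) {
    bad_idx <- which(lengths(parts) != 6L)[1]
    bad_line <- (bad_idx - 1L) %% nrow(m) + 1L
    abort(sprintf(
      "sync parse error at line %d: count field is not a 6-tuple", bad_line))
  }
  cnt <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 6L,
                                 byrow = TRUE))
  if (anyNA(cnt)) {
    bad_idx <- ceiling(which(is.na(t(cnt)))[1] / 6)
    bad_line <- (bad_idx - 1L) %% nrow(m) + 1L
    abort(sprintf("sync parse error at line %d: non-integer count", bad_line))
  }
  if (any(cnt < 0L)) abort("sync counts must be non-negative")

  tibble::tibble(
    chrom = rep(m[, 1], times = n_pools),
    pos = rep(pos, times = n_pools),
    ref = rep(m[, 3], times = n_pools),
    pool_id = rep(pool_ids, each = nrow(m)),
    A = cnt[, 1], T = cnt[, 2], C = cnt[, 3],
    G = cnt[, 4], N = cnt[, 5], del = cnt[, 6]
  ) |>
    dplyr::arrange(factor(.data$pool_id, levels = pool_ids)) |>
    dplyr::arrange(.data$chrom, .data$pos,
                   factor(.data$pool_id, levels = pool_ids))
}

#' Write a sync file
#'
#' Inverse of [read_sync()]: serialises a tidy sync tibble back to the
#' tab-separated multi-pool format, ordered by `(chrom, pos)`.
#'
#' @param sync Tidy sync tibble as returned by [read_sync()].
#' @param path Output path.
#' @param pool_ids Pool order for the count columns; defaults to the order of
#'   first appearance in `sync`.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path, pool_ids = NULL) {
  pool_ids <- pool_ids %||% unique(sync$pool_id)
  wide <- sync |>
    dplyr::mutate(field = paste(.data$A, .data$T, .data$C, .data$G, .data$N,
                                .data$del, sep = ":")) |>
    dplyr::select("chrom", "pos", "ref", "pool_id", "field") |>
    tidyr::pivot_wider(names_from = "pool_id", values_from = "field") |>
    dplyr::arrange(.data$chrom, .data$pos)
  wide <- wide[, c("chrom", "pos", "ref", pool_ids)]
  readr::write_tsv(wide, path, col_names = FALSE)
  invisible(path)
}

#' Derive filtered per-site minor-allele frequencies from sync counts
#'
#' Applies the standard pool-seq site filters and polarises the minor allele
#' against the ancestral pool so that signed frequency changes are comparable
#' across evolved pools. A site is retained only when
#' (i) exactly two nucleotides carry reads (summed over all pools) and
#' neither `N` nor deletions rank among the two most frequent states,
#' (ii) the minor allele's summed count is at least `min_count`, and
#' (iii) every pool's total depth lies within `[min_cov, max_cov]`.
#'
#' The minor allele is the rarer of the two alleles in the ancestral pool
#' (ties at 0.5 broken alphabetically) and the same allele is tracked in all
#' pools. Reported `depth` is the biallelic depth (major + minor reads), so
#' `freq * depth` reproduces the minor read count exactly; the coverage
#' filter is applied to the full six-state depth.
#'
#' @param sync Tidy sync tibble from [read_sync()] or [simulate_er_experiment()].
#' @param ancestral Pool id of the ancestral (G1) pool used to polarise the
#'   minor allele; `NULL` polarises on counts summed over all pools.
#' @param min_count Minimum summed minor-allele count (default 12).
#' @param min_cov,max_cov Per-pool total depth bounds (defaults 18 and 150).
#'
#' @return A tibble with one row per retained site per pool: `chrom`, `pos`,
#'   `major`, `minor`, `pool_id`, `depth`, `count` (minor reads) and `freq`.
#' @export
sites_to_frequencies <- function(sync, ancestral = NULL, min_count = 12,
                                 min_cov = 18, max_cov = 150) {
  if (min_cov > max_cov) abort("`min_cov` must not exceed `max_cov`")
  if (min_count < 1 || min_cov < 1) abort("filter thresholds must be positive")
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), major = character(),
    minor = character(), pool_id = character(), depth = integer(),
    count = integer(), freq = double()
  )
  if (nrow(sync) == 0L) return(empty)
  if (!is.null(ancestral) && !ancestral %in% sync$pool_id) {
    abort(sprintf("ancestral pool '%s' not present in sync data", ancestral))
  }

  alleles <- c("A", "T", "C", "G")
  tot <- sync |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c(alleles, "N", "del")), sum),
                     .groups = "drop")
  nuc <- as.matrix(tot[, alleles])
  nd_max <- pmax(tot$N, tot$del)

  # rank alleles by summed count; alphabetical (column) order breaks ties
  ord <- apply(nuc, 1L, order, decreasing = TRUE)
  top1 <- alleles[ord[1L, ]]
  top2 <- alleles[ord[2L, ]]
  c1 <- nuc[cbind(seq_len(nrow(nuc)), ord[1L, ])]
  c2 <- nuc[cbind(seq_len(nrow(nuc)), ord[2L, ])]
  n_nonzero <- rowSums(nuc > 0L)

  keep <- n_nonzero == 2L & c2 >= min_count & nd_max < c2
  sites <- tibble::tibble(chrom = tot$chrom, pos = tot$pos,
                          a1 = top1, a2 = top2)[keep, , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)

  long <- sync |>
    dplyr::inner_join(sites, by = c("chrom", "pos")) |>
    dplyr::mutate(
      total_depth = .data$A + .data$T + .data$C + .data$G + .data$N + .data$del
    )
  cm <- as.matrix(long[, alleles])
  long$count1 <- cm[cbind(seq_len(nrow(long)), match(long$a1, alleles))]
  long$count2 <- cm[cbind(seq_len(nrow(long)), match(long$a2, alleles))]

  # every pool must satisfy the coverage window
  cov_ok <- long |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      ok = all(.data$total_depth >= min_cov & .data$total_depth <= max_cov),
      .groups = "drop") |>
    dplyr::filter(.data$ok)
  long <- dplyr::semi_join(long, cov_ok, by = c("chrom", "pos"))
  if (nrow(long) == 0L) return(empty)

  # polarise: minor = rarer allele in the ancestral pool (alphabetical tie
  # break); when no ancestral pool is named, use counts summed over pools
  pol_src <- if (is.null(ancestral)) long else
    dplyr::filter(long, .data$pool_id == ancestral)
  pol <- pol_src |>
    dplyr::group_by(.data$chrom, .data$pos, .data$a1, .data$a2) |>
    dplyr::summarise(s1 = sum(.data$count1), s2 = sum(.data$count2),
                     .groups = "drop") |>
    dplyr::mutate(
      minor = dplyr::case_when(
        .data$s2 < .data$s1 ~ .data$a2,
        .data$s1 < .data$s2 ~ .data$a1,
        TRUE ~ pmin(.data$a1, .data$a2)
      ),
      major = ifelse(.data$minor == .data$a1, .data$a2, .data$a1)
    ) |>
    dplyr::select("chrom", "pos", "major", "minor")

  long |>
    dplyr::inner_join(pol, by = c("chrom", "pos")) |>
    dplyr::mutate(
      count = ifelse(.data$minor == .data$a1, .data$count1, .data$count2),
      depth = .data$count1 + .data$count2,
      freq = .data$count / .data$depth
    ) |>
    dplyr::select("chrom", "pos", "major", "minor", "pool_id", "depth",
                  "count", "freq") |>
    dplyr::arrange(.data$chrom, .data$pos)
}
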