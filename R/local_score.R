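#' Convert q-values to local scores
#'
#' `score = -log10(q) - xi`. The offset `xi` makes typical (non-significant)
#' SNPs contribute negative scores so the Lindley process returns to zero
#' between signal clusters; `xi = 1` is the relaxed and `xi = 2` the strict
#' convention.
#'
#' @param q Q-values in `(0, 1]`; exact zeros are capped (with a warning) so
#'   the score never exceeds `max_score`.
#' @param xi Positive score offset.
#' @param max_score Cap applied to `-log10(q) - xi` (default 10).
#' @return Numeric scores (possibly negative).
#' @export
scores_from_q <- function(q, xi = 1, max_score = 10) {
  if (xi <= 0) abort("xi must be positive")
  if (any(q < 0 | q > 1, na.rm = TRUE)) abort("q-values must be in [0, 1]")
  if (any(q == 0, na.rm = TRUE)) {
    warn("q-values of 0 capped at the maximum score")
  }
  pmin(-log10(q) - xi, max_score)
}

#' Lindley (cumulative score) process
#'
#' `h_0 = 0; h_i = max(0, h_{i-1} + s_i)`, computed with the cumulative-sum
#' identity `h_i = S_i - min(0, S_1, ..., S_i)`.
#'
#' @param scores Scores ordered by position along one chromosome.
#' @return Numeric vector `h` of the same length.
#' @export
lindley <- function(scores) {
  if (length(scores) == 0L) return(numeric(0))
  cs <- cumsum(scores)
  cs - pmin(0, cummin(cs))
}

#' Chromosome-specific Gumbel significance threshold for the local score
#'
#' Calibrates the null distribution of the maximum Lindley score by
#' resampling: in each resample the observed scores are permuted across the
#' chromosome's SNP positions (preserving the score distribution while
#' destroying spatial clustering), a window width is drawn from
#' `window_range`, the Lindley process is run independently within each
#' non-overlapping window of that width and the maximum over the chromosome
#' is recorded. A Gumbel distribution is fitted to the resampled maxima by
#' moments (`beta = sd * sqrt(6)/pi`, `mu = mean - gamma * beta`) and the
#' threshold is its upper `alpha` quantile
#' `mu - beta * log(-log(1 - alpha))`.
#'
#' @param scores Observed SNP scores on one chromosome.
#' @param positions SNP positions (bp), ascending, same length as `scores`.
#' @param n_resample Number of resampled trajectories (default 5000).
#' @param window_range Window width range in bp (default 10-70 kb). With
#'   `scheme = "uniform"` a width is drawn uniformly per resample; with
#'   `scheme = "grid"` the maximum over a fixed grid of widths is taken.
#' @param alpha Significance level (default 0.05).
#' @param scheme Window-width scheme (see `window_range`).
#' @param seed Optional seed.
#' @return A `driftscan_gumbel` object with `mu`, `beta`, `threshold`,
#'   `degenerate` flag and the resampled `maxima`.
#' @export
gumbel_threshold <- function(scores, positions, n_resample = 5000,
                             window_range = c(1e4, 7e4), alpha = 0.05,
                             scheme = c("uniform", "grid"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (length(scores) < 2L) abort("need >= 2 SNPs on the chromosome")
  stopifnot(length(scores) == length(positions))
  if (is.unsorted(positions)) abort("positions must be ascending")

  if (all(scores <= 0)) {
    return(structure(
      list(mu = NA_real_, beta = NA_real_, threshold = Inf,
           degenerate = TRUE, n_resample = n_resample,
           window_range = window_range, alpha = alpha,
           maxima = numeric(0), seed = seed),
      class = "driftscan_gumbel"))
  }

  offset <- positions - positions[1]
  grid_widths <- seq(window_range[1], window_range[2], length.out = 7)
  maxima <- with_seed_if(seed, {
    vapply(seq_len(n_resample), function(b) {
      s <- sample(scores)
      widths <- if (scheme == "uniform") {
        runif(1, window_range[1], window_range[2])
      } else grid_widths
      max(vapply(widths, function(w) {
        max_window_lindley(s, offset %/% w)
      }, 0))
    }, 0)
  })

  m <- mean(maxima)
  v <- sd(maxima)
  if (!is.finite(v) || v == 0) {
    return(structure(
      list(mu = m, beta = 0, threshold = Inf, degenerate = TRUE,
           n_resample = n_resample, window_range = window_range,
           alpha = alpha, maxima = maxima, seed = seed),
      class = "driftscan_gumbel"))
  }
  beta <- v * sqrt(6) / pi
  mu <- m - .EULER_GAMMA * beta
  structure(
    list(mu = mu, beta = beta,
         threshold = mu - beta * log(-log(1 - alpha)),
         degenerate = FALSE, n_resample = n_resample,
         window_range = window_range, alpha = alpha, maxima = maxima,
         seed = seed),
    class = "driftscan_gumbel"
  )
}

# max over windows of the within-window Lindley maximum; `win` is an
# integer window id per SNP (non-decreasing)
max_window_lindley <- function(scores, win) {
  dt <- data.table::data.table(win = win, s = scores)
  res <- dt[, {
    cs <- cumsum(s)
    max(cs - pmin(0, cummin(cs)))
  }, by = win]
  max(res$V1)
}

#' Gumbel quantile for a fitted local-score null
#'
#' @param fit A `driftscan_gumbel` object.
#' @param alpha Significance level.
#' @return The threshold at `alpha` (upper quantile).
#' @export
gumbel_quantile <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "driftscan_gumbel"))
  if (fit$degenerate) return(Inf)
  fit$mu - fit$beta * log(-log(1 - alpha))
}

#' Call significant local-score segments
#'
#' Reports one interval per excursion of the Lindley process whose maximum
#' exceeds the threshold. The interval starts at the first SNP of the
#' excursion (the first SNP after the last zero of `h`) and ends at the SNP
#' where the excursion attains its maximum — the significant core of the
#' excursion.
#'
#' @param chrom Chromosome name (scalar).
#' @param positions Ascending SNP positions.
#' @param scores SNP scores (same length).
#' @param threshold Finite positive threshold (from [gumbel_threshold()]).
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive), `peak`,
#'   `n_snps`; zero rows when nothing exceeds the threshold.
#' @export
call_segments <- function(chrom, positions, scores, threshold) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), peak = double(),
                          n_snps = integer())
  if (!is.finite(threshold)) return(empty)
  if (threshold <= 0) abort("threshold must be positive")
  h <- lindley(scores)
  if (!any(h > threshold)) return(empty)
  pos_run <- h > 0
  runs <- rle(pos_run)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- purrr::map_dfr(which(runs$values), function(k) {
    i0 <- starts[k]
    i1 <- ends[k]
    seg <- h[i0:i1]
    if (max(seg) <= threshold) return(NULL)
    i_peak <- i0 + which.max(seg) - 1L
    tibble::tibble(chrom = chrom, start = positions[i0],
                   end = positions[i_peak], peak = max(seg),
                   n_snps = i_peak - i0 + 1L)
  })
  if (nrow(out) == 0L) empty else out
}

#' Genome-wide local-score scan
#'
#' Converts per-treatment q-values to scores, runs the Lindley process per
#' chromosome, calibrates chromosome-specific Gumbel thresholds and calls
#' significant segments.
#'
#' @param tests Per-SNP test tibble with `chrom`, `pos`, `temperature`,
#'   `pollination`, `p` and `q` (from [cmh_scan()] / [scan_selection()]).
#' @param xi Score offset (1 relaxed, 2 strict).
#' @param score Which significance value feeds the score conversion: raw
#'   `"p"` (default; uniform under the null, the assumption behind the
#'   local-score calibration) or BH-adjusted `"q"` (more conservative:
#'   adjusted values compress moderate signal below zero score).
#' @param n_resample,window_range,alpha,scheme Passed to
#'   [gumbel_threshold()].
#' @param seed Optional base seed (offset per chromosome and treatment).
#' @return Tibble of segments with treatment columns, `chrom`, `start`,
#'   `end`, `peak`, `n_snps`, `threshold`, `xi`.
#' @export
local_score_scan <- function(tests, xi = 1, score = c("p", "q"),
                             n_resample = 5000,
                             window_range = c(1e4, 7e4), alpha = 0.05,
                             scheme = "uniform", seed = NULL) {
  score <- match.arg(score)
  groups <- tests |>
    dplyr::filter(!is.na(.data[[score]])) |>
    dplyr::group_by(.data$temperature, .data$pollination, .data$chrom) |>
    dplyr::group_split()
  purrr::map_dfr(seq_along(groups), function(i) {
    g <- dplyr::arrange(groups[[i]], .data$pos)
    if (nrow(g) < 2L) return(NULL)
    s <- scores_from_q(g[[score]], xi = xi)
    fit <- gumbel_threshold(
      s, g$pos, n_resample = n_resample, window_range = window_range,
      alpha = alpha, scheme = scheme,
      seed = if (is.null(seed)) NULL else seed + i)
    segs <- call_segments(g$chrom[1], g$pos, s, fit$threshold)
    if (nrow(segs) == 0L) return(NULL)
    segs |>
      dplyr::mutate(temperature = g$temperature[1],
                    pollination = g$pollination[1],
                    threshold = fit$threshold, xi = xi, .before = 1)
  })
}

#' @export
print.driftscan_gumbel <- function(x, ...) {
  if (x$degenerate) {
    cat("Local-score Gumbel fit: degenerate (no positive scores)\n")
  } else {
    cat(sprintf(
      "Local-score Gumbel fit: mu = %.3f, beta = %.3f, threshold(%.2g) = %.3f\n",
      x$mu, x$beta, x$alpha, x$threshold))
  }
  invisible(x)
}
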