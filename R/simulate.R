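#' Configure a synthetic evolve-and-resequence experiment
#'
#' Collects every knob of the forward simulator: genome layout, founder
#' allele-frequency spectrum, number of generations, the pool design, the
#' selected loci with their regime-specific selection coefficients, and the
#' sequencing model (pool sampling, Poisson read depth, optional symmetric
#' sequencing error).
#'
#' @param design Design tibble (see [pool_design()], [study_design()]).
#' @param n_chromosomes,snps_per_chromosome,chromosome_length Genome layout;
#'   SNP positions are drawn uniformly without replacement per chromosome.
#' @param founder Founder spectrum: `list(dist = "uniform", maf_min = 0.1)`
#'   draws minor-allele frequencies from `Uniform(maf_min, 1 - maf_min)`;
#'   `list(dist = "beta", shape1 =, shape2 =, maf_min =)` draws from a Beta
#'   truncated to the same interval.
#' @param generations Number of generations each evolved pool is propagated;
#'   must match the length of every `ne` trajectory in `design`.
#' @param selected_loci Tibble with columns `locus` (global SNP index in
#'   position order), `s_ambient` and `s_hot`: the genic selection
#'   coefficients applied in the two temperature regimes. Control
#'   (hand-pollinated) pools always evolve neutrally.
#' @param depth_mean Mean sequencing depth per pool (Poisson); default 120.
#' @param error_rate Symmetric per-read sequencing error rate in `[0, 0.5)`.
#' @param block_width When non-`NULL`, SNPs within non-overlapping windows of
#'   this width (bp) share a single founder frequency and drift/selection
#'   trajectory, creating the locally clustered signal that region-level
#'   scans detect; `NULL` (default) gives free recombination between SNPs.
#' @param seed Optional integer seed fixing every draw.
#'
#' @return A `driftscan_sim_config` list.
#' @export
sim_config <- function(design = study_design(),
                       n_chromosomes = 2, snps_per_chromosome = 1000,
                       chromosome_length = 2e6,
                       founder = list(dist = "uniform", maf_min = 0.1),
                       generations = 6,
                       selected_loci = NULL,
                       depth_mean = 120, error_rate = 0,
                       block_width = NULL, seed = NULL) {
  validate_design(design)
  maf_min <- founder$maf_min %||% 0.1
  if (maf_min <= 0 || maf_min >= 0.5) abort("maf_min must be in (0, 0.5)")
  founder$maf_min <- maf_min
  if (generations < 1) abort("generations must be >= 1")
  if (depth_mean <= 0) abort("depth_mean must be positive")
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("error_rate must be in [0, 0.5)")
  }
  evolved <- !is.na(design$pollination)
  if (any(lengths(design$ne[evolved]) != generations)) {
    abort("every evolved pool's ne trajectory must have `generations` entries")
  }
  n_snps <- n_chromosomes * snps_per_chromosome
  if (!is.null(selected_loci)) {
    selected_loci <- tibble::as_tibble(selected_loci)
    stopifnot(all(c("locus", "s_ambient", "s_hot") %in% names(selected_loci)))
    if (any(selected_loci$locus < 1 | selected_loci$locus > n_snps)) {
      abort("selected locus index out of range")
    }
    if (any(abs(c(selected_loci$s_ambient, selected_loci$s_hot)) >= 1)) {
      abort("selection coefficients must satisfy |s| < 1")
    }
  }
  structure(
    list(design = design, n_chromosomes = n_chromosomes,
         snps_per_chromosome = snps_per_chromosome,
         chromosome_length = chromosome_length, founder = founder,
         generations = generations, selected_loci = selected_loci,
         depth_mean = depth_mean, error_rate = error_rate,
         block_width = block_width, seed = seed),
    class = "driftscan_sim_config"
  )
}

#' Draw founder minor-allele frequencies
#'
#' @param n_snps Number of frequencies to draw.
#' @param founder Spectrum specification as in [sim_config()].
#' @param seed Optional seed.
#' @return Numeric vector in `[maf_min, 1 - maf_min]`.
#' @export
draw_founder_spectrum <- function(n_snps,
                                  founder = list(dist = "uniform",
                                                 maf_min = 0.1),
                                  seed = NULL) {
  if (n_snps < 1) abort("n_snps must be >= 1")
  maf_min <- founder$maf_min %||% 0.1
  if (maf_min <= 0 || maf_min >= 0.5) abort("maf_min must be in (0, 0.5)")
  dist <- founder$dist %||% "uniform"
  with_seed_if(seed, {
    if (dist == "uniform") {
      runif(n_snps, maf_min, 1 - maf_min)
    } else if (dist == "beta") {
      # rejection-sample the truncated Beta
      p <- numeric(0)
      while (length(p) < n_snps) {
        cand <- rbeta(n_snps, founder$shape1, founder$shape2)
        p <- c(p, cand[cand >= maf_min & cand <= 1 - maf_min])
      }
      p[seq_len(n_snps)]
    } else {
      abort(sprintf("unknown founder distribution '%s'", dist))
    }
  })
}

#' One Wright-Fisher generation with genic selection
#'
#' Applies the deterministic genic-selection update
#' `p* = p(1 + s) / (1 + p s)` and then binomial sampling of `2 * ne` allele
#' copies. Vectorised over loci; `0` and `1` are absorbing.
#'
#' @param p Allele frequencies in `[0, 1]`.
#' @param ne Effective population size for this generation (scalar, >= 1).
#' @param s Genic selection coefficient(s), scalar or per-locus.
#' @return Frequencies after one generation.
#' @export
wf_step <- function(p, ne, s = 0) {
  check_range(p, 0, 1, "p")
  if (ne < 1) abort("ne must be >= 1")
  p_sel <- p * (1 + s) / (1 + p * s)
  rbinom(length(p), 2L * as.integer(ne), p_sel) / (2 * as.integer(ne))
}

#' Pool-seq read counts for a set of loci
#'
#' Two-stage sampling of pooled sequencing: `2 * n_individuals` chromosomes
#' are drawn binomially at the population frequency, then read depth is
#' Poisson and minor-allele reads are binomial at the pool frequency, moved
#' toward the other allele by the symmetric sequencing error rate.
#'
#' @param p Population minor-allele frequencies.
#' @param n_individuals Individuals in the pool (>= 1).
#' @param depth_mean Mean Poisson read depth.
#' @param error_rate Symmetric error rate in `[0, 0.5)`.
#' @param seed Optional seed.
#' @return A tibble with columns `count` (minor reads) and `depth`.
#' @export
pool_read_counts <- function(p, n_individuals, depth_mean = 120,
                             error_rate = 0, seed = NULL) {
  check_range(p, 0, 1, "p")
  if (n_individuals < 1) abort("n_individuals must be >= 1")
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("error_rate must be in [0, 0.5)")
  }
  with_seed_if(seed, {
    n <- length(p)
    chroms <- 2L * as.integer(n_individuals)
    p_pool <- rbinom(n, chroms, p) / chroms
    depth <- rpois(n, depth_mean)
    p_read <- p_pool * (1 - error_rate) + (1 - p_pool) * error_rate
    tibble::tibble(count = rbinom(n, depth, p_read), depth = depth)
  })
}

# expected Fig.-3-style class implied by the signs of (s_ambient, s_hot)
expected_class <- function(s_ambient, s_hot) {
  dplyr::case_when(
    s_ambient == 0 & s_hot == 0 ~ "background",
    s_ambient != 0 & s_hot == 0 ~ "conditional_ambient",
    s_ambient == 0 & s_hot != 0 ~ "conditional_hot",
    sign(s_ambient) == sign(s_hot) ~ "global_adaptation",
    TRUE ~ "antagonistic_pleiotropy"
  )
}

#' Simulate a full evolve-and-resequence experiment
#'
#' Runs the forward Wright-Fisher model for every evolved pool in the design:
#' all pools share one set of founder frequencies; replicates within a
#' treatment share those founders but drift (and respond to selection)
#' independently; selection uses `s_ambient` in ambient pools and `s_hot` in
#' hot pools, and is switched off in control (hand-pollinated) pools. The
#' ancestral pool is "sequenced" once from the founder frequencies through
#' the same pool/read sampling and shared by all comparisons.
#'
#' @param config A [sim_config()] object.
#' @return A `driftscan_sim` list with elements `sync` (tidy sync tibble for
#'   every pool including the ancestral one), `design`, `truth` (planted-loci
#'   table with expected classification) and `founder` (per-SNP founder
#'   state).
#' @export
simulate_er_experiment <- function(config) {
  stopifnot(inherits(config, "driftscan_sim_config"))
  with_seed_if(config$seed, simulate_er_impl(config))
}

simulate_er_impl <- function(config) {
  design <- config$design
  n_chr <- config$n_chromosomes
  n_per <- config$snps_per_chromosome
  n_snps <- n_chr * n_per
  chroms <- sprintf("A%02d", seq_len(n_chr))

  pos <- unlist(lapply(seq_len(n_chr), function(i) {
    sort(sample.int(config$chromosome_length, n_per))
  }))
  chrom <- rep(chroms, each = n_per)

  # block structure: units are blocks when block_width is set, else SNPs
  if (!is.null(config$block_width)) {
    block <- paste0(chrom, ":", (pos - 1L) %/% config$block_width)
    unit <- match(block, unique(block))
  } else {
    unit <- seq_len(n_snps)
  }
  n_units <- max(unit)

  p0_unit <- draw_founder_spectrum(n_units, config$founder)
  p0 <- p0_unit[unit]

  bases <- c("A", "C", "G", "T")
  major <- sample(bases, n_snps, replace = TRUE)
  minor <- vapply(major, function(b) sample(setdiff(bases, b), 1L), "")

  # per-unit selection coefficients for the two temperature regimes
  s_amb <- numeric(n_units)
  s_hot <- numeric(n_units)
  truth <- NULL
  if (!is.null(config$selected_loci) && nrow(config$selected_loci) > 0L) {
    sl <- config$selected_loci
    u <- unit[sl$locus]
    if (anyDuplicated(u)) {
      abort("two selected loci fall in the same linkage block")
    }
    s_amb[u] <- sl$s_ambient
    s_hot[u] <- sl$s_hot
    truth <- tibble::tibble(
      chrom = chrom[sl$locus], pos = pos[sl$locus],
      locus = sl$locus, s_ambient = sl$s_ambient, s_hot = sl$s_hot,
      expected_class = expected_class(sl$s_ambient, sl$s_hot)
    )
  } else {
    truth <- tibble::tibble(chrom = character(), pos = integer(),
                            locus = integer(), s_ambient = double(),
                            s_hot = double(), expected_class = character())
  }

  anc_id <- ancestral_pool(design)
  sync_one <- function(pool_id, p_snp, n_ind) {
    reads <- pool_read_counts(p_snp, n_ind, config$depth_mean,
                              config$error_rate)
    cnt <- matrix(0L, n_snps, 6L,
                  dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
    cnt[cbind(seq_len(n_snps), match(minor, colnames(cnt)))] <- reads$count
    cnt[cbind(seq_len(n_snps), match(major, colnames(cnt)))] <-
      reads$depth - reads$count
    tibble::tibble(chrom = chrom, pos = pos, ref = major, pool_id = pool_id,
                   A = cnt[, "A"], T = cnt[, "T"], C = cnt[, "C"],
                   G = cnt[, "G"], N = cnt[, "N"], del = cnt[, "del"])
  }

  anc_n <- design$n_individuals[design$pool_id == anc_id]
  out <- list(sync_one(anc_id, p0, anc_n))

  for (i in which(!is.na(design$pollination))) {
    s_unit <- if (design$pollination[i] == "control") {
      numeric(n_units)
    } else if (design$temperature[i] == "ambient") s_amb else s_hot
    p <- p0_unit
    for (ne_g in design$ne[[i]]) p <- wf_step(p, ne_g, s_unit)
    out[[length(out) + 1L]] <-
      sync_one(design$pool_id[i], p[unit], design$n_individuals[i])
  }

  structure(
    list(sync = dplyr::bind_rows(out), design = design, truth = truth,
         founder = tibble::tibble(chrom = chrom, pos = pos, major = major,
                                  minor = minor, p0 = p0, unit = unit),
         config = config),
    class = "driftscan_sim"
  )
}

#' Write a simulated experiment to disk
#'
#' Emits one sync file per pool (ancestral included), the design table and
#' the planted-truth table. Byte-identical for a fixed [sim_config()] seed.
#'
#' @param sim A `driftscan_sim` object from [simulate_er_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
simulate_er_files <- function(sim, dir) {
  stopifnot(inherits(sim, "driftscan_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sync_paths <- vapply(unique(sim$sync$pool_id), function(pid) {
    path <- file.path(dir, paste0(pid, ".sync"))
    write_sync(dplyr::filter(sim$sync, .data$pool_id == pid), path)
    path
  }, "")
  design_path <- file.path(dir, "design.tsv")
  write_design(sim$design, design_path)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_path)
  invisible(list(sync = sync_paths, design = design_path, truth = truth_path))
}
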