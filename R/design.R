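#' Build an experiment design table
#'
#' The design table describes every sequenced pool: the ancestral (G1) pool
#' plus one row per evolved population, with its temperature regime,
#' pollination regime, replicate label, number of pooled individuals and the
#' realised per-generation effective population sizes.
#'
#' @param pool_id Character vector of pool names.
#' @param temperature `"ambient"` or `"hot"` (`NA` for the ancestral pool).
#' @param pollination One of `"bumblebee"`, `"butterfly"`, `"generalised"`,
#'   `"control"` (`NA` for the ancestral pool).
#' @param replicate Replicate label, conventionally `"A"`/`"B"` (`NA` for the
#'   ancestral pool).
#' @param n_individuals Number of individuals in each pool (>= 1).
#' @param ne List of integer vectors: the per-generation effective sizes
#'   `Ne_g` of each evolved pool; the ancestral pool takes `integer(0)`.
#'
#' @return A validated design tibble with a `ne` list-column.
#' @export
pool_design <- function(pool_id, temperature, pollination, replicate,
                        n_individuals, ne) {
  d <- tibble::tibble(
    pool_id = as.character(pool_id),
    temperature = as.character(temperature),
    pollination = as.character(pollination),
    replicate = as.character(replicate),
    n_individuals = as.integer(n_individuals),
    ne = ne
  )
  validate_design(d)
}

#' @rdname pool_design
#' @param design A design tibble to validate.
#' @export
validate_design <- function(design) {
  req <- c("pool_id", "temperature", "pollination", "replicate",
           "n_individuals", "ne")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(paste0("design is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(design$pool_id)) abort("duplicated pool_id in design")
  if (any(design$n_individuals < 1L)) abort("n_individuals must be >= 1")
  bad_temp <- !is.na(design$temperature) &
    !design$temperature %in% c("ambient", "hot")
  if (any(bad_temp)) abort("temperature must be 'ambient' or 'hot'")
  evolved <- !is.na(design$pollination)
  if (any(lengths(design$ne[evolved]) == 0L)) {
    abort("evolved pools need a non-empty ne trajectory")
  }
  if (any(unlist(design$ne) < 1)) abort("every Ne_g must be >= 1")
  design
}

#' @rdname pool_design
#' @export
ancestral_pool <- function(design) {
  anc <- design$pool_id[is.na(design$pollination)]
  if (length(anc) != 1L) {
    abort("design must contain exactly one ancestral pool (pollination = NA)")
  }
  anc
}

#' The default two-temperature, four-regime study design
#'
#' Builds the full crossed design used by the simulator's defaults: two
#' temperature regimes (`ambient`, `hot`) by four pollination regimes
#' (`bumblebee`, `butterfly`, `generalised`, `control`) by two replicates,
#' plus the ancestral G1 pool. Bumblebee pools take a constant effective size
#' of 18 per generation; the other regimes 35, reflecting the much smaller
#' subset of plants that set seed under single-bumblebee pollination.
#'
#' @param n_individuals Pool size (individuals) for every pool; default 25.
#' @param generations Number of generations of evolution; default 6.
#' @param ne_bumblebee,ne_other Constant per-generation effective sizes.
#' @return A design tibble (see [pool_design()]).
#' @export
study_design <- function(n_individuals = 25, generations = 6,
                         ne_bumblebee = 18, ne_other = 35) {
  regimes <- tidyr::expand_grid(
    temperature = c("ambient", "hot"),
    pollination = c("bumblebee", "butterfly", "generalised", "control"),
    replicate = c("A", "B")
  )
  ne <- ifelse(regimes$pollination == "bumblebee", ne_bumblebee, ne_other)
  pool_design(
    pool_id = c("G1", paste(substr(regimes$temperature, 1, 1),
                            regimes$pollination, regimes$replicate, sep = "_")),
    temperature = c(NA, regimes$temperature),
    pollination = c(NA, regimes$pollination),
    replicate = c(NA, regimes$replicate),
    n_individuals = rep(n_individuals, nrow(regimes) + 1L),
    ne = c(list(integer(0)),
           lapply(ne, function(x) rep(as.integer(x), generations)))
  )
}

#' Read or write a design table as TSV
#'
#' The on-disk format is one row per pool with columns `pool_id`,
#' `temperature`, `pollination`, `replicate`, `n_individuals` and then
#' `ne_g1` ... `ne_gt`; the ancestral pool leaves the `ne_g*` fields empty.
#'
#' @param path TSV path.
#' @return `read_design()` returns a design tibble; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  ne_cols <- grep("^ne_g[0-9]+$", names(raw), value = TRUE)
  ne_cols <- ne_cols[order(as.integer(sub("^ne_g", "", ne_cols)))]
  ne_mat <- as.matrix(raw[, ne_cols])
  ne <- lapply(seq_len(nrow(raw)), function(i) {
    v <- as.integer(ne_mat[i, ])
    v[!is.na(v)]
  })
  pool_design(raw$pool_id, raw$temperature, raw$pollination, raw$replicate,
              raw$n_individuals, ne)
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
write_design <- function(design, path) {
  t_max <- max(lengths(design$ne))
  ne_mat <- t(vapply(design$ne, function(v) {
    c(v, rep(NA_integer_, t_max - length(v)))
  }, integer(t_max)))
  colnames(ne_mat) <- paste0("ne_g", seq_len(t_max))
  out <- dplyr::bind_cols(
    design[, c("pool_id", "temperature", "pollination", "replicate",
               "n_individuals")],
    tibble::as_tibble(ne_mat)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
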