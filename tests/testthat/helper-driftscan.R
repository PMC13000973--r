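# shared fixture builders; everything is generated in code

# two-temperature single-regime design: G1 + 2x2 evolved pools
tiny_design <- function(ne = 18L, generations = 6L, n_individuals = 25L,
                        pollination = "bumblebee") {
  pool_design(
    pool_id = c("G1", "aA", "aB", "hA", "hB"),
    temperature = c(NA, "ambient", "ambient", "hot", "hot"),
    pollination = c(NA, rep(pollination, 4)),
    replicate = c(NA, "A", "B", "A", "B"),
    n_individuals = n_individuals,
    ne = c(list(integer(0)),
           rep(list(rep(as.integer(ne), generations)), 4))
  )
}

# single-treatment design (one temperature, two replicates)
one_treatment_design <- function(ne = 100L, generations = 6L,
                                 n_individuals = 50L) {
  pool_design(
    pool_id = c("G1", "repA", "repB"),
    temperature = c(NA, "ambient", "ambient"),
    pollination = c(NA, "bumblebee", "bumblebee"),
    replicate = c(NA, "A", "B"),
    n_individuals = n_individuals,
    ne = c(list(integer(0)),
           rep(list(rep(as.integer(ne), generations)), 2))
  )
}

# hand-built sync tibble: counts is a list of named per-pool 6-vectors
# (A, T, C, G, N, del), one list element per pool, recycled across sites
make_sync <- function(pos, counts, chrom = "A01", ref = "A",
                      pool_ids = NULL) {
  pool_ids <- pool_ids %||% paste0("pool", seq_along(counts[[1]]))
  rows <- lapply(seq_along(pos), function(i) {
    site_counts <- counts[[i]]
    do.call(rbind, lapply(seq_along(site_counts), function(j) {
      cnt <- site_counts[[j]]
      data.frame(chrom = chrom, pos = pos[i], ref = ref,
                 pool_id = pool_ids[j],
                 A = cnt[1], T = cnt[2], C = cnt[3], G = cnt[4],
                 N = cnt[5], del = cnt[6])
    }))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force maximal clipped contiguous segment sum (local-score oracle)
brute_max_segment <- function(s) {
  n <- length(s)
  best <- 0
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + s[j]
      if (acc > best) best <- acc
    }
  }
  best
}
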