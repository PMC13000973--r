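#' Read gene models from GFF3
#'
#' Extracts gene features from a GFF3 file (via [ape::read.gff()]) together
#' with GO annotations taken either from inline `Ontology_term` attributes or
#' from a two-column side table (`gene_id`, `go_id`).
#'
#' @param path GFF3 file path.
#' @param go_map Optional tibble with columns `gene_id` and `go_id`
#'   supplementing (or replacing) inline `Ontology_term` annotations; see
#'   [read_go_map()].
#' @param feature Feature type to keep (default `"gene"`).
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `description` and a `go_terms` list-column.
#' @export
read_gff <- function(path, go_map = NULL, feature = "gene") {
  if (!file.exists(path)) abort(sprintf("GFF file not found: %s", path))
  gff <- ape::read.gff(path)
  gff <- gff[gff$type == feature, , drop = FALSE]
  if (nrow(gff) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), description = character(),
                          go_terms = list()))
  }
  if (any(gff$start > gff$end)) abort("GFF gene feature with start > end")

  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]*)"))
    m[, 2]
  }
  ids <- attr_field(gff$attributes, "ID")
  missing_id <- is.na(ids) | ids == ""
  if (any(missing_id)) {
    warn(sprintf("skipping %d gene feature(s) without an ID attribute",
                 sum(missing_id)))
    gff <- gff[!missing_id, , drop = FALSE]
    ids <- ids[!missing_id]
  }
  desc <- attr_field(gff$attributes, "Note")
  desc[is.na(desc)] <- attr_field(gff$attributes, "description")[is.na(desc)]
  onto <- attr_field(gff$attributes, "Ontology_term")
  go_inline <- lapply(onto, function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ",")[[1]]
  })

  genes <- tibble::tibble(
    gene_id = ids,
    chrom = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    description = desc,
    go_terms = go_inline
  )
  if (!is.null(go_map)) {
    side <- split(go_map$go_id, go_map$gene_id)
    genes$go_terms <- lapply(seq_len(nrow(genes)), function(i) {
      sort(unique(c(genes$go_terms[[i]], side[[genes$gene_id[i]]])))
    })
  }
  genes
}

#' Read a gene-to-GO side table
#'
#' @param path Two-column TSV (`gene_id`, `go_id`), one annotation per row;
#'   a header is optional.
#' @return A tibble with columns `gene_id` and `go_id`.
#' @export
read_go_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  raw <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE)
  if (!has_header) names(raw) <- c("gene_id", "go_id")
  tibble::as_tibble(raw[, c("gene_id", "go_id")])
}

#' Write candidate intervals as BED
#'
#' Converts 1-based inclusive intervals to the BED convention (0-based,
#' half-open) and writes them sorted by `(chrom, start)`.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally a
#'   `name` column (a label is synthesised when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- intervals |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      bed_start = .data$start - 1L,
      name = if ("name" %in% names(intervals)) .data$name else
        paste0(.data$chrom, ":", .data$start, "-", .data$end)
    ) |>
    dplyr::select("chrom", "bed_start", "end", "name")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
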