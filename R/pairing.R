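#' Pair homologues of two families by genomic co-location
#'
#' For every nucleotide record carrying hits of both families, pairs hits
#' whose coding genes lie fewer than `max_separation` gene positions apart
#' (strict `<`, so the default keeps separations 0..19). Genes close together
#' on a record are likely on one operon and hence likely to function -- and
#' co-evolve -- together.
#'
#' With `pairing = "closest"` (default) one pair is emitted per record: the
#' pair with the smallest gene separation, ties broken by smallest combined
#' e-value, then lexicographically by `(gene_index_a, gene_index_b)`. This
#' keeps paralogue fans from contributing duplicated rows to the paired
#' alignment. `pairing = "all"` emits every qualifying combination.
#'
#' @param hits_a,hits_b Filtered hit tibbles for families A and B
#'   (see [filter_hits()]).
#' @param max_separation Strict upper bound on `|gene_index_a - gene_index_b|`;
#'   default 20.
#' @param pairing `"closest"` (one pair per record) or `"all"`.
#' @return A tibble sorted by `record_id` with columns `record_id`,
#'   `family_a`, `gene_index_a`, `evalue_a`, `coverage_a`, `aligned_seq_a`,
#'   the `_b` counterparts, and `separation`.
#' @examples
#' a <- tibble::tibble(family_id = "fA", record_id = "R1", gene_index = 5L,
#'                     evalue = 1e-20, coverage = 0.9, aligned_seq = "MK")
#' b <- tibble::tibble(family_id = "fB", record_id = "R1", gene_index = 9L,
#'                     evalue = 1e-15, coverage = 0.8, aligned_seq = "AYE")
#' pair_by_locus(a, b)
#' @export
pair_by_locus <- function(hits_a, hits_b, max_separation = 20L,
                          pairing = c("closest", "all")) {
  pairing <- match.arg(pairing)
  if (!is_count(max_separation, min = 1L)) {
    abort_validation("`max_separation` must be an integer >= 1")
  }
  for (h in list(hits_a, hits_b)) {
    if (nrow(h) > 0L && any(h$gene_index < 0L)) {
      abort_data("gene_index must be non-negative")
    }
  }
  empty <- tibble(
    record_id = character(),
    family_a = character(), gene_index_a = integer(), evalue_a = double(),
    coverage_a = double(), aligned_seq_a = character(),
    family_b = character(), gene_index_b = integer(), evalue_b = double(),
    coverage_b = double(), aligned_seq_b = character(),
    separation = integer()
  )
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L) {
    return(empty)
  }
  a <- rename(
    hits_a,
    family_a = "family_id", gene_index_a = "gene_index",
    evalue_a = "evalue", coverage_a = "coverage", aligned_seq_a = "aligned_seq"
  )
  b <- rename(
    hits_b,
    family_b = "family_id", gene_index_b = "gene_index",
    evalue_b = "evalue", coverage_b = "coverage", aligned_seq_b = "aligned_seq"
  )
  pairs <- inner_join(a, b, by = "record_id", relationship = "many-to-many")
  pairs <- mutate(pairs,
    separation = abs(.data$gene_index_a - .data$gene_index_b)
  )
  pairs <- dplyr::filter(pairs, .data$separation < max_separation)
  if (pairing == "closest" && nrow(pairs) > 0L) {
    pairs <- pairs |>
      group_by(.data$record_id) |>
      arrange(
        .data$separation, .data$evalue_a + .data$evalue_b,
        .data$gene_index_a, .data$gene_index_b,
        .by_group = TRUE
      ) |>
      slice(1L) |>
      ungroup()
  }
  pairs <- arrange(pairs,
    .data$record_id, .data$gene_index_a, .data$gene_index_b
  )
  select(pairs, names(empty))
}

#' Write paired records to TSV
#'
#' @param pairs Tibble from [pair_by_locus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_records <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}
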