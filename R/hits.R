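#' Read a homologue hit table
#'
#' Ingests the tab-separated product of an upstream iterative profile search
#' (one row per hit of a protein family on a nucleotide record). The expected
#' header is `family_id  record_id  gene_index  evalue  coverage  aligned_seq`
#' with 0-based `gene_index` (ordinal position of the coding gene on the
#' record) and `aligned_seq` the query-aligned hit sequence over the 20
#' amino-acid letters plus `-`, of length equal to the family profile.
#'
#' @param path Path to a TSV file with the header above.
#' @param family_id Family the table belongs to; rows carrying a different
#'   `family_id` are rejected.
#' @param profile_length Declared profile length; every `aligned_seq` must
#'   have exactly this many characters.
#' @return A tibble with columns `family_id`, `record_id`, `gene_index`
#'   (integer), `evalue`, `coverage`, `aligned_seq`, one row per hit.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "family_id\trecord_id\tgene_index\tevalue\tcoverage\taligned_seq",
#'   "virB5\tREC1\t4\t1e-20\t0.8\tMKLV"
#' ), tf)
#' read_hit_table(tf, "virB5", profile_length = 4)
#' @export
read_hit_table <- function(path, family_id, profile_length) {
  if (!file.exists(path)) {
    abort_validation(sprintf("hit table not found: %s", path))
  }
  if (!is_count(profile_length, min = 1L)) {
    abort_validation("`profile_length` must be a positive integer")
  }
  hits <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      family_id = readr::col_character(),
      record_id = readr::col_character(),
      gene_index = readr::col_integer(),
      evalue = readr::col_double(),
      coverage = readr::col_double(),
      aligned_seq = readr::col_character()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(hits)
  if (nrow(probs) > 0L) {
    abort_data(sprintf(
      "malformed hit table %s: cannot parse line %d (%s)",
      path, probs$row[1], probs$expected[1]
    ))
  }
  required <- c("family_id", "record_id", "gene_index", "evalue", "coverage", "aligned_seq")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0L) {
    abort_data(sprintf(
      "hit table %s lacks column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  hits <- hits[required]
  if (nrow(hits) == 0L) {
    return(hits)
  }
  validate_hits(hits, family_id, profile_length, source = path)
  hits
}

validate_hits <- function(hits, family_id, profile_length, source = "hit table") {
  # data lines start after the header, hence + 1
  line_of <- function(i) i + 1L
  bad_fam <- which(hits$family_id != family_id)
  if (length(bad_fam) > 0L) {
    abort_data(sprintf(
      "%s line %d: family_id '%s' does not match expected '%s'",
      source, line_of(bad_fam[1]), hits$family_id[bad_fam[1]], family_id
    ))
  }
  bad_cov <- which(is.na(hits$coverage) | hits$coverage < 0 | hits$coverage > 1)
  if (length(bad_cov) > 0L) {
    abort_data(sprintf(
      "%s line %d: coverage %s outside [0, 1]",
      source, line_of(bad_cov[1]), format(hits$coverage[bad_cov[1]])
    ))
  }
  bad_e <- which(is.na(hits$evalue) | hits$evalue < 0)
  if (length(bad_e) > 0L) {
    abort_data(sprintf(
      "%s line %d: e-value must be a non-negative number", source, line_of(bad_e[1])
    ))
  }
  bad_idx <- which(is.na(hits$gene_index) | hits$gene_index < 0L)
  if (length(bad_idx) > 0L) {
    abort_data(sprintf(
      "%s line %d: gene_index must be a non-negative integer", source, line_of(bad_idx[1])
    ))
  }
  lens <- nchar(hits$aligned_seq)
  bad_len <- which(is.na(lens) | lens != profile_length)
  if (length(bad_len) > 0L) {
    abort_data(sprintf(
      "%s line %d: aligned_seq length %d does not equal profile length %d",
      source, line_of(bad_len[1]), lens[bad_len[1]], profile_length
    ))
  }
  bad_alpha <- which(!grepl("^[ACDEFGHIKLMNPQRSTVWY-]+$", hits$aligned_seq))
  if (length(bad_alpha) > 0L) {
    abort_data(sprintf(
      "%s line %d: aligned_seq contains characters outside the amino-acid alphabet and '-'",
      source, line_of(bad_alpha[1])
    ))
  }
  invisible(hits)
}

#' Write a homologue hit table
#'
#' Inverse of [read_hit_table()]; emits the documented TSV layout.
#'
#' @param hits Tibble of hits as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("family_id", "record_id", "gene_index", "evalue", "coverage", "aligned_seq")
  readr::write_tsv(hits[cols], path, progress = FALSE)
  invisible(path)
}

#' Filter homologue hits by coverage and e-value
#'
#' Keeps hits whose query coverage strictly exceeds `min_coverage` (the
#' ">60%" rule, hence the boundary value is dropped) and whose e-value is at
#' most `max_evalue` (cutoff semantics of profile-search tools). Input order
#' is preserved and the filter is idempotent.
#'
#' @param hits Tibble of hits (see [read_hit_table()]).
#' @param min_coverage Strict lower bound on coverage, in `[0, 1]`. Default 0.60.
#' @param max_evalue Inclusive upper bound on e-value. Default `1e-3`, the
#'   final-round cutoff of the upstream search schedule.
#' @return The surviving rows, same columns and order.
#' @export
filter_hits <- function(hits, min_coverage = 0.60, max_evalue = 1e-3) {
  if (!is_fraction(min_coverage)) {
    abort_validation("`min_coverage` must be a single value in [0, 1]")
  }
  if (!is.numeric(max_evalue) || length(max_evalue) != 1L || is.na(max_evalue)) {
    abort_validation("`max_evalue` must be a single finite-or-Inf number")
  }
  dplyr::filter(hits, .data$coverage > min_coverage, .data$evalue <= max_evalue)
}
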