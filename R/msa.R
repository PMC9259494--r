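#' Construct a paired (two-block) alignment
#'
#' A paired MSA is a tibble of rows `record_id`, `sequence` whose sequences
#' concatenate the block-A alignment (columns `1..len_a`, 1-based) with the
#' block-B alignment (columns `len_a+1 .. len_a+len_b`). The block partition
#' travels with the object as attributes `len_a`/`len_b`.
#'
#' @param rows Tibble or data frame with columns `record_id`, `sequence`.
#' @param len_a,len_b Block widths.
#' @return A `coevo_msa` tibble.
#' @export
paired_msa <- function(rows, len_a, len_b) {
  if (!is_count(len_a, min = 1L) || !is_count(len_b, min = 1L)) {
    abort_validation("`len_a` and `len_b` must be positive integers")
  }
  rows <- as_tibble(rows)[, c("record_id", "sequence")]
  bad <- which(nchar(rows$sequence) != len_a + len_b)
  if (length(bad) > 0L) {
    abort_data(sprintf(
      "sequence for record '%s' has length %d, expected len_a + len_b = %d",
      rows$record_id[bad[1]], nchar(rows$sequence[bad[1]]), len_a + len_b
    ))
  }
  structure(
    rows,
    len_a = as.integer(len_a), len_b = as.integer(len_b),
    class = c("coevo_msa", class(tibble()))
  )
}

#' @export
print.coevo_msa <- function(x, ...) {
  cat(sprintf(
    "<coevo_msa> %d rows, block A %d + block B %d columns\n",
    nrow(x), attr(x, "len_a"), attr(x, "len_b")
  ))
  NextMethod()
}

#' Block widths of a paired MSA
#'
#' @param msa A `coevo_msa`.
#' @return Named integer vector `c(len_a = , len_b = )`.
#' @export
msa_partition <- function(msa) {
  c(len_a = attr(msa, "len_a"), len_b = attr(msa, "len_b"))
}

#' Concatenate genome-paired homologues into a paired MSA
#'
#' One alignment row per paired record: the query-aligned family-A hit
#' followed by the family-B hit. Row order follows the input.
#'
#' @param pairs Tibble from [pair_by_locus()].
#' @param len_a,len_b Profile lengths of the two families.
#' @return A `coevo_msa`.
#' @export
build_paired_msa <- function(pairs, len_a, len_b) {
  bad_a <- which(nchar(pairs$aligned_seq_a) != len_a)
  if (length(bad_a) > 0L) {
    abort_data(sprintf(
      "record '%s': aligned_seq_a has length %d, expected %d",
      pairs$record_id[bad_a[1]], nchar(pairs$aligned_seq_a[bad_a[1]]), len_a
    ))
  }
  bad_b <- which(nchar(pairs$aligned_seq_b) != len_b)
  if (length(bad_b) > 0L) {
    abort_data(sprintf(
      "record '%s': aligned_seq_b has length %d, expected %d",
      pairs$record_id[bad_b[1]], nchar(pairs$aligned_seq_b[bad_b[1]]), len_b
    ))
  }
  paired_msa(
    tibble(
      record_id = pairs$record_id,
      sequence = paste0(pairs$aligned_seq_a, pairs$aligned_seq_b)
    ),
    len_a, len_b
  )
}

#' Drop over-gapped alignment rows
#'
#' Retains rows whose gap fraction (count of `-` over the full row width)
#' is at most `max_gap_ratio`. The boundary value is kept (`<=` semantics of
#' a "gap ratio <= 25%" rule). Order is preserved; the filter is idempotent.
#'
#' @param msa A `coevo_msa`.
#' @param max_gap_ratio Maximal tolerated gap fraction, default 0.25.
#' @return The filtered `coevo_msa`.
#' @export
gap_filter <- function(msa, max_gap_ratio = 0.25) {
  if (!is_fraction(max_gap_ratio)) {
    abort_validation("`max_gap_ratio` must be a single value in [0, 1]")
  }
  part <- msa_partition(msa)
  width <- sum(part)
  gap_frac <- stringr::str_count(msa$sequence, stringr::fixed("-")) / width
  paired_msa(msa[gap_frac <= max_gap_ratio, ], part[["len_a"]], part[["len_b"]])
}

#' Remove redundant alignment rows by pairwise identity
#'
#' Greedy keep-first scan in row order: a row is dropped when its identity
#' to any previously retained row exceeds `max_identity`. Identity is
#' matches over mutually non-gap columns (0 when the two rows share no
#' such column), the standard denominator in MSA curation. Deterministic,
#' idempotent, and order-preserving for the retained rows.
#'
#' @param msa A `coevo_msa`.
#' @param max_identity Maximal tolerated identity to a retained row; rows at
#'   exactly this identity are kept (`<=` semantics of "maximal identity
#'   <= 90%"). Default 0.90.
#' @return The filtered `coevo_msa`.
#' @export
redundancy_filter <- function(msa, max_identity = 0.90) {
  if (!is.numeric(max_identity) || length(max_identity) != 1L ||
      is.na(max_identity) || max_identity <= 0 || max_identity > 1) {
    abort_validation("`max_identity` must be a single value in (0, 1]")
  }
  part <- msa_partition(msa)
  n <- nrow(msa)
  if (n <= 1L) {
    return(msa)
  }
  enc <- encode_alignment(msa$sequence)
  keep <- logical(n)
  keep[1] <- TRUE
  kept_idx <- 1L
  for (r in 2:n) {
    cand <- enc[r, ]
    kept <- enc[kept_idx, , drop = FALSE]
    both <- !is.na(cand)[col(kept)] & !is.na(kept)
    eq <- both & (kept == matrix(cand, nrow = nrow(kept), ncol = ncol(kept), byrow = TRUE))
    valid <- rowSums(both)
    ident <- ifelse(valid == 0L, 0, rowSums(eq, na.rm = TRUE) / pmax(valid, 1L))
    if (all(ident <= max_identity)) {
      keep[r] <- TRUE
      kept_idx <- c(kept_idx, r)
    }
  }
  paired_msa(msa[keep, ], part[["len_a"]], part[["len_b"]])
}

#' Pairwise identity between two aligned sequences
#'
#' Matches over mutually non-gap columns; 0 when no such column exists.
#'
#' @param x,y Equal-length aligned sequences.
#' @return A fraction in `[0, 1]`.
#' @export
sequence_identity <- function(x, y) {
  enc <- encode_alignment(c(x, y))
  both <- !is.na(enc[1, ]) & !is.na(enc[2, ])
  if (!any(both)) {
    return(0)
  }
  sum(enc[1, both] == enc[2, both]) / sum(both)
}
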