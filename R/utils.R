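# Canonical 20-letter amino-acid alphabet; '-' marks an alignment gap.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# The e-value schedule of the upstream six-round iterative profile search.
# Carried as provenance metadata only; the search itself is out of scope.
HMM_SEARCH_EVALUE_SCHEDULE <- c(1e-12, 1e-12, 1e-12, 1e-12, 1e-6, 1e-3)

abort_validation <- function(message, ...) {
  abort(message, class = "coevomap_validation_error", ...)
}

abort_data <- function(message, ...) {
  abort(message, class = "coevomap_data_error", ...)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' Encode aligned sequences as an integer matrix
#'
#' Rows are sequences, columns are alignment columns. Residues map to
#' 1..20 in the order of the canonical alphabet; gaps and any
#' non-standard letter become `NA`.
#'
#' @param sequences Character vector of equal-length aligned sequences.
#' @return Integer matrix of dimension `length(sequences)` x alignment width.
#' @keywords internal
#' @noRd
encode_alignment <- function(sequences) {
  if (length(sequences) == 0L) {
    return(matrix(integer(), nrow = 0L, ncol = 0L))
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    abort_data("aligned sequences have unequal lengths")
  }
  chars <- matrix(
    unlist(strsplit(toupper(sequences), "", fixed = TRUE), use.names = FALSE),
    nrow = length(sequences), byrow = TRUE
  )
  m <- match(chars, AA_ALPHABET)
  dim(m) <- dim(chars)
  m
}

random_aa_string <- function(n, length) {
  vapply(
    seq_len(n),
    function(i) paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer regardless of the user's base seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
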