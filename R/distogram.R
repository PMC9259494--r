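# Distograms: per inter-protein residue pair, a probability distribution
# over discretised distance bins, the standard output shape of deep
# contact/distance predictors. Container is a long-format TSV
# `i  j  bin_lower  bin_upper  prob` (1-based residue indices; a row with
# bin_upper = Inf is the no-contact bin). Every (i, j) pair on the full
# len_a x len_b grid must carry the identical bin set.

#' Construct a distogram object
#'
#' @param prob Array of dim `(len_a, len_b, n_bins)`, each per-pair vector
#'   summing to 1 within `1e-4` (renormalised on construction).
#' @param bin_edges Ascending numeric vector of finite bin edges
#'   (length = number of finite bins + 1, first edge >= 0).
#' @param has_nocontact_bin If `TRUE` the last slice of `prob` is the
#'   catch-all "no contact" bin beyond the last finite edge.
#' @return A `coevo_distogram`.
#' @export
distogram <- function(prob, bin_edges, has_nocontact_bin = FALSE) {
  if (length(dim(prob)) != 3L) {
    abort_validation("`prob` must be a 3-d array (len_a, len_b, bins)")
  }
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    abort_data("bin edges must be strictly increasing")
  }
  if (bin_edges[1] < 0) {
    abort_data("first bin edge must be >= 0")
  }
  n_finite <- length(bin_edges) - 1L
  expected_bins <- n_finite + as.integer(has_nocontact_bin)
  if (dim(prob)[3] != expected_bins) {
    abort_data(sprintf(
      "probability tensor has %d bins but edges imply %d",
      dim(prob)[3], expected_bins
    ))
  }
  if (any(prob < 0)) {
    abort_data("probabilities must be non-negative")
  }
  sums <- apply(prob, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-4)) {
    worst <- which.max(abs(sums - 1))
    abort_data(sprintf(
      "per-pair probabilities must sum to 1 within 1e-4 (worst deviation %.2e)",
      max(abs(sums - 1))
    ))
  }
  prob <- prob / rep(sums, times = dim(prob)[3])  # exact renormalisation
  structure(
    list(
      len_a = dim(prob)[1], len_b = dim(prob)[2],
      bin_edges = bin_edges, has_nocontact_bin = has_nocontact_bin,
      prob = prob
    ),
    class = "coevo_distogram"
  )
}

#' @export
print.coevo_distogram <- function(x, ...) {
  cat(sprintf(
    "<coevo_distogram> %d x %d residue pairs, %d finite bins [%g, %g] A%s\n",
    x$len_a, x$len_b, length(x$bin_edges) - 1L,
    x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
    if (x$has_nocontact_bin) " + no-contact bin" else ""
  ))
  invisible(x)
}

#' Read a distogram from long-format TSV
#'
#' Expects a header `i  j  bin_lower  bin_upper  prob`; `bin_upper = Inf`
#' marks the no-contact bin. The grid must be complete and every pair must
#' carry the same bins, with strictly increasing edges read from the file
#' (never assumed).
#'
#' @param path Path to the TSV.
#' @return A `coevo_distogram`.
#' @export
read_distogram <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("distogram file not found: %s", path))
  }
  d <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      i = readr::col_integer(), j = readr::col_integer(),
      bin_lower = readr::col_double(), bin_upper = readr::col_double(),
      prob = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(d)
  if (nrow(probs) > 0L) {
    abort_data(sprintf(
      "malformed distogram %s at line %d", path, probs$row[1] + 1L
    ))
  }
  if (nrow(d) == 0L) {
    abort_data(sprintf("distogram %s contains no residue pairs", path))
  }
  bins <- dplyr::distinct(d[, c("bin_lower", "bin_upper")])
  bins <- arrange(bins, .data$bin_lower)
  has_nc <- any(!is.finite(bins$bin_upper))
  finite_bins <- dplyr::filter(bins, is.finite(.data$bin_upper))
  if (nrow(finite_bins) == 0L) {
    abort_data("distogram needs at least one finite distance bin")
  }
  edges <- c(finite_bins$bin_lower[1], finite_bins$bin_upper)
  if (any(diff(edges) <= 0) ||
      !isTRUE(all.equal(finite_bins$bin_lower,
                        edges[-length(edges)], tolerance = 1e-9))) {
    abort_data(sprintf(
      "distogram %s: bin edges are not ascending and contiguous", path
    ))
  }
  len_a <- max(d$i)
  len_b <- max(d$j)
  n_bins <- nrow(bins)
  expected <- len_a * len_b * n_bins
  if (nrow(d) != expected || min(d$i) < 1L || min(d$j) < 1L) {
    abort_data(sprintf(
      "distogram %s: expected a complete %d x %d grid with %d bins per pair (%d rows), found %d rows",
      path, len_a, len_b, n_bins, expected, nrow(d)
    ))
  }
  # bin order: finite bins ascending, no-contact bin (if any) last
  bin_order <- arrange(bins, !is.finite(.data$bin_upper), .data$bin_lower)
  bin_key <- paste(bin_order$bin_lower, bin_order$bin_upper)
  k <- match(paste(d$bin_lower, d$bin_upper), bin_key)
  prob <- array(NA_real_, dim = c(len_a, len_b, n_bins))
  prob[cbind(d$i, d$j, k)] <- d$prob
  if (anyNA(prob)) {
    abort_data(sprintf(
      "distogram %s: some residue pairs are missing bins", path
    ))
  }
  distogram(prob, edges, has_nocontact_bin = has_nc)
}

#' Write a distogram to long-format TSV
#'
#' @param d A `coevo_distogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distogram <- function(d, path) {
  n_finite <- length(d$bin_edges) - 1L
  lowers <- d$bin_edges[-length(d$bin_edges)]
  uppers <- d$bin_edges[-1]
  if (d$has_nocontact_bin) {
    lowers <- c(lowers, d$bin_edges[length(d$bin_edges)])
    uppers <- c(uppers, Inf)
  }
  grid <- expand.grid(
    i = seq_len(d$len_a), j = seq_len(d$len_b), bin = seq_along(lowers)
  )
  out <- tibble(
    i = grid$i, j = grid$j,
    bin_lower = lowers[grid$bin], bin_upper = uppers[grid$bin],
    prob = d$prob[cbind(grid$i, grid$j, grid$bin)]
  )
  out <- arrange(out, .data$i, .data$j, .data$bin_lower)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Aggregate distogram mass into contact probabilities
#'
#' The contact probability of residue pair (i, j) is the summed probability
#' of all distance bins whose upper edge is at or below `distance_cutoff`
#' (guaranteeing "distance <= cutoff" semantics whatever the bin grid); the
#' no-contact bin never contributes. The default 12 A cutoff is the
#' conventional C-alpha contact radius used throughout the package.
#'
#' @param d A `coevo_distogram`.
#' @param distance_cutoff Distance cutoff in Angstrom, within the binned
#'   range. Default 12.
#' @return A `coevo_scores` object (backend `"distogram"`, values in `[0, 1]`).
#' @export
aggregate_contact_probability <- function(d, distance_cutoff = 12.0) {
  edges <- d$bin_edges
  if (!is.numeric(distance_cutoff) || length(distance_cutoff) != 1L ||
      distance_cutoff < edges[1] || distance_cutoff > edges[length(edges)]) {
    abort_validation(sprintf(
      "`distance_cutoff` must lie within the binned range [%g, %g]",
      edges[1], edges[length(edges)]
    ))
  }
  uppers <- edges[-1]
  use <- which(uppers <= distance_cutoff)
  scores <- matrix(0, nrow = d$len_a, ncol = d$len_b)
  for (k in use) {
    scores <- scores + d$prob[, , k]
  }
  new_coevo_scores(
    inter = scores, backend = "distogram",
    params = list(distance_cutoff = distance_cutoff)
  )
}
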