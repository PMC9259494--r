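#' Select top co-evolving pairs from a ranked list
#'
#' Three selection rules, mirroring common reporting practice for predicted
#' contacts:
#' * `"threshold70"` — keep pairs scoring at least 70% of the top pair's
#'   score (typically yields a small displayable set);
#' * `"top:N"` — keep the first N ranked pairs (used where the 70% rule
#'   would keep too many, e.g. `top:30`);
#' * `"min_score:x"` — keep pairs scoring at least x.
#'
#' @param ranked Tibble from [rank_inter_pairs()], best first.
#' @param mode Selection rule string as above. Default `"threshold70"`.
#' @return The selected subset of `ranked`, order preserved.
#' @export
select_pairs <- function(ranked, mode = "threshold70") {
  if (!is.character(mode) || length(mode) != 1L) {
    abort_validation("`mode` must be a single string")
  }
  if (mode == "threshold70") {
    if (nrow(ranked) == 0L) {
      abort_validation("threshold70 selection needs a non-empty ranked list")
    }
    cut <- 0.7 * max(ranked$score)
    return(dplyr::filter(ranked, .data$score >= cut))
  }
  if (grepl("^top:[0-9]+$", mode)) {
    n <- as.integer(sub("^top:", "", mode))
    if (n < 1L) {
      abort_validation("top:N selection needs N >= 1")
    }
    return(head(ranked, n))
  }
  if (grepl("^min_score:", mode)) {
    x <- suppressWarnings(as.numeric(sub("^min_score:", "", mode)))
    if (is.na(x)) {
      abort_validation(sprintf("cannot parse selection mode '%s'", mode))
    }
    return(dplyr::filter(ranked, .data$score >= x))
  }
  abort_validation(sprintf(
    "unknown selection mode '%s' (use threshold70, top:N or min_score:x)", mode
  ))
}

#' Map selected pairs onto a multi-chain structure
#'
#' Annotates each (i, j) pair with its minimal cross-chain C-alpha distance,
#' its structural category (intra / homo_oligomeric / hetero_oligomeric) and
#' whether it falls within the interface (`min_distance <= contact_cutoff`).
#' Pairs unresolved in the structure are kept with `NA` distance, never
#' silently dropped.
#'
#' @param pairs Tibble with columns `i`, `j` (block-local profile columns)
#'   and optionally `score`, e.g. from [select_pairs()].
#' @param m A `coevo_structure`.
#' @param fam_a,fam_b Family ids of blocks A and B in the chain map.
#' @param contact_cutoff Interface distance cutoff in Angstrom; default 12,
#'   matching the distogram aggregation cutoff.
#' @return A `coevo_map` tibble: input columns plus `category`,
#'   `min_distance` and `within_interface`.
#' @export
map_pairs <- function(pairs, m, fam_a, fam_b, contact_cutoff = 12.0) {
  if (!is.numeric(contact_cutoff) || contact_cutoff <= 0) {
    abort_validation("`contact_cutoff` must be a positive distance")
  }
  out <- mutate(
    as_tibble(pairs),
    category = purrr::map2_chr(
      .data$i, .data$j, \(i, j) classify_pair(m, fam_a, i, fam_b, j)
    ),
    min_distance = purrr::map2_dbl(
      .data$i, .data$j, \(i, j) min_cross_distance(m, fam_a, i, fam_b, j)
    ),
    within_interface = .data$min_distance <= contact_cutoff
  )
  structure(
    out,
    contact_cutoff = contact_cutoff,
    families = c(a = fam_a, b = fam_b),
    class = c("coevo_map", class(tibble()))
  )
}

#' Fraction of mapped pairs lying within the interface
#'
#' Pairs with `min_distance <= contact_cutoff` over pairs with a computable
#' distance; unresolved pairs are excluded from the denominator (their count
#' is reported by [glance.coevo_map()]).
#'
#' @param selected A `coevo_map` (or tibble with `min_distance`).
#' @param contact_cutoff Distance cutoff in Angstrom; defaults to the cutoff
#'   stored on the `coevo_map`, else 12.
#' @return A fraction in `[0, 1]`.
#' @export
interface_precision <- function(selected, contact_cutoff = NULL) {
  contact_cutoff <- contact_cutoff %||% attr(selected, "contact_cutoff") %||% 12.0
  if (nrow(selected) == 0L) {
    abort_validation("cannot compute interface precision of an empty selection")
  }
  d <- selected$min_distance
  resolved <- d[!is.na(d)]
  if (length(resolved) == 0L) {
    abort_validation("no selected pair has a computable structure distance")
  }
  sum(resolved <= contact_cutoff) / length(resolved)
}

#' Summary of a structure-mapped selection
#'
#' @param x A `coevo_map`.
#' @param ... Unused.
#' @return One-row tibble: pair counts per category, unresolved count,
#'   cutoff, and interface precision.
#' @method glance coevo_map
#' @export
glance.coevo_map <- function(x, ...) {
  cutoff <- attr(x, "contact_cutoff")
  tibble(
    n_pairs = nrow(x),
    n_hetero = sum(x$category == "hetero_oligomeric", na.rm = TRUE),
    n_homo = sum(x$category == "homo_oligomeric", na.rm = TRUE),
    n_intra = sum(x$category == "intra", na.rm = TRUE),
    n_unresolved = sum(is.na(x$min_distance)),
    contact_cutoff = cutoff,
    precision = interface_precision(x, cutoff)
  )
}

#' Score-versus-distance plot of mapped pairs
#'
#' The diagnostic view of interface validation: each selected pair plotted
#' by co-evolution score against its minimal cross-chain C-alpha distance,
#' with the contact cutoff marked. Faithful predictions pile up left of the
#' cutoff line.
#'
#' @param object A `coevo_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coevo_map
#' @export
autoplot.coevo_map <- function(object, ...) {
  cutoff <- attr(object, "contact_cutoff")
  df <- dplyr::filter(as_tibble(object), !is.na(.data$min_distance))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$min_distance, y = .data$score, colour = .data$category
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = "minimal cross-chain Cα–Cα distance (Å)",
      y = "co-evolution score",
      title = "Selected co-evolving pairs on the structure"
    ) +
    ggplot2::theme_minimal()
}

#' Partner-residue hotspots among top-ranked pairs
#'
#' Collects the residue indices on one side of the top `top_k` ranked pairs
#' with occurrence counts — the mapping mode used when the partner protein
#' is absent from the structure and only one side can be displayed.
#'
#' @param ranked Tibble from [rank_inter_pairs()], best first.
#' @param side `"a"` or `"b"`: which block's residues to collect.
#' @param top_k Number of top pairs to use; default 50.
#' @return Tibble `residue`, `count`, most frequent first (ties by
#'   ascending residue).
#' @export
residue_hotspots <- function(ranked, side = c("b", "a"), top_k = 50L) {
  side <- match.arg(side)
  if (!is_count(top_k, min = 1L)) {
    abort_validation("`top_k` must be an integer >= 1")
  }
  if (nrow(ranked) == 0L) {
    abort_validation("`ranked` must be non-empty")
  }
  top <- head(ranked, top_k)
  res <- if (side == "a") top$i else top$j
  out <- count(tibble(residue = res), .data$residue, name = "count")
  arrange(out, desc(.data$count), .data$residue)
}
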