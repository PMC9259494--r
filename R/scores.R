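# Score container shared by both backends: an LA x LB inter-protein matrix,
# optionally flanked by the within-block matrices the MI backend also yields.

new_coevo_scores <- function(inter, backend, intra_a = NULL, intra_b = NULL,
                             params = list()) {
  stopifnot(is.matrix(inter))
  if (backend == "distogram" &&
      (any(inter < -1e-12) || any(inter > 1 + 1e-12))) {
    abort_data("distogram-backend scores must lie in [0, 1]")
  }
  structure(
    list(
      len_a = nrow(inter), len_b = ncol(inter),
      inter = inter, intra_a = intra_a, intra_b = intra_b,
      backend = backend, params = params
    ),
    class = "coevo_scores"
  )
}

#' @export
print.coevo_scores <- function(x, ...) {
  cat(sprintf(
    "<coevo_scores> backend '%s', %d x %d inter-protein pairs%s\n",
    x$backend, x$len_a, x$len_b,
    if (!is.null(x$intra_a)) " (+ intra-block matrices)" else ""
  ))
  cat(sprintf("  score range [%.4g, %.4g]\n",
              min(x$inter), max(x$inter)))
  invisible(x)
}

#' Tidy a score object into a long tibble
#'
#' @param x A `coevo_scores`.
#' @param block Which blocks to include: any of `"inter"`, `"intra_a"`,
#'   `"intra_b"`. Intra blocks are upper-triangle only (i < j) and reported
#'   in block-local 1-based coordinates.
#' @param ... Unused.
#' @return Tibble with columns `block`, `i`, `j`, `score`.
#' @method tidy coevo_scores
#' @export
tidy.coevo_scores <- function(x, block = "inter", ...) {
  block <- match.arg(block, c("inter", "intra_a", "intra_b"), several.ok = TRUE)
  out <- list()
  if ("inter" %in% block) {
    out$inter <- tibble(
      block = "inter",
      i = rep(seq_len(x$len_a), times = x$len_b),
      j = rep(seq_len(x$len_b), each = x$len_a),
      score = as.vector(x$inter)
    )
  }
  for (bl in intersect(c("intra_a", "intra_b"), block)) {
    m <- x[[bl]]
    if (is.null(m)) next
    ut <- which(upper.tri(m), arr.ind = TRUE)
    out[[bl]] <- tibble(
      block = bl, i = ut[, 1], j = ut[, 2], score = m[ut]
    )
  }
  bind_rows(out)
}

#' One-row summary of a score object
#'
#' @param x A `coevo_scores`.
#' @param ... Unused.
#' @return Tibble with backend, dimensions and inter-score range.
#' @method glance coevo_scores
#' @export
glance.coevo_scores <- function(x, ...) {
  tibble(
    backend = x$backend, len_a = x$len_a, len_b = x$len_b,
    n_inter_pairs = x$len_a * x$len_b,
    min_score = min(x$inter), max_score = max(x$inter)
  )
}

#' Contact-map heatmap of inter-protein scores
#'
#' @param object A `coevo_scores`.
#' @param ... Unused.
#' @return A ggplot: residue i (family A) vs residue j (family B),
#'   fill = score.
#' @method autoplot coevo_scores
#' @export
autoplot.coevo_scores <- function(object, ...) {
  df <- tidy(object, block = "inter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "score") +
    ggplot2::labs(
      x = "residue (family B)", y = "residue (family A)",
      title = sprintf("Inter-protein co-evolution scores (%s backend)", object$backend)
    ) +
    ggplot2::theme_minimal()
}

#' Rank inter-protein residue pairs by score
#'
#' Pairs scoring at least `min_score` (default 0.05, the conventional
#' reporting floor for aggregated contact probabilities) sorted by
#' descending score, ties broken by ascending `(i, j)`. Residue indices are
#' 1-based block-local profile columns.
#'
#' @param sm A `coevo_scores`.
#' @param min_score Inclusive score floor, default 0.05.
#' @param scope `"inter"` (default: hetero pairs only, the scope used when
#'   selecting pairs for structure mapping) or `"all"` to append the
#'   intra-block pairs when the backend provides them.
#' @return Tibble `block`, `i`, `j`, `score`, best first.
#' @export
rank_inter_pairs <- function(sm, min_score = 0.05, scope = c("inter", "all")) {
  scope <- match.arg(scope)
  if (!all(is.finite(sm$inter))) {
    abort_data("score matrix contains non-finite values")
  }
  blocks <- if (scope == "inter") "inter" else c("inter", "intra_a", "intra_b")
  df <- tidy(sm, block = blocks)
  df <- dplyr::filter(df, .data$score >= min_score)
  arrange(df, desc(.data$score), .data$block, .data$i, .data$j)
}

#' Write scores as TSV with a JSON provenance header
#'
#' First line is a `#`-prefixed JSON object recording backend and
#' parameters; then the long-format table `block  i  j  score`.
#'
#' @param sm A `coevo_scores`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sm, path) {
  scalar_params <- purrr::keep(sm$params, \(p) is.atomic(p) && length(p) == 1L)
  header <- jsonlite::toJSON(
    c(list(backend = sm$backend, len_a = sm$len_a, len_b = sm$len_b),
      scalar_params),
    auto_unbox = TRUE, digits = NA
  )
  df <- tidy(sm, block = c("inter", "intra_a", "intra_b"))
  writeLines(paste0("# ", header), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read scores written by [write_scores()]
#'
#' @param path Path to the scores TSV.
#' @return A `coevo_scores`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("score file not found: %s", path))
  }
  header_line <- readLines(path, n = 1L)
  if (!startsWith(header_line, "# ")) {
    abort_data(sprintf("%s lacks the JSON provenance header", path))
  }
  meta <- jsonlite::fromJSON(sub("^# ", "", header_line))
  df <- readr::read_tsv(path, skip = 1L, col_types = "ciid", progress = FALSE)
  inter <- matrix(NA_real_, meta$len_a, meta$len_b)
  di <- dplyr::filter(df, .data$block == "inter")
  inter[cbind(di$i, di$j)] <- di$score
  mk_intra <- function(bl, n) {
    db <- dplyr::filter(df, .data$block == bl)
    if (nrow(db) == 0L) return(NULL)
    m <- matrix(NA_real_, n, n)
    m[cbind(db$i, db$j)] <- db$score
    m[cbind(db$j, db$i)] <- db$score
    m
  }
  new_coevo_scores(
    inter,
    backend = meta$backend,
    intra_a = mk_intra("intra_a", meta$len_a),
    intra_b = mk_intra("intra_b", meta$len_b),
    params = meta[setdiff(names(meta), c("backend", "len_a", "len_b"))]
  )
}
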