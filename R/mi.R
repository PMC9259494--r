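# Mutual-information scorer with average-product correction (APC).
#
# A deliberately transparent, network-free backend: for every pair of
# alignment columns, MI in bits is computed from add-pseudocount empirical
# joint/marginal frequencies over the 20-letter alphabet, with rows gapped
# in either column excluded from that pair's counts (pairwise-complete
# deletion; gaps reflect alignment coverage, not residue identity). APC then
# subtracts the entropic/phylogenetic background:
#   score(i, j) = MI(i, j) - mean_i(MI) * mean_j(MI) / mean(MI)
# with means taken over the off-diagonal of the full (L_A+L_B)^2 matrix.

mi_from_counts <- function(counts) {
  total <- sum(counts)
  if (total <= 0) {
    return(0)
  }
  p <- counts / total
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  nz <- which(p > 0)
  expected <- outer(pi_, pj_)
  sum(p[nz] * log2(p[nz] / expected[nz]))
}

pair_mi <- function(ci, cj, pseudocount) {
  ok <- !is.na(ci) & !is.na(cj)
  if (sum(ok) < 2L) {
    return(NA_real_)  # flagged by the caller
  }
  counts <- matrix(pseudocount, 20L, 20L)
  tab <- tabulate((ci[ok] - 1L) * 20L + cj[ok], nbins = 400L)
  counts <- counts + matrix(tab, 20L, 20L, byrow = TRUE)
  mi_from_counts(counts)
}

apply_apc <- function(mi) {
  diag(mi) <- NA_real_
  row_mean <- rowMeans(mi, na.rm = TRUE)
  all_mean <- mean(mi[upper.tri(mi)], na.rm = TRUE)
  if (!is.finite(all_mean) || all_mean == 0) {
    return(mi)  # nothing to correct against (all-zero MI)
  }
  mi - outer(row_mean, row_mean) / all_mean
}

#' Mutual-information / APC co-evolution scores for a paired MSA
#'
#' Computes, for every pair of alignment columns, mutual information in bits
#' from pseudocounted contingency tables (pairwise-complete over non-gap
#' rows), applies the average-product correction over the full column set,
#' and returns the inter-protein block together with both within-block
#' matrices. Column pairs with fewer than two mutually ungapped rows score 0
#' and trigger one consolidated warning.
#'
#' @param msa A `coevo_msa` with at least 2 rows.
#' @param pseudocount Count added to every cell of each 20 x 20 joint table
#'   (Laplace default 1.0). `0` gives the plug-in estimator.
#' @return A `coevo_scores` with `backend = "mi_apc"`: `$inter` is
#'   `len_a x len_b` (APC-corrected), `$intra_a` / `$intra_b` are the
#'   symmetric within-block matrices (diagonal `NA`). The uncorrected MI
#'   matrix over all columns is attached as `$params$raw_mi`.
#' @export
mi_apc_scores <- function(msa, pseudocount = 1.0) {
  if (nrow(msa) < 2L) {
    abort_validation("MI scoring needs an alignment with at least 2 rows")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    abort_validation("`pseudocount` must be a single non-negative number")
  }
  part <- msa_partition(msa)
  la <- part[["len_a"]]
  lb <- part[["len_b"]]
  l <- la + lb
  enc <- encode_alignment(msa$sequence)
  cols <- lapply(seq_len(l), function(c) enc[, c])
  mi <- matrix(0, l, l)
  n_sparse <- 0L
  for (i in seq_len(l - 1L)) {
    ci <- cols[[i]]
    for (j in (i + 1L):l) {
      v <- pair_mi(ci, cols[[j]], pseudocount)
      if (is.na(v)) {
        n_sparse <- n_sparse + 1L
        v <- 0
      }
      mi[i, j] <- v
      mi[j, i] <- v
    }
  }
  if (n_sparse > 0L) {
    warn(sprintf(
      "%d column pair(s) had fewer than 2 mutually ungapped rows; scored 0",
      n_sparse
    ))
  }
  apc <- apply_apc(mi)
  new_coevo_scores(
    inter = apc[seq_len(la), la + seq_len(lb), drop = FALSE],
    intra_a = apc[seq_len(la), seq_len(la), drop = FALSE],
    intra_b = apc[la + seq_len(lb), la + seq_len(lb), drop = FALSE],
    backend = "mi_apc",
    params = list(pseudocount = pseudocount, raw_mi = mi)
  )
}
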