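# Independent brute-force MI/APC oracle, deliberately written on a
# different code path than the package scorer: character-level splitting,
# factor-based contingency tables, and explicit double-loop log sums.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_pair_mi <- function(chars_i, chars_j, pseudocount) {
  ok <- chars_i %in% ORACLE_AA & chars_j %in% ORACLE_AA
  if (sum(ok) < 2) {
    return(0)
  }
  tab <- table(
    factor(chars_i[ok], levels = ORACLE_AA),
    factor(chars_j[ok], levels = ORACLE_AA)
  )
  counts <- unclass(tab) + pseudocount
  total <- sum(counts)
  p <- counts / total
  pi_ <- apply(p, 1, sum)
  pj_ <- apply(p, 2, sum)
  mi <- 0
  for (a in 1:20) {
    for (b in 1:20) {
      if (p[a, b] > 0) {
        mi <- mi + p[a, b] * log2(p[a, b] / (pi_[a] * pj_[b]))
      }
    }
  }
  mi
}

oracle_mi_matrix <- function(sequences, pseudocount) {
  chars <- strsplit(sequences, "")
  l <- length(chars[[1]])
  cols <- lapply(seq_len(l), function(c) vapply(chars, `[`, "", c))
  mi <- matrix(0, l, l)
  for (i in seq_len(l)) {
    for (j in seq_len(l)) {
      if (i < j) {
        v <- oracle_pair_mi(cols[[i]], cols[[j]], pseudocount)
        mi[i, j] <- v
        mi[j, i] <- v
      }
    }
  }
  mi
}

oracle_apc_matrix <- function(mi) {
  diag(mi) <- NA
  l <- nrow(mi)
  row_mean <- numeric(l)
  for (i in seq_len(l)) {
    row_mean[i] <- mean(mi[i, -i])
  }
  vals <- mi[upper.tri(mi)]
  all_mean <- mean(vals)
  if (!is.finite(all_mean) || all_mean == 0) {
    return(mi)
  }
  out <- mi
  for (i in seq_len(l)) {
    for (j in seq_len(l)) {
      out[i, j] <- mi[i, j] - row_mean[i] * row_mean[j] / all_mean
    }
  }
  out
}

oracle_mi_apc <- function(msa, pseudocount) {
  part <- msa_partition(msa)
  la <- part[["len_a"]]
  lb <- part[["len_b"]]
  apc <- oracle_apc_matrix(oracle_mi_matrix(msa$sequence, pseudocount))
  list(
    inter = apc[seq_len(la), la + seq_len(lb), drop = FALSE],
    intra_a = apc[seq_len(la), seq_len(la), drop = FALSE],
    intra_b = apc[la + seq_len(lb), la + seq_len(lb), drop = FALSE]
  )
}

# Random gapped alignment for property sweeps.
random_test_msa <- function(n_rows, len_a, len_b, gap_rate = 0.1) {
  l <- len_a + len_b
  chars <- matrix(
    sample(ORACLE_AA, n_rows * l, replace = TRUE),
    nrow = n_rows
  )
  gaps <- matrix(runif(n_rows * l) < gap_rate, nrow = n_rows)
  chars[gaps] <- "-"
  paired_msa(
    tibble::tibble(
      record_id = sprintf("T%04d", seq_len(n_rows)),
      sequence = apply(chars, 1, paste, collapse = "")
    ),
    len_a, len_b
  )
}

# Exhaustive-enumeration distance oracle over all chain combinations.
oracle_min_cross <- function(m, fam_a, i, fam_b, j) {
  best <- Inf
  for (ca in names(m$chain_to_protein)) {
    if (m$chain_to_protein[[ca]] != fam_a) next
    for (cb in names(m$chain_to_protein)) {
      if (m$chain_to_protein[[cb]] != fam_b) next
      if (identical(fam_a, fam_b) && ca == cb) next
      da <- m$chains[[ca]]
      db <- m$chains[[cb]]
      ra <- which(da$resno == i)
      rb <- which(db$resno == j)
      if (length(ra) != 1 || length(rb) != 1) next
      d <- sqrt((da$x[ra] - db$x[rb])^2 + (da$y[ra] - db$y[rb])^2 +
                  (da$z[ra] - db$z[rb])^2)
      best <- min(best, d)
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

write_tmp_hit_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "family_id\trecord_id\tgene_index\tevalue\tcoverage\taligned_seq"
  writeLines(c(header, rows), path)
  path
}

make_hits <- function(family_id, record_id, gene_index, evalue, coverage,
                      aligned_seq) {
  tibble::tibble(
    family_id = family_id, record_id = record_id,
    gene_index = as.integer(gene_index), evalue = evalue,
    coverage = coverage, aligned_seq = aligned_seq
  )
}
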