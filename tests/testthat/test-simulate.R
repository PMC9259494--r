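test_that("genome simulation is empty at n=0 and reproducible under a seed", {
  empty <- sim_genome_hits(0, seed = 1)
  expect_equal(nrow(empty$hits_a), 0L)
  expect_equal(nrow(empty$hits_b), 0L)

  g1 <- sim_genome_hits(60, colocate_prob = 0.5, seed = 7)
  g2 <- sim_genome_hits(60, colocate_prob = 0.5, seed = 7)
  expect_identical(g1, g2)
  g3 <- sim_genome_hits(60, colocate_prob = 0.5, seed = 8)
  expect_false(identical(g1$hits_a, g3$hits_a))
})

test_that("planted co-located pairs are recovered at 100% recall through filtering", {
  g <- sim_genome_hits(120, colocate_prob = 0.6, max_separation = 20, seed = 3)
  fa <- filter_hits(g$hits_a)
  fb <- filter_hits(g$hits_b)
  pairs <- pair_by_locus(fa, fb, max_separation = 20)
  # every planted record is recovered with its planted loci
  expect_true(all(g$truth$record_id %in% pairs$record_id))
  merged <- dplyr::inner_join(pairs, g$truth, by = "record_id",
                              suffix = c("", ".truth"))
  expect_equal(merged$gene_index_a, merged$gene_index_a.truth)
  expect_equal(merged$gene_index_b, merged$gene_index_b.truth)
  # and nothing beyond the separation bound sneaks in
  expect_true(all(pairs$separation < 20))
  # planted pairs at separation >= max_separation are never recovered
  strict <- pair_by_locus(fa, fb, max_separation = 2)
  lost <- g$truth[g$truth$separation >= 2, ]
  expect_false(any(lost$record_id %in% strict$record_id))
  # decoy records exercise the filters: some hits fail coverage or e-value
  expect_true(nrow(fb) < nrow(g$hits_b))
})

test_that("coupled alignments have the requested shape and reject bad plantings", {
  planted <- tibble::tibble(i = c(2, 5), j = c(3, 1))
  sim <- sim_coupled_msa(6, 6, n_seqs = 500, planted = planted,
                         epsilon = 0.8, gap_rate = 0.05, seed = 2)
  expect_equal(nrow(sim$msa), 500L)
  expect_equal(msa_partition(sim$msa), c(len_a = 6L, len_b = 6L))

  expect_error(
    sim_coupled_msa(6, 6, 100, tibble::tibble(i = c(2, 2), j = c(3, 3))),
    "duplicate", class = "coevomap_validation_error"
  )
  expect_error(
    sim_coupled_msa(6, 6, 100, tibble::tibble(i = 9, j = 1)),
    class = "coevomap_validation_error"
  )
  # same seed, same alignment
  sim2 <- sim_coupled_msa(6, 6, n_seqs = 500, planted = planted,
                          epsilon = 0.8, gap_rate = 0.05, seed = 2)
  expect_identical(sim$msa$sequence, sim2$msa$sequence)
})

test_that("at epsilon=0 planted pairs are indistinguishable from background", {
  planted <- tibble::tibble(i = 1:3, j = 1:3)
  sim <- sim_coupled_msa(8, 8, n_seqs = 600, planted = planted,
                         epsilon = 0, gap_rate = 0, seed = 11)
  sm <- mi_apc_scores(sim$msa, pseudocount = 1)
  raw <- sm$params$raw_mi
  planted_mi <- raw[cbind(planted$i, 8 + planted$j)]
  inter_all <- raw[1:8, 9:16]
  background <- inter_all[-(match(
    paste(planted$i, planted$j),
    paste(rep(1:8, times = 8), rep(1:8, each = 8))
  ))]
  # planted means sit inside the background spread
  expect_lt(mean(planted_mi), mean(background) + 3 * sd(background))
  expect_gt(mean(planted_mi), mean(background) - 3 * sd(background))
})

test_that("at epsilon=1 without gaps planted MI equals the column entropy", {
  planted <- tibble::tibble(i = c(1, 4), j = c(2, 3))
  sim <- sim_coupled_msa(5, 5, n_seqs = 400, planted = planted,
                         epsilon = 1, gap_rate = 0, seed = 13)
  sm <- mi_apc_scores(sim$msa, pseudocount = 0)
  raw <- sm$params$raw_mi
  chars <- strsplit(sim$msa$sequence, "")
  for (p in seq_len(nrow(planted))) {
    col_i <- vapply(chars, `[`, "", planted$i[p])
    freqs <- table(col_i) / length(col_i)
    entropy <- -sum(freqs * log2(freqs))
    expect_equal(raw[planted$i[p], 5 + planted$j[p]], entropy,
                 tolerance = 1e-10)
  }
})

test_that("toy structures respect planted contact geometry exactly", {
  planted <- tibble::tibble(i = c(1, 4, 6), j = c(2, 5, 3))
  m <- sim_structure(6, 6, planted, n_copies_a = 2, n_copies_b = 2,
                     contact_distance = 8, far_distance = 20, seed = 5)
  is_planted <- matrix(FALSE, 6, 6)
  is_planted[cbind(planted$i, planted$j)] <- TRUE
  for (i in 1:6) {
    for (j in 1:6) {
      d <- min_cross_distance(m, "famA", i, "famB", j)
      if (is_planted[i, j]) {
        expect_lte(d, 8)
      } else {
        expect_gte(d, 20)
      }
    }
  }

  # rotated copies are isometries of the base unit
  fam_a_chains <- names(m$chain_to_protein)[m$chain_to_protein == "famA"]
  d_intra <- function(ch) {
    df <- m$chains[[ch]]
    as.matrix(dist(cbind(df$x, df$y, df$z)))
  }
  expect_equal(d_intra(fam_a_chains[1]), d_intra(fam_a_chains[2]),
               tolerance = 1e-9)

  # infeasible plantings are rejected
  expect_error(
    sim_structure(6, 6, tibble::tibble(i = c(1, 1, 1), j = c(2, 3, 4))),
    "2 planted pairs", class = "coevomap_validation_error"
  )
  # chained planting that would force a non-planted pair into contact
  expect_error(
    sim_structure(6, 6, tibble::tibble(i = c(1, 2, 2), j = c(2, 2, 3))),
    "non-planted", class = "coevomap_validation_error"
  )
})

test_that("bundles are internally consistent and seed-sensitive", {
  b <- sim_bundle(config = list(n_records = 60, n_planted = 4), seed = 9)
  expect_equal(nrow(b$truth_pairs), 4L)
  expect_equal(nrow(b$msa), nrow(b$truth_records))
  # aligned sequences embedded in the hit tables reconstruct the bundle MSA
  fa <- filter_hits(b$hits_a)
  fb <- filter_hits(b$hits_b)
  pairs <- pair_by_locus(fa, fb)
  msa <- build_paired_msa(pairs, 30, 30)
  expect_setequal(msa$sequence, b$msa$sequence)
  # structure realises the planted pairs
  for (p in seq_len(4)) {
    d <- min_cross_distance(b$structure, "famA", b$truth_pairs$i[p],
                            "famB", b$truth_pairs$j[p])
    expect_lte(d, b$params$contact_distance)
  }
  b2 <- sim_bundle(config = list(n_records = 60, n_planted = 4), seed = 10)
  expect_false(identical(b$msa$sequence, b2$msa$sequence))
  expect_identical(
    sim_bundle(config = list(n_records = 60, n_planted = 4), seed = 9)$msa,
    b$msa
  )

  expect_error(sim_bundle(config = list(bogus = 1)),
               class = "coevomap_validation_error")
})
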