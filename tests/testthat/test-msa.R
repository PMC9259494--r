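test_that("paired MSA concatenates blocks and tracks the partition", {
  pairs <- tibble::tibble(
    record_id = "R1", aligned_seq_a = "MKLV", aligned_seq_b = "AYE"
  )
  msa <- build_paired_msa(pairs, 4, 3)
  expect_equal(msa$sequence, "MKLVAYE")
  expect_equal(msa_partition(msa), c(len_a = 4L, len_b = 3L))

  three <- build_paired_msa(
    tibble::tibble(
      record_id = c("R1", "R2", "R3"),
      aligned_seq_a = c("MKLV", "MK-V", "AAAA"),
      aligned_seq_b = c("AYE", "A-E", "YYY")
    ), 4, 3
  )
  expect_equal(nrow(three), 3L)
  expect_true(all(nchar(three$sequence) == 7L))

  bad <- tibble::tibble(record_id = "Rbad", aligned_seq_a = "MKL",
                        aligned_seq_b = "AYE")
  expect_error(build_paired_msa(bad, 4, 3), "Rbad",
               class = "coevomap_data_error")
})

test_that("gap filter keeps the 25% boundary and is idempotent", {
  msa <- paired_msa(tibble::tibble(
    record_id = c("R1", "R2"),
    sequence = c("MK--LVAY",    # 2/8 = 25%: kept
                 "M---LVA-")    # 4/8 = 50%: removed
  ), 4, 4)
  kept <- gap_filter(msa, 0.25)
  expect_equal(kept$record_id, "R1")

  # 3 gaps in 8 columns (37.5%) removed at the same threshold
  msa3 <- paired_msa(tibble::tibble(record_id = "R3",
                                    sequence = "MKL---AY"), 4, 4)
  expect_equal(nrow(gap_filter(msa3, 0.25)), 0L)

  # gap-free alignment is untouched
  clean <- paired_msa(tibble::tibble(record_id = c("R1", "R2"),
                                     sequence = c("MKLVAYEW", "ACDEFGHI")), 4, 4)
  expect_equal(gap_filter(clean), clean)

  # gap fractions {0, 0.25, 0.26 -> 2/8..}, hand-counted survivors
  four <- paired_msa(tibble::tibble(
    record_id = sprintf("R%d", 1:4),
    sequence = c("MKLVAYEW", "MK--LVAY", "MK---VAY", "MKLV----")
  ), 4, 4)
  surv <- gap_filter(four, 0.25)
  expect_equal(surv$record_id, c("R1", "R2"))
  expect_equal(gap_filter(surv, 0.25), surv)
  expect_equal(msa_partition(surv), msa_partition(four))
})

test_that("greedy redundancy filter enforces the identity ceiling", {
  # identical 10-column rows: second dropped at <= 90%
  twin <- paired_msa(tibble::tibble(
    record_id = c("R1", "R2"),
    sequence = rep("MKLVAYEWCD", 2)
  ), 5, 5)
  expect_equal(redundancy_filter(twin, 0.90)$record_id, "R1")

  single <- paired_msa(tibble::tibble(record_id = "R1",
                                      sequence = "MKLVAYEWCD"), 5, 5)
  expect_equal(redundancy_filter(single), single)

  # r1~r2 identity 0.9 -> r2 dropped at 0.89; r3 at 0.5 to both retained
  r1 <- "MKLVAYEWCD"
  r2 <- "MKLVAYEWCA"                  # 9/10 to r1
  r3 <- "MKLVAGGGGG"                  # 5/10 to r1
  msa <- paired_msa(tibble::tibble(record_id = c("R1", "R2", "R3"),
                                   sequence = c(r1, r2, r3)), 5, 5)
  kept <- redundancy_filter(msa, 0.89)
  expect_equal(kept$record_id, c("R1", "R3"))
  # boundary: identity exactly equal to max_identity is retained
  expect_equal(redundancy_filter(msa, 0.90)$record_id, c("R1", "R2", "R3"))
  expect_equal(redundancy_filter(kept, 0.89), kept)
})

test_that("identity uses mutually non-gap columns only", {
  expect_equal(sequence_identity("MK-V", "MKLV"), 1.0)
  expect_equal(sequence_identity("MK-V", "MA-V"), 2 / 3)
  expect_equal(sequence_identity("--AB", "AB--"), 0)
})

test_that("after filtering no retained pair exceeds the identity ceiling", {
  withr::with_seed(7, {
    for (rep in 1:3) {
      base <- sample(ORACLE_AA, 12, replace = TRUE)
      rows <- vapply(1:15, function(r) {
        mut <- base
        k <- sample(0:8, 1)
        pos <- sample(12, k)
        mut[pos] <- sample(ORACLE_AA, k, replace = TRUE)
        paste(mut, collapse = "")
      }, "")
      msa <- paired_msa(tibble::tibble(
        record_id = sprintf("R%02d", 1:15), sequence = rows
      ), 6, 6)
      kept <- redundancy_filter(msa, 0.75)
      if (nrow(kept) > 1) {
        combos <- utils::combn(nrow(kept), 2)
        idents <- apply(combos, 2, function(p) {
          sequence_identity(kept$sequence[p[1]], kept$sequence[p[2]])
        })
        expect_true(all(idents <= 0.75))
      }
      expect_equal(redundancy_filter(kept, 0.75), kept)
    }
  })
})

test_that("FASTA and Stockholm round trips preserve rows and partition", {
  msa <- paired_msa(tibble::tibble(
    record_id = c("REC00001", "REC00002"),
    sequence = c("MK-VAYE", "ACDEFGH")
  ), 4, 3)
  fa <- tempfile(fileext = ".fasta")
  write_paired_msa(msa, fa, format = "fasta")
  back <- read_paired_msa(fa)
  expect_equal(as.data.frame(back), as.data.frame(msa))
  expect_equal(msa_partition(back), msa_partition(msa))

  sto <- tempfile(fileext = ".sto")
  write_paired_msa(msa, sto, format = "stockholm")
  back2 <- read_paired_msa(sto)
  expect_equal(back2$sequence, msa$sequence)
  expect_equal(msa_partition(back2), msa_partition(msa))
})
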