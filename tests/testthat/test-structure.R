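toy_structure <- function(chains, chain_map, offsets = NULL) {
  coevomap:::new_structure_model(chains, chain_map, offsets)
}

xyz_chain <- function(coords) {
  tibble::tibble(
    resno = seq_len(nrow(coords)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
}

test_that("a minimal PDB file loads as one chain with two residues", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  m <- load_structure(path, chain_map = c(A = "famA"))
  expect_equal(names(m$chains), "A")
  expect_equal(nrow(m$chains$A), 2L)
  expect_equal(m$chains$A$x, c(0, 3.8))

  expect_error(load_structure(path, chain_map = c(Z = "famA")),
               "absent", class = "coevomap_data_error")
})

test_that("a hand-written mmCIF fixture loads with two mapped chains", {
  path <- tempfile(fileext = ".cif")
  fields <- c(
    "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
    "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
  )
  atom_line <- function(id, chain, resno, x, y, z) {
    sprintf("ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s CA 1",
            id, chain, resno, x, y, z, resno, chain)
  }
  writeLines(c(
    "data_toy", "#", "loop_", paste0("_atom_site.", fields),
    atom_line(1, "X", 1, 0, 0, 0),
    atom_line(2, "X", 2, 3, 0, 0),
    atom_line(3, "X", 3, 6, 0, 0),
    atom_line(4, "Y", 1, 0, 4, 0),
    atom_line(5, "Y", 2, 3, 4, 0),
    atom_line(6, "Y", 3, 6, 4, 0),
    "#"
  ), path)
  m <- load_structure(path, chain_map = c(X = "famA", Y = "famB"))
  expect_setequal(names(m$chains), c("X", "Y"))
  expect_equal(nrow(m$chains$X), 3L)
  expect_equal(min_cross_distance(m, "famA", 1, "famB", 1), 4)
})

test_that("CA-only PDB writing round trips through the loader", {
  m <- sim_structure(4, 4, tibble::tibble(i = 1, j = 2),
                     n_copies_a = 2, n_copies_b = 2, seed = 3)
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(m, path)
  back <- load_structure(path, chain_map = m$chain_to_protein)
  for (ch in names(m$chains)) {
    # PDB coordinates carry 3 decimals: absolute agreement to 5e-4
    expect_lt(max(abs(back$chains[[ch]]$x - m$chains[[ch]]$x)), 1e-3)
    expect_lt(max(abs(back$chains[[ch]]$z - m$chains[[ch]]$z)), 1e-3)
  }
})

test_that("minimal cross-chain distance follows hand geometry", {
  # coincident residues are at distance 0
  m0 <- toy_structure(
    list(A = xyz_chain(matrix(c(0, 0, 0), 1)),
         B = xyz_chain(matrix(c(0, 0, 0), 1))),
    c(A = "famA", B = "famB")
  )
  expect_equal(min_cross_distance(m0, "famA", 1, "famB", 1), 0)

  # two copies of B place residue 1 at (3,4,0) and (10,0,0): min is 5
  m1 <- toy_structure(
    list(A = xyz_chain(matrix(c(0, 0, 0), 1)),
         B = xyz_chain(matrix(c(3, 4, 0), 1)),
         C = xyz_chain(matrix(c(10, 0, 0), 1))),
    c(A = "famA", B = "famB", C = "famB")
  )
  expect_equal(min_cross_distance(m1, "famA", 1, "famB", 1), 5)
  # symmetric in the two residue arguments
  expect_equal(min_cross_distance(m1, "famB", 1, "famA", 1), 5)

  # same family: only distinct-chain combinations count
  mh <- toy_structure(
    list(A = xyz_chain(matrix(c(0, 0, 0, 30, 0, 0), 2, byrow = TRUE)),
         B = xyz_chain(matrix(c(0, 6, 0, 30, 6, 0), 2, byrow = TRUE))),
    c(A = "famA", B = "famA")
  )
  expect_equal(min_cross_distance(mh, "famA", 1, "famA", 2),
               sqrt(30^2 + 6^2))

  expect_error(min_cross_distance(m0, "nope", 1, "famB", 1),
               "unknown family", class = "coevomap_data_error")
})

test_that("distances equal exhaustive enumeration on symmetric multi-copy structures", {
  withr::with_seed(9, {
    for (copies in c(2, 3, 6)) {
      planted <- tibble::tibble(i = c(1, 3), j = c(2, 4))
      m <- sim_structure(5, 5, planted, n_copies_a = copies,
                         n_copies_b = copies, seed = copies)
      for (i in 1:5) {
        for (j in 1:5) {
          expect_equal(
            min_cross_distance(m, "famA", i, "famB", j),
            oracle_min_cross(m, "famA", i, "famB", j)
          )
        }
      }
      # homo-family distances also match enumeration
      expect_equal(
        min_cross_distance(m, "famA", 1, "famA", 2),
        oracle_min_cross(m, "famA", 1, "famA", 2)
      )
    }
  })
})

test_that("pair classification applies the cross-vs-within rule and ignores chain labels", {
  # hetero families are always hetero_oligomeric
  m <- sim_structure(3, 3, tibble::tibble(i = 1, j = 1), seed = 1)
  expect_equal(classify_pair(m, "famA", 1, "famB", 1), "hetero_oligomeric")

  # same family: within-chain 30 A, cross-chain 6 A -> homo_oligomeric
  mh <- toy_structure(
    list(A = xyz_chain(matrix(c(0, 0, 0, 30, 0, 0), 2, byrow = TRUE)),
         B = xyz_chain(matrix(c(0, 6, 0, 30, 6, 0), 2, byrow = TRUE))),
    c(A = "famA", B = "famA")
  )
  # residue 1 chain A vs residue 2 chain B: cross = sqrt(30^2+6^2) ~ 30.6,
  # within = 30 -> intra; make a genuinely close cross pair instead:
  mc <- toy_structure(
    list(A = xyz_chain(matrix(c(0, 0, 0, 30, 0, 0), 2, byrow = TRUE)),
         B = xyz_chain(matrix(c(24, 6, 0, -6, 6, 0), 2, byrow = TRUE))),
    c(A = "famA", B = "famA")
  )
  # cross-chain (1 in A, 2 in B) = sqrt(6^2+6^2) ~ 8.49 < within 30
  expect_equal(classify_pair(mc, "famA", 1, "famA", 2), "homo_oligomeric")
  expect_equal(classify_pair(mh, "famA", 1, "famA", 2), "intra")

  # relabelling chains must not change the outcome
  relabel <- function(m, new_names) {
    chains <- m$chains
    names(chains) <- new_names[names(chains)]
    cmap <- m$chain_to_protein
    names(cmap) <- new_names[names(cmap)]
    toy_structure(chains, cmap)
  }
  swapped <- relabel(mc, c(A = "Q", B = "P"))
  expect_equal(classify_pair(swapped, "famA", 1, "famA", 2), "homo_oligomeric")
  m6 <- sim_structure(4, 4, tibble::tibble(i = 2, j = 3),
                      n_copies_a = 3, n_copies_b = 3, seed = 2)
  perm <- setNames(rev(names(m6$chains)), names(m6$chains))
  m6r <- relabel(m6, perm)
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(classify_pair(m6r, "famA", i, "famB", j),
                   classify_pair(m6, "famA", i, "famB", j))
    }
  }
})

test_that("unresolved residues yield NA distances, not errors", {
  m <- toy_structure(
    list(A = xyz_chain(matrix(c(0, 0, 0), 1)),
         B = xyz_chain(matrix(c(1, 0, 0), 1))),
    c(A = "famA", B = "famB")
  )
  expect_true(is.na(min_cross_distance(m, "famA", 5, "famB", 1)))
})

test_that("profile-column offsets map columns to author residue numbers", {
  ch <- tibble::tibble(resno = 101:103, x = c(0, 3, 6), y = 0, z = 0)
  m <- toy_structure(list(A = ch, B = tibble::tibble(resno = 1, x = 0, y = 4, z = 0)),
                     c(A = "famA", B = "famB"),
                     offsets = c(famA = 100L, famB = 0L))
  expect_equal(min_cross_distance(m, "famA", 1, "famB", 1), 4)
  expect_equal(min_cross_distance(m, "famA", 3, "famB", 1), sqrt(36 + 16))
})
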