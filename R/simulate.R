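# Seeded synthetic data with known ground truth: genome hit tables in which
# two families co-occur near each other on some records, paired alignments
# with planted coupled column pairs, and toy symmetric multi-chain
# structures in which exactly the planted pairs are in contact. Together
# they let every pipeline stage be tested end-to-end with no downloads.

#' Simulate homologue hit tables for two co-occurring families
#'
#' Draws `n_records` nucleotide records. With probability `colocate_prob` a
#' record carries one hit of each family separated by fewer than
#' `max_separation` coding genes, with coverage/e-value drawn to pass the
#' default filters — these records are the planted truth and must survive
#' filtering. The remaining records exercise the filters: a far-separated
#' pair, a single-family record, or a co-located pair whose coverage or
#' e-value fails the default thresholds.
#'
#' @param n_records Number of records to draw (>= 0).
#' @param colocate_prob Probability a record is a planted co-located pair.
#' @param max_separation Separation bound the planted pairs respect
#'   (strictly below), default 20.
#' @param len_a,len_b Profile lengths used for the random aligned sequences.
#' @param fam_a,fam_b Family ids written into the tables.
#' @param seed Integer seed; same seed, same tables.
#' @return List with tibbles `hits_a`, `hits_b`, and `truth` (one row per
#'   planted record: `record_id`, `gene_index_a`, `gene_index_b`,
#'   `separation`).
#' @export
sim_genome_hits <- function(n_records, colocate_prob = 0.8,
                            max_separation = 20L, len_a = 30L, len_b = 30L,
                            fam_a = "famA", fam_b = "famB", seed = 1L) {
  if (!is_count(n_records)) {
    abort_validation("`n_records` must be a non-negative integer")
  }
  if (!is_fraction(colocate_prob)) {
    abort_validation("`colocate_prob` must be in [0, 1]")
  }
  empty_hits <- function(fam) tibble(
    family_id = character(), record_id = character(), gene_index = integer(),
    evalue = double(), coverage = double(), aligned_seq = character()
  )
  if (n_records == 0L) {
    return(list(
      hits_a = empty_hits(fam_a), hits_b = empty_hits(fam_b),
      truth = tibble(record_id = character(), gene_index_a = integer(),
                     gene_index_b = integer(), separation = integer())
    ))
  }
  withr::with_seed(seed, {
    rows_a <- list()
    rows_b <- list()
    truth <- list()
    pass_cov <- function() runif(1, 0.65, 0.99)
    fail_cov <- function() runif(1, 0.10, 0.60)
    pass_e <- function() 10^runif(1, -30, -5)
    fail_e <- function() 10^runif(1, -2, 0)
    for (r in seq_len(n_records)) {
      rid <- sprintf("REC%05d", r)
      gi_a <- sample(0:49, 1)
      colocated <- runif(1) < colocate_prob
      if (colocated) {
        sep <- sample(1:(max_separation - 1L), 1)
        gi_b <- gi_a + sep
        rows_a[[rid]] <- tibble(
          family_id = fam_a, record_id = rid, gene_index = gi_a,
          evalue = pass_e(), coverage = pass_cov(),
          aligned_seq = random_aa_string(1, len_a)
        )
        rows_b[[rid]] <- tibble(
          family_id = fam_b, record_id = rid, gene_index = gi_b,
          evalue = pass_e(), coverage = pass_cov(),
          aligned_seq = random_aa_string(1, len_b)
        )
        truth[[rid]] <- tibble(
          record_id = rid, gene_index_a = gi_a, gene_index_b = gi_b,
          separation = sep
        )
      } else {
        decoy <- sample(c("far", "single", "lowcov", "highe"), 1)
        if (decoy == "single") {
          rows_a[[rid]] <- tibble(
            family_id = fam_a, record_id = rid, gene_index = gi_a,
            evalue = pass_e(), coverage = pass_cov(),
            aligned_seq = random_aa_string(1, len_a)
          )
        } else {
          gi_b <- if (decoy == "far") {
            gi_a + max_separation + sample(0:30, 1)
          } else {
            gi_a + sample(1:(max_separation - 1L), 1)
          }
          cov_b <- if (decoy == "lowcov") fail_cov() else pass_cov()
          e_b <- if (decoy == "highe") fail_e() else pass_e()
          rows_a[[rid]] <- tibble(
            family_id = fam_a, record_id = rid, gene_index = gi_a,
            evalue = pass_e(), coverage = pass_cov(),
            aligned_seq = random_aa_string(1, len_a)
          )
          rows_b[[rid]] <- tibble(
            family_id = fam_b, record_id = rid, gene_index = gi_b,
            evalue = e_b, coverage = cov_b,
            aligned_seq = random_aa_string(1, len_b)
          )
        }
      }
    }
    list(
      hits_a = bind_rows(rows_a), hits_b = bind_rows(rows_b),
      truth = if (length(truth)) bind_rows(truth) else
        tibble(record_id = character(), gene_index_a = integer(),
               gene_index_b = integer(), separation = integer())
    )
  })
}

#' Simulate a paired MSA with planted coupled column pairs
#'
#' Background columns are drawn independently from per-column random
#' profiles (flat-Dirichlet over the 20 letters). For each planted pair
#' (i, j) — i a block-A column, j a block-B column — a fixed random
#' one-to-one state mapping couples the two columns: with probability
#' `epsilon` the block-B state is the mapped image of the block-A state,
#' otherwise both are drawn independently. At `epsilon = 1` (no gaps) the
#' pair's mutual information equals the block-A column entropy, giving a
#' closed-form check. Gaps are injected uniformly at `gap_rate`.
#'
#' @param len_a,len_b Block widths.
#' @param n_seqs Number of alignment rows (>= 2).
#' @param planted Tibble or data frame with columns `i` (1..len_a) and
#'   `j` (1..len_b); duplicate pairs are rejected.
#' @param epsilon Coupling strength in `[0, 1]`; default 0.9.
#' @param gap_rate Per-cell gap probability; default 0.05.
#' @param seed Integer seed.
#' @return List: `msa` (a `coevo_msa`, row ids `SIM00001`...), `truth`
#'   (the planted pairs), `params`.
#' @export
sim_coupled_msa <- function(len_a, len_b, n_seqs, planted, epsilon = 0.9,
                            gap_rate = 0.05, seed = 1L) {
  if (!is_count(n_seqs, min = 2L)) {
    abort_validation("`n_seqs` must be an integer >= 2")
  }
  if (!is_fraction(epsilon) || !is_fraction(gap_rate)) {
    abort_validation("`epsilon` and `gap_rate` must be fractions in [0, 1]")
  }
  planted <- as_tibble(planted)
  if (nrow(planted) > 0L) {
    if (any(planted$i < 1L | planted$i > len_a |
            planted$j < 1L | planted$j > len_b)) {
      abort_validation("planted pairs out of block bounds")
    }
    if (anyDuplicated(planted[, c("i", "j")]) > 0L) {
      abort_validation("duplicate planted pairs")
    }
  }
  l <- len_a + len_b
  withr::with_seed(seed, {
    # per-column profiles: flat Dirichlet over the 20 states
    profiles <- matrix(rgamma(20L * l, shape = 1), nrow = 20L)
    profiles <- sweep(profiles, 2, colSums(profiles), "/")
    states <- matrix(0L, nrow = n_seqs, ncol = l)
    for (c in seq_len(l)) {
      states[, c] <- sample.int(20L, n_seqs, replace = TRUE, prob = profiles[, c])
    }
    if (nrow(planted) > 0L) {
      for (p in seq_len(nrow(planted))) {
        ci <- planted$i[p]
        cj <- len_a + planted$j[p]
        sigma <- sample.int(20L)  # fixed one-to-one state mapping
        coupled <- runif(n_seqs) < epsilon
        states[coupled, cj] <- sigma[states[coupled, ci]]
      }
    }
    chars <- matrix(AA_ALPHABET[states], nrow = n_seqs)
    if (gap_rate > 0) {
      gaps <- matrix(runif(n_seqs * l) < gap_rate, nrow = n_seqs)
      chars[gaps] <- "-"
    }
    msa <- paired_msa(
      tibble(
        record_id = sprintf("SIM%05d", seq_len(n_seqs)),
        sequence = apply(chars, 1, paste, collapse = "")
      ),
      len_a, len_b
    )
    list(
      msa = msa, truth = planted,
      params = list(len_a = len_a, len_b = len_b, n_seqs = n_seqs,
                    epsilon = epsilon, gap_rate = gap_rate, seed = seed)
    )
  })
}

rotate_z <- function(xyz, theta) {
  r <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), nrow = 3)
  xyz %*% t(r)
}

#' Simulate a toy symmetric multi-chain structure with planted contacts
#'
#' Places C-alpha positions so that every planted inter-family pair is
#' within `contact_distance` (inside one chain-copy unit) and every other
#' inter-family pair is at least `far_distance` apart, across all copies.
#' Copies are generated by rotating the base unit about a common z axis at
#' a radius large enough to keep copies mutually distant. Residues coupled
#' by planting are clustered in a shared cell; all remaining residues
#' occupy well-separated grid cells.
#'
#' @param len_a,len_b Number of residues per family.
#' @param planted Tibble with planted pairs `i`, `j` (block-local columns).
#'   Pairs must form star-shaped groups whose internal inter-family pairs
#'   are all planted, with at most 2 planted pairs per residue; otherwise
#'   the geometry is infeasible and an error is raised.
#' @param n_copies_a,n_copies_b Number of symmetric chain copies (>= 1).
#' @param contact_distance Planted-pair distance bound in Angstrom, default 8.
#' @param far_distance Minimal distance for all other inter-family pairs,
#'   default 20.
#' @param fam_a,fam_b Family ids used in the chain map.
#' @param seed Integer seed (controls in-cell jitter only).
#' @return A `coevo_structure` whose chain map assigns the first
#'   `n_copies_a` copies to `fam_a` and `n_copies_b` to `fam_b`.
#' @export
sim_structure <- function(len_a, len_b, planted, n_copies_a = 1L,
                          n_copies_b = 1L, contact_distance = 8.0,
                          far_distance = 20.0, fam_a = "famA", fam_b = "famB",
                          seed = 1L) {
  if (!is_count(n_copies_a, 1L) || !is_count(n_copies_b, 1L)) {
    abort_validation("copy counts must be integers >= 1")
  }
  if (contact_distance <= 0 || far_distance <= contact_distance) {
    abort_validation("need 0 < contact_distance < far_distance")
  }
  planted <- as_tibble(planted)
  # group residues coupled by planting (union-find over planted pairs)
  node_id <- function(side, k) paste0(side, k)
  parent <- new.env()
  find <- function(x) {
    while (!identical(get0(x, envir = parent, ifnotfound = x), x)) {
      x <- get(x, envir = parent)
    }
    x
  }
  union <- function(x, y) assign(find(x), find(y), envir = parent)
  if (nrow(planted) > 0L) {
    deg <- table(c(node_id("A", planted$i), node_id("B", planted$j)))
    if (any(deg > 2L)) {
      abort_validation(
        "infeasible planting: more than 2 planted pairs on one residue"
      )
    }
    for (p in seq_len(nrow(planted))) {
      union(node_id("A", planted$i[p]), node_id("B", planted$j[p]))
    }
    comp_a <- vapply(planted$i, function(k) find(node_id("A", k)), "")
    groups <- split(seq_len(nrow(planted)), comp_a)
    for (g in groups) {
      ia <- unique(planted$i[g])
      jb <- unique(planted$j[g])
      # every inter-family pair inside a cluster must itself be planted,
      # otherwise it cannot simultaneously be "far"
      if (length(g) != length(ia) * length(jb)) {
        abort_validation(
          "infeasible planting: a coupled residue group contains non-planted inter-family pairs"
        )
      }
    }
  } else {
    groups <- list()
  }
  spacing <- far_distance + 2 * contact_distance
  withr::with_seed(seed, {
    pos_a <- matrix(NA_real_, nrow = len_a, ncol = 3)
    pos_b <- matrix(NA_real_, nrow = len_b, ncol = 3)
    # enumerate well-separated grid cells
    side_n <- ceiling((2 * (len_a + len_b))^(1 / 3)) + 1L
    grid <- as.matrix(expand.grid(
      x = seq_len(side_n), y = seq_len(side_n), z = seq_len(side_n)
    )) * spacing
    cell <- 0L
    next_cell <- function() {
      cell <<- cell + 1L
      grid[cell, ]
    }
    in_ball <- function(center, r) {
      center + runif(3, -r / sqrt(3), r / sqrt(3))
    }
    for (g in groups) {
      center <- next_cell()
      for (i in unique(planted$i[g])) {
        pos_a[i, ] <- in_ball(center, contact_distance / 2)
      }
      for (j in unique(planted$j[g])) {
        pos_b[j, ] <- in_ball(center, contact_distance / 2)
      }
    }
    for (i in which(is.na(pos_a[, 1]))) pos_a[i, ] <- in_ball(next_cell(), 1)
    for (j in which(is.na(pos_b[, 1]))) pos_b[j, ] <- in_ball(next_cell(), 1)
  })
  unit <- rbind(pos_a, pos_b)
  center <- colMeans(unit)
  unit <- sweep(unit, 2, center)
  n_units <- max(n_copies_a, n_copies_b)
  if (n_units > 1L) {
    r_max <- max(sqrt(rowSums(unit^2)))
    radius <- (2 * r_max + far_distance) / (2 * sin(pi / n_units))
  } else {
    radius <- 0
  }
  unit <- sweep(unit, 2, c(radius, 0, 0), "+")
  chains <- list()
  chain_map <- character(0)
  chain_ids <- c(LETTERS, letters)
  next_chain <- 0L
  for (u in seq_len(n_units)) {
    rotated <- rotate_z(unit, 2 * pi * (u - 1) / n_units)
    if (u <= n_copies_a) {
      next_chain <- next_chain + 1L
      ch <- chain_ids[next_chain]
      chains[[ch]] <- tibble(
        resno = seq_len(len_a),
        x = rotated[seq_len(len_a), 1],
        y = rotated[seq_len(len_a), 2],
        z = rotated[seq_len(len_a), 3]
      )
      chain_map[ch] <- fam_a
    }
    if (u <= n_copies_b) {
      next_chain <- next_chain + 1L
      ch <- chain_ids[next_chain]
      chains[[ch]] <- tibble(
        resno = seq_len(len_b),
        x = rotated[len_a + seq_len(len_b), 1],
        y = rotated[len_a + seq_len(len_b), 2],
        z = rotated[len_a + seq_len(len_b), 3]
      )
      chain_map[ch] <- fam_b
    }
  }
  m <- new_structure_model(chains, chain_map)
  assert_planted_geometry(m, planted, len_a, len_b, fam_a, fam_b,
                          contact_distance, far_distance)
  m
}

# constructive guarantee, verified: planted pairs in contact, others far
assert_planted_geometry <- function(m, planted, len_a, len_b, fam_a, fam_b,
                                    contact_distance, far_distance) {
  is_planted <- matrix(FALSE, len_a, len_b)
  if (nrow(planted) > 0L) {
    is_planted[cbind(planted$i, planted$j)] <- TRUE
  }
  for (i in seq_len(len_a)) {
    for (j in seq_len(len_b)) {
      d <- min_cross_distance(m, fam_a, i, fam_b, j)
      if (is_planted[i, j] && d > contact_distance) {
        abort_data(sprintf(
          "internal geometry failure: planted pair (%d, %d) at %.1f A", i, j, d
        ))
      }
      if (!is_planted[i, j] && d < far_distance) {
        abort_data(sprintf(
          "internal geometry failure: non-planted pair (%d, %d) at %.1f A", i, j, d
        ))
      }
    }
  }
  invisible(m)
}

#' Default configuration of the synthetic bundle
#'
#' The study conditions emulated by [sim_bundle()]: two 30-column families,
#' 500 nucleotide records of which ~80% carry a co-located pair, 10 planted
#' coupled column pairs at coupling 0.9, 5% gaps, and a 2+2-copy symmetric
#' toy structure with planted contacts within 8 A and everything else
#' beyond 20 A.
#'
#' @return Named list of generator parameters.
#' @export
bundle_defaults <- function() {
  list(
    len_a = 30L, len_b = 30L,
    n_records = 500L, colocate_prob = 0.8,
    max_separation = 20L,
    n_planted = 10L, epsilon = 0.9, gap_rate = 0.05,
    n_copies_a = 2L, n_copies_b = 2L,
    contact_distance = 8.0, far_distance = 20.0,
    fam_a = "famA", fam_b = "famB"
  )
}

#' Generate a consistent synthetic bundle: genomes + coupled MSA + structure
#'
#' Orchestrates the three generators so the planted truth is recoverable
#' end-to-end: co-located genome records carry the rows of a coupled paired
#' alignment as their aligned sequences, and the toy structure realises
#' exactly the planted column pairs as inter-family contacts.
#'
#' @param config Named list of generator parameters; defaults from
#'   [bundle_defaults()], unknown names rejected.
#' @param seed Integer seed driving all draws.
#' @return A `coevo_bundle` list: `hits_a`, `hits_b`, `truth_records`,
#'   `truth_pairs`, `msa`, `structure`, `params`.
#' @export
sim_bundle <- function(config = list(), seed = 1L) {
  defaults <- bundle_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "unknown bundle parameter(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  cfg <- utils::modifyList(defaults, config)
  genome <- sim_genome_hits(
    n_records = cfg$n_records, colocate_prob = cfg$colocate_prob,
    max_separation = cfg$max_separation, len_a = cfg$len_a, len_b = cfg$len_b,
    fam_a = cfg$fam_a, fam_b = cfg$fam_b, seed = derive_seed(seed, 101L)
  )
  n_pairs <- nrow(genome$truth)
  if (n_pairs < 2L) {
    abort_validation("bundle needs at least 2 co-located records; increase n_records or colocate_prob")
  }
  if (cfg$n_planted > min(cfg$len_a, cfg$len_b)) {
    abort_validation("n_planted may not exceed min(len_a, len_b)")
  }
  planted <- withr::with_seed(derive_seed(seed, 202L), tibble(
    i = sample.int(cfg$len_a, cfg$n_planted),
    j = sample.int(cfg$len_b, cfg$n_planted)
  ))
  sim <- sim_coupled_msa(
    cfg$len_a, cfg$len_b, n_seqs = n_pairs, planted = planted,
    epsilon = cfg$epsilon, gap_rate = cfg$gap_rate,
    seed = derive_seed(seed, 303L)
  )
  # co-located records carry the coupled alignment rows (sorted record order)
  truth_ids <- sort(genome$truth$record_id)
  seqs <- setNames(sim$msa$sequence, truth_ids)
  block_a <- substr(seqs, 1L, cfg$len_a)
  block_b <- substr(seqs, cfg$len_a + 1L, cfg$len_a + cfg$len_b)
  hits_a <- genome$hits_a
  hits_b <- genome$hits_b
  ia <- match(truth_ids, hits_a$record_id)
  ib <- match(truth_ids, hits_b$record_id)
  hits_a$aligned_seq[ia] <- unname(block_a)
  hits_b$aligned_seq[ib] <- unname(block_b)
  msa <- paired_msa(
    tibble(record_id = truth_ids, sequence = unname(seqs)),
    cfg$len_a, cfg$len_b
  )
  struct <- sim_structure(
    cfg$len_a, cfg$len_b, planted,
    n_copies_a = cfg$n_copies_a, n_copies_b = cfg$n_copies_b,
    contact_distance = cfg$contact_distance, far_distance = cfg$far_distance,
    fam_a = cfg$fam_a, fam_b = cfg$fam_b, seed = derive_seed(seed, 404L)
  )
  structure(
    list(
      hits_a = hits_a, hits_b = hits_b,
      truth_records = genome$truth, truth_pairs = planted,
      msa = msa, structure = struct,
      params = c(cfg, list(seed = seed))
    ),
    class = "coevo_bundle"
  )
}

#' @export
print.coevo_bundle <- function(x, ...) {
  cat(sprintf(
    "<coevo_bundle> %d + %d hits, %d co-located records, %d planted pairs, seed %d\n",
    nrow(x$hits_a), nrow(x$hits_b), nrow(x$truth_records),
    nrow(x$truth_pairs), x$params$seed
  ))
  invisible(x)
}

#' Write a bundle to disk in the pipeline's input formats
#'
#' Hit tables as TSV, structure as CA-only PDB, chain map and truth as JSON
#' — the exact formats [run_pipeline()] consumes, so generated fixtures
#' double as format round-trip tests.
#'
#' @param bundle A `coevo_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    hits_a = file.path(dir, "hits_a.tsv"),
    hits_b = file.path(dir, "hits_b.tsv"),
    structure = file.path(dir, "structure.pdb"),
    chain_map = file.path(dir, "chain_map.json"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_records = file.path(dir, "truth_records.tsv")
  )
  write_hit_table(bundle$hits_a, paths$hits_a)
  write_hit_table(bundle$hits_b, paths$hits_b)
  write_structure_pdb(bundle$structure, paths$structure)
  jsonlite::write_json(
    as.list(bundle$structure$chain_to_protein), paths$chain_map,
    auto_unbox = TRUE
  )
  readr::write_tsv(bundle$truth_pairs, paths$truth_pairs, progress = FALSE)
  readr::write_tsv(bundle$truth_records, paths$truth_records, progress = FALSE)
  invisible(paths)
}
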