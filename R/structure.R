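# Multi-chain C-alpha structure model. Chains are tibbles of
# (resno, x, y, z); `chain_to_protein` maps chain ids to family ids so a
# family present in several symmetric copies contributes several chains.
# `offsets` optionally shifts profile columns to author residue numbers
# (resno = column + offset[family]).

new_structure_model <- function(chains, chain_to_protein, offsets = NULL) {
  if (!all(names(chain_to_protein) %in% names(chains))) {
    missing <- setdiff(names(chain_to_protein), names(chains))
    abort_data(sprintf(
      "chain(s) named in chain map absent from structure: %s",
      paste(missing, collapse = ", ")
    ))
  }
  for (ch in names(chains)) {
    xyz <- as.matrix(chains[[ch]][, c("x", "y", "z")])
    if (!all(is.finite(xyz))) {
      abort_data(sprintf("chain %s contains non-finite coordinates", ch))
    }
  }
  structure(
    list(
      chains = chains,
      chain_to_protein = chain_to_protein,
      offsets = offsets %||% setNames(
        rep(0L, length(unique(chain_to_protein))), unique(chain_to_protein)
      )
    ),
    class = "coevo_structure"
  )
}

#' @export
print.coevo_structure <- function(x, ...) {
  fams <- split(names(x$chain_to_protein), x$chain_to_protein)
  cat(sprintf("<coevo_structure> %d chain(s)\n", length(x$chains)))
  for (f in names(fams)) {
    cat(sprintf(
      "  %s: chain(s) %s (%s residues)\n", f,
      paste(fams[[f]], collapse = ","),
      paste(vapply(fams[[f]], function(ch) nrow(x$chains[[ch]]), 1L),
            collapse = ",")
    ))
  }
  invisible(x)
}

#' Load a C-alpha structure model from PDB or mmCIF
#'
#' Parses coordinates with bio3d, keeps C-alpha atoms only, and attaches the
#' chain-to-family map. Residues present in the file but lacking a C-alpha
#' are skipped with a warning.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param chain_map Named character vector or list, chain id -> family id.
#'   Every named chain must exist in the file. Unmapped chains are dropped.
#' @param offsets Optional named integer vector, family id -> offset added
#'   to a profile column to obtain the author residue number.
#' @return A `coevo_structure`.
#' @export
load_structure <- function(path, chain_map, offsets = NULL) {
  if (!file.exists(path)) {
    abort_validation(sprintf("structure file not found: %s", path))
  }
  chain_map <- unlist(chain_map)
  pdb <- tryCatch(
    if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
    },
    error = function(e) {
      abort_data(sprintf("cannot parse structure file %s: %s", path,
                         conditionMessage(e)))
    }
  )
  atoms <- as_tibble(pdb$atom)
  missing <- setdiff(names(chain_map), unique(atoms$chain))
  if (length(missing) > 0L) {
    abort_data(sprintf(
      "chain(s) named in chain map absent from %s: %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  atoms <- dplyr::filter(atoms, .data$chain %in% names(chain_map))
  ca <- dplyr::filter(atoms, .data$elety == "CA")
  n_no_ca <- nrow(dplyr::anti_join(
    dplyr::distinct(atoms, .data$chain, .data$resno),
    dplyr::distinct(ca, .data$chain, .data$resno),
    by = c("chain", "resno")
  ))
  if (n_no_ca > 0L) {
    warn(sprintf("skipped %d residue(s) lacking a C-alpha atom", n_no_ca))
  }
  ca <- dplyr::distinct(ca, .data$chain, .data$resno, .keep_all = TRUE)
  chains <- lapply(split(ca, ca$chain), function(df) {
    arrange(tibble(resno = df$resno, x = df$x, y = df$y, z = df$z), .data$resno)
  })
  new_structure_model(chains, chain_map, offsets)
}

#' Write a C-alpha structure model as PDB
#'
#' Minimal CA-only ATOM records (residues rendered as alanine), one chain
#' per structure chain; round-trips through [load_structure()].
#'
#' @param m A `coevo_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(m, path) {
  lines <- character(0)
  serial <- 0L
  for (ch in names(m$chains)) {
    df <- m$chains[[ch]]
    for (r in seq_len(nrow(df))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, ch, df$resno[r], df$x[r], df$y[r], df$z[r], 1.0, 0.0
      ))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

resolve_residue <- function(m, family, column) {
  chains <- names(m$chain_to_protein)[m$chain_to_protein == family]
  if (length(chains) == 0L) {
    abort_data(sprintf("unknown family in structure: %s", family))
  }
  resno <- column + (m$offsets[[family]] %||% 0L)
  out <- list()
  for (ch in chains) {
    df <- m$chains[[ch]]
    hit <- which(df$resno == resno)
    if (length(hit) == 1L) {
      out[[ch]] <- c(df$x[hit], df$y[hit], df$z[hit])
    }
  }
  out
}

#' Minimal cross-chain C-alpha distance between two residues
#'
#' Minimum Euclidean distance over all chain-copy combinations of the two
#' families; for `fam_a == fam_b` only distinct-chain combinations count
#' (the homo-oligomeric reading of a contact). `NA` when either residue is
#' unresolved in every copy.
#'
#' @param m A `coevo_structure`.
#' @param fam_a,fam_b Family ids present in the chain map.
#' @param i,j 1-based profile columns of the residue in family A / B.
#' @return Distance in Angstrom, or `NA_real_`.
#' @export
min_cross_distance <- function(m, fam_a, i, fam_b, j) {
  pa <- resolve_residue(m, fam_a, i)
  pb <- resolve_residue(m, fam_b, j)
  if (length(pa) == 0L || length(pb) == 0L) {
    return(NA_real_)
  }
  best <- Inf
  for (ca in names(pa)) {
    for (cb in names(pb)) {
      if (identical(fam_a, fam_b) && ca == cb) next
      d <- sqrt(sum((pa[[ca]] - pb[[cb]])^2))
      if (d < best) best <- d
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

min_within_distance <- function(m, family, i, j) {
  pa <- resolve_residue(m, family, i)
  pb <- resolve_residue(m, family, j)
  shared <- intersect(names(pa), names(pb))
  if (length(shared) == 0L) {
    return(NA_real_)
  }
  min(vapply(shared, function(ch) sqrt(sum((pa[[ch]] - pb[[ch]])^2)), 1.0))
}

#' Classify a co-evolving residue pair against a structure
#'
#' Pairs across two families are `hetero_oligomeric`. Within one family the
#' pair is `homo_oligomeric` when its minimal cross-chain distance is
#' smaller than its minimal within-chain distance (the contact is realised
#' between oligomer copies), otherwise `intra`.
#'
#' @inheritParams min_cross_distance
#' @return One of `"hetero_oligomeric"`, `"homo_oligomeric"`, `"intra"`,
#'   or `NA_character_` when no distance is computable.
#' @export
classify_pair <- function(m, fam_a, i, fam_b, j) {
  if (!identical(fam_a, fam_b)) {
    return("hetero_oligomeric")
  }
  cross <- min_cross_distance(m, fam_a, i, fam_b, j)
  within <- min_within_distance(m, fam_a, i, j)
  if (is.na(cross) && is.na(within)) {
    return(NA_character_)
  }
  if (is.na(within)) {
    return("homo_oligomeric")
  }
  if (is.na(cross)) {
    return("intra")
  }
  if (cross < within) "homo_oligomeric" else "intra"
}
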