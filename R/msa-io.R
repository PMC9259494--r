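# Paired-MSA serialisation. FASTA goes through Biostrings; Stockholm is a
# minimal single-block dialect written here because no installed package
# provides one. The block partition (len_a, len_b) is carried in a sidecar
# JSON for FASTA and in #=GF fields for Stockholm.

msa_sidecar_path <- function(path) paste0(path, ".json")

#' Write a paired MSA to FASTA or Stockholm
#'
#' FASTA output gets a sidecar `<path>.json` recording the block partition;
#' Stockholm records it in `#=GF LA` / `#=GF LB` lines.
#'
#' @param msa A `coevo_msa`.
#' @param path Output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_paired_msa <- function(msa, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  part <- msa_partition(msa)
  if (format == "fasta") {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      set <- Biostrings::AAStringSet(setNames(msa$sequence, msa$record_id))
      Biostrings::writeXStringSet(set, path)
    } else {
      writeLines(
        as.vector(rbind(paste0(">", msa$record_id), msa$sequence)),
        path
      )
    }
    jsonlite::write_json(
      list(len_a = unname(part[["len_a"]]), len_b = unname(part[["len_b"]]),
           n_rows = nrow(msa)),
      msa_sidecar_path(path), auto_unbox = TRUE
    )
  } else {
    ids <- format(msa$record_id, width = max(nchar(msa$record_id), 1L))
    writeLines(c(
      "# STOCKHOLM 1.0",
      sprintf("#=GF LA %d", part[["len_a"]]),
      sprintf("#=GF LB %d", part[["len_b"]]),
      paste(ids, msa$sequence),
      "//"
    ), path)
  }
  invisible(path)
}

#' Read a paired MSA written by [write_paired_msa()]
#'
#' @param path Path to the FASTA (with its sidecar JSON) or Stockholm file.
#' @param format `"fasta"` or `"stockholm"`; guessed from the extension when
#'   omitted.
#' @return A `coevo_msa`.
#' @export
read_paired_msa <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort_validation(sprintf("MSA file not found: %s", path))
  }
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path)) "stockholm" else "fasta"
  }
  format <- match.arg(format, c("fasta", "stockholm"))
  if (format == "fasta") {
    sidecar <- msa_sidecar_path(path)
    if (!file.exists(sidecar)) {
      abort_data(sprintf(
        "FASTA paired MSA requires its partition sidecar: %s", sidecar
      ))
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      set <- Biostrings::readAAStringSet(path)
      rows <- tibble(record_id = names(set), sequence = as.character(set))
    } else {
      lines <- readLines(path)
      idx <- grepl("^>", lines)
      rows <- tibble(
        record_id = sub("^>", "", lines[idx]),
        sequence = vapply(
          split(lines[!idx], cumsum(idx)[!idx]),
          paste, character(1), collapse = ""
        )
      )
    }
    paired_msa(rows, meta$len_a, meta$len_b)
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1])) {
      abort_data(sprintf("%s is not a Stockholm file", path))
    }
    get_gf <- function(tag) {
      m <- grep(sprintf("^#=GF %s ", tag), lines, value = TRUE)
      if (length(m) == 0L) {
        abort_data(sprintf("Stockholm file lacks '#=GF %s' partition line", tag))
      }
      as.integer(sub(sprintf("^#=GF %s +", tag), "", m[1]))
    }
    len_a <- get_gf("LA")
    len_b <- get_gf("LB")
    seq_lines <- lines[!grepl("^(#|//|\\s*$)", lines)]
    parts <- stringr::str_split_fixed(stringr::str_squish(seq_lines), " ", 2)
    paired_msa(
      tibble(record_id = parts[, 1], sequence = parts[, 2]),
      len_a, len_b
    )
  }
}
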