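# End-to-end orchestration: pair -> paired MSA -> score -> select -> map.
# A run is declared by a flat config (R list or YAML file), validated
# before any computation; every intermediate artifact is persisted so each
# report field can be recomputed from disk, and identical config + seed
# reproduces byte-identical outputs.

config_defaults <- function() {
  list(
    # inputs
    hits_a = NULL, hits_b = NULL,
    family_a = "famA", family_b = "famB",
    profile_length_a = NULL, profile_length_b = NULL,
    distogram = NULL,
    structure = NULL, chain_map = NULL, offsets = NULL,
    output_dir = NULL,
    # thresholds (documented defaults of the whole pipeline)
    min_coverage = 0.60, max_evalue = 1e-3,
    max_separation = 20L, pairing = "closest",
    max_gap_ratio = 0.25, max_identity = 0.90,
    backend = "mi_apc", pseudocount = 1.0,
    distance_cutoff = 12.0, min_score = 0.05,
    selection = "threshold70", scope = "inter",
    contact_cutoff = 12.0,
    seed = 1L
  )
}

#' Build and validate a pipeline run configuration
#'
#' @param ... Named configuration entries, or a single list/YAML path via
#'   `config`. Unknown keys are rejected; thresholds must lie in their
#'   documented ranges.
#' @param config Optional list or path to a YAML file with entries.
#' @return A validated `coevo_config` list with defaults filled in.
#' @export
coevo_config <- function(..., config = NULL) {
  user <- list(...)
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      if (!file.exists(config)) {
        abort_validation(sprintf("config file not found: %s", config))
      }
      config <- yaml::read_yaml(config)
    }
    user <- utils::modifyList(as.list(config), user)
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "unknown config key(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  cfg <- utils::modifyList(defaults, user)
  for (key in c("hits_a", "hits_b", "output_dir")) {
    if (is.null(cfg[[key]])) {
      abort_validation(sprintf("config is missing required entry '%s'", key))
    }
  }
  for (key in c("hits_a", "hits_b")) {
    if (!file.exists(cfg[[key]])) {
      abort_validation(sprintf("config %s: file not found: %s", key, cfg[[key]]))
    }
  }
  if (is.null(cfg$profile_length_a) || is.null(cfg$profile_length_b)) {
    abort_validation("config must declare profile_length_a and profile_length_b")
  }
  if (!is_fraction(cfg$min_coverage) || !is_fraction(cfg$max_gap_ratio) ||
      !is_fraction(cfg$max_identity) || cfg$max_identity == 0) {
    abort_validation("coverage/gap/identity thresholds must be fractions in [0, 1]")
  }
  if (!is_count(cfg$max_separation, 1L)) {
    abort_validation("max_separation must be an integer >= 1")
  }
  if (!cfg$backend %in% c("mi_apc", "distogram")) {
    abort_validation("backend must be 'mi_apc' or 'distogram'")
  }
  if (cfg$backend == "distogram" && is.null(cfg$distogram)) {
    abort_validation("distogram backend needs a 'distogram' input path")
  }
  if (!cfg$pairing %in% c("closest", "all")) {
    abort_validation("pairing must be 'closest' or 'all'")
  }
  if (!cfg$scope %in% c("inter", "all")) {
    abort_validation("scope must be 'inter' or 'all'")
  }
  if (cfg$distance_cutoff <= 0 || cfg$contact_cutoff <= 0) {
    abort_validation("distance cutoffs must be positive")
  }
  if (!is.null(cfg$structure) && is.null(cfg$chain_map)) {
    abort_validation("a structure input needs a chain_map JSON")
  }
  structure(cfg, class = "coevo_config")
}

log_line <- function(con, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full interface-inference pipeline
#'
#' Executes hit filtering, genomic pairing, paired-MSA construction with
#' gap/redundancy filtering, co-evolution scoring (MI/APC or distogram
#' aggregation), ranking and selection, and — when a structure is supplied —
#' distance mapping and interface precision. All intermediates are written
#' under `output_dir` together with a JSON report and a JSON-lines run log;
#' the same config and seed reproduce byte-identical outputs.
#'
#' @param config A `coevo_config`, a plain list, or a YAML path.
#' @return The run report (named list), invisibly: row counts surviving
#'   each filter, selection size, and interface precision when computed.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "coevo_config")) {
    config <- if (is.character(config)) {
      coevo_config(config = config)
    } else {
      do.call(coevo_config, as.list(config))
    }
  }
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run_log.jsonl")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort_data(
        sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        parent = e
      )
    })
  }
  # the log describes the analysis (inputs + thresholds), not the destination
  log_line(log_con, "config",
    params = cfg[setdiff(names(cfg), c("offsets", "output_dir"))],
    upstream_search_evalue_schedule = HMM_SEARCH_EVALUE_SCHEDULE,
    package_version = as.character(utils::packageVersion("coevomap"))
  )

  hits_a <- run_stage("read_hits", read_hit_table(
    cfg$hits_a, cfg$family_a, cfg$profile_length_a
  ))
  hits_b <- run_stage("read_hits", read_hit_table(
    cfg$hits_b, cfg$family_b, cfg$profile_length_b
  ))
  fa <- filter_hits(hits_a, cfg$min_coverage, cfg$max_evalue)
  fb <- filter_hits(hits_b, cfg$min_coverage, cfg$max_evalue)
  log_line(log_con, "filter_hits",
    min_coverage = cfg$min_coverage, max_evalue = cfg$max_evalue,
    n_in = c(nrow(hits_a), nrow(hits_b)), n_out = c(nrow(fa), nrow(fb))
  )

  pairs <- run_stage("pair_by_locus", pair_by_locus(
    fa, fb, max_separation = cfg$max_separation, pairing = cfg$pairing
  ))
  write_paired_records(pairs, file.path(cfg$output_dir, "pairs.tsv"))
  log_line(log_con, "pair_by_locus",
    max_separation = cfg$max_separation, pairing = cfg$pairing,
    n_out = nrow(pairs)
  )

  msa <- run_stage("build_msa", build_paired_msa(
    pairs, cfg$profile_length_a, cfg$profile_length_b
  ))
  msa_gap <- gap_filter(msa, cfg$max_gap_ratio)
  msa_final <- redundancy_filter(msa_gap, cfg$max_identity)
  write_paired_msa(msa_final, file.path(cfg$output_dir, "paired_msa.fasta"))
  log_line(log_con, "msa_filters",
    max_gap_ratio = cfg$max_gap_ratio, max_identity = cfg$max_identity,
    n_rows = c(built = nrow(msa), gap_filtered = nrow(msa_gap),
               nonredundant = nrow(msa_final))
  )

  scores <- run_stage("score", if (cfg$backend == "mi_apc") {
    mi_apc_scores(msa_final, pseudocount = cfg$pseudocount)
  } else {
    aggregate_contact_probability(
      read_distogram(cfg$distogram), distance_cutoff = cfg$distance_cutoff
    )
  })
  write_scores(scores, file.path(cfg$output_dir, "scores.tsv"))
  ranked <- rank_inter_pairs(scores, min_score = cfg$min_score, scope = cfg$scope)
  readr::write_tsv(ranked, file.path(cfg$output_dir, "ranked_pairs.tsv"),
                   progress = FALSE)
  selected <- run_stage("select", select_pairs(ranked, mode = cfg$selection))
  readr::write_tsv(selected, file.path(cfg$output_dir, "selected_pairs.tsv"),
                   progress = FALSE)
  log_line(log_con, "score_select",
    backend = cfg$backend, min_score = cfg$min_score,
    selection = cfg$selection, scope = cfg$scope,
    n_ranked = nrow(ranked), n_selected = nrow(selected)
  )

  report <- list(
    n_hits = c(a = nrow(hits_a), b = nrow(hits_b)),
    n_hits_filtered = c(a = nrow(fa), b = nrow(fb)),
    n_paired_records = nrow(pairs),
    n_msa_rows = c(built = nrow(msa), gap_filtered = nrow(msa_gap),
                   nonredundant = nrow(msa_final)),
    backend = cfg$backend,
    n_ranked_pairs = nrow(ranked),
    top_score = if (nrow(ranked) > 0L) ranked$score[1] else NA_real_,
    selection = cfg$selection,
    n_selected_pairs = nrow(selected),
    seed = cfg$seed
  )

  if (!is.null(cfg$structure)) {
    chain_map <- unlist(jsonlite::read_json(cfg$chain_map, simplifyVector = TRUE))
    m <- run_stage("load_structure", load_structure(
      cfg$structure, chain_map, offsets = cfg$offsets
    ))
    mapped <- run_stage("map", map_pairs(
      selected, m, cfg$family_a, cfg$family_b,
      contact_cutoff = cfg$contact_cutoff
    ))
    readr::write_tsv(as_tibble(mapped),
                     file.path(cfg$output_dir, "mapped_pairs.tsv"),
                     progress = FALSE)
    summary <- glance(mapped)
    report$interface <- as.list(summary)
    log_line(log_con, "map",
      contact_cutoff = cfg$contact_cutoff,
      precision = summary$precision, n_unresolved = summary$n_unresolved
    )
  }

  jsonlite::write_json(
    report, file.path(cfg$output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}
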