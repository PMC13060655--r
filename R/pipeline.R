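#' Validate a pipeline configuration
#'
#' A configuration is a YAML file or named list. Top-level keys: `seed`
#' (integer), `output_dir`, `preset` (screen threshold preset name),
#' `thresholds` (named overrides for [screen_config()]), `cohort`,
#' `invitro`, `transcripts`, `signatures`, `sc`. Unknown keys anywhere are
#' rejected by name. `cohort`, `invitro` and `sc` may each be the string
#' `"simulate"` (synthetic inputs with the default generator parameters and
#' the configured seed) or a list of file paths:
#'
#' * `cohort`: `expression` (TSV), `clinical` (TSV), optional `scale`.
#' * `invitro`: `expression` (TSV), `normoxia_ids`, `hypoxia_ids`.
#' * `sc`: either `counts` (dense TSV) or `mtx` + `features` + `barcodes`,
#'   plus `annotations`, `query`, optional `markers`, `min_fold`.
#' * `transcripts`: path to a one-id-per-line universe file (required when
#'   `cohort` is file-based; the synthetic cohort carries its own universe).
#' * `signatures`: optional paths `hypoxia`, `stroma`, `immune` (defaults:
#'   shipped fixtures).
#'
#' @param config YAML path or named list.
#' @return Normalized config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a named list")
  known <- c("seed", "output_dir", "preset", "thresholds", "cohort",
             "invitro", "transcripts", "signatures", "sc")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_section <- function(x, keys, what) {
    if (is.list(x)) {
      bad <- setdiff(names(x), keys)
      if (length(bad) > 0L)
        stop("unknown config key(s) in '", what, "': ", paste(bad, collapse = ", "))
    }
    x
  }
  check_section(config$cohort, c("expression", "clinical", "scale"), "cohort")
  check_section(config$invitro, c("expression", "normoxia_ids", "hypoxia_ids"), "invitro")
  check_section(config$sc, c("counts", "mtx", "features", "barcodes",
                             "annotations", "query", "markers", "min_fold"), "sc")
  check_section(config$signatures, c("hypoxia", "stroma", "immune"), "signatures")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$preset)) config$preset <- "figure-strict"
  config
}

#' Run the full screening pipeline from a configuration
#'
#' Stages run in dependency order: hypoxia scoring, signature z-scores,
#' in-vitro differential expression, candidate criteria and intersection,
#' then single-cell restriction. Stages whose inputs are not configured are
#' skipped and listed in the report. Required files missing for a configured
#' stage raise an error before any computation. The report is fully
#' determined by (inputs, config, seed) apart from its timestamp.
#'
#' @param config YAML path or list (see [validate_pipeline_config()]).
#' @return list (class `pipeline_report`): per-stage outputs, `skipped`,
#'   and `provenance` (config, seed, package version, timestamp). When
#'   `output_dir` is set, score/stratification/candidate TSVs and a Venn
#'   JSON are also written there.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  # fail fast on missing configured inputs
  for (section in c("cohort", "invitro", "sc")) {
    s <- cfg[[section]]
    if (is.list(s)) {
      paths <- unlist(s[names(s) %in% c("expression", "clinical", "counts",
                                        "mtx", "features", "barcodes",
                                        "annotations")])
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0L)
        stop("configured ", section, " input file(s) not found: ",
             paste(missing, collapse = ", "))
    }
  }
  thr <- c(list(preset = cfg$preset), cfg$thresholds)
  config_screen <- do.call(screen_config, thr)
  seed <- as.integer(cfg$seed)
  report <- list(skipped = character(0))
  sim <- NULL

  hyp_path <- if (!is.null(cfg$signatures$hypoxia)) cfg$signatures$hypoxia else
    signature_fixture("hypoxia_metagene_27")
  str_path <- if (!is.null(cfg$signatures$stroma)) cfg$signatures$stroma else
    signature_fixture("stroma_141")
  imm_path <- if (!is.null(cfg$signatures$immune)) cfg$signatures$immune else
    signature_fixture("immune_141")
  hyp_sig <- read_signature(hyp_path)

  # ---- bulk cohort stages ----
  # synthetic mode uses the screening-scale validation design (250 tumors):
  # at the 57-tumor cohort scale the strict preset has little power for the
  # default planted couplings (see the methods vignette)
  sim_design <- sim_params(n_tumor = 250)
  cohort <- NULL; transcripts <- NULL
  if (identical(cfg$cohort, "simulate")) {
    sim <- simulate_cohort(sim_design, seed = seed)
    cohort <- sim$cohort
    transcripts <- sim$truth$transcripts$transcript
  } else if (is.list(cfg$cohort)) {
    scale <- if (is.null(cfg$cohort$scale)) "log2" else cfg$cohort$scale
    expr <- read_expression_matrix(cfg$cohort$expression, scale = scale)
    clin <- read_clinical_table(cfg$cohort$clinical)
    cohort <- align_cohort(expr, clin)
    if (is.null(cfg$transcripts))
      stop("a file-based cohort requires a 'transcripts' universe file")
    transcripts <- trimws(readLines(cfg$transcripts))
    transcripts <- transcripts[nzchar(transcripts)]
  } else {
    report$skipped <- c(report$skipped, "cohort")
  }

  if (!is.null(cohort)) {
    fct <- compute_fold_changes(cohort, hyp_sig)
    scores <- hypoxia_score(fct)
    report$hypoxia_scores <- scores
    report$signature_scores <- list(
      stroma = zscore_signature_score(cohort, read_signature(str_path)),
      immune = zscore_signature_score(cohort, read_signature(imm_path)))
  }

  invitro_de <- NULL
  if (identical(cfg$invitro, "simulate")) {
    iv <- simulate_invitro(sim_design, seed = seed)
    invitro_de <- two_group_de(iv$expr, iv$normoxia_ids, iv$hypoxia_ids)
  } else if (is.list(cfg$invitro)) {
    expr <- read_expression_matrix(cfg$invitro$expression)
    invitro_de <- two_group_de(expr, cfg$invitro$normoxia_ids,
                               cfg$invitro$hypoxia_ids)
  } else {
    report$skipped <- c(report$skipped, "invitro")
  }
  report$invitro_de <- invitro_de

  if (!is.null(cohort) && !is.null(invitro_de)) {
    criteria <- evaluate_criteria(cohort, report$hypoxia_scores, invitro_de,
                                  transcripts, config_screen)
    report$criteria <- criteria
    report$candidate_sets <- intersect_candidates(criteria)
  } else {
    report$skipped <- c(report$skipped, "candidate_selection")
  }

  # ---- single-cell stage ----
  if (identical(cfg$sc, "simulate")) {
    scsim <- simulate_sc(sim_design, seed = seed)
    report$sc_restriction <- restrict_transcript(
      scsim$sc, scsim$truth$query, scsim$truth$markers)
  } else if (is.list(cfg$sc)) {
    sc <- if (!is.null(cfg$sc$counts))
      read_sc_dense(cfg$sc$counts, cfg$sc$annotations)
    else
      read_sc_mtx(cfg$sc$mtx, cfg$sc$features, cfg$sc$barcodes,
                  cfg$sc$annotations)
    min_fold <- if (is.null(cfg$sc$min_fold)) 10 else cfg$sc$min_fold
    markers <- if (is.null(cfg$sc$markers)) character(0) else cfg$sc$markers
    report$sc_restriction <- restrict_transcript(sc, cfg$sc$query, markers,
                                                 min_fold = min_fold)
  } else {
    report$skipped <- c(report$skipped, "sc_restriction")
  }

  report$provenance <- list(config = cfg, seed = seed,
                            screen_config = unclass(config_screen),
                            package_version = as.character(utils::packageVersion("lncscreen")),
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(report) <- "pipeline_report"

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- cfg$output_dir
    if (!is.null(report$hypoxia_scores))
      utils::write.table(report$hypoxia_scores, file.path(od, "hypoxia_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$criteria))
      utils::write.table(report$criteria, file.path(od, "candidate_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$candidate_sets))
      write_venn_counts(report$candidate_sets, file.path(od, "venn_counts.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$hypoxia_scores)) {
    tab <- table(x$hypoxia_scores$class)
    cat("  hypoxia classes:", paste(names(tab), tab, collapse = ", ", sep = "="), "\n")
  }
  if (!is.null(x$candidate_sets)) print(x$candidate_sets)
  if (!is.null(x$sc_restriction)) print(x$sc_restriction$score)
  if (length(x$skipped) > 0L)
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
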