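#' Threshold configuration for the three-criterion candidate screen
#'
#' Two named presets reflect the two threshold dialects used for the screen:
#'
#' * `"figure-strict"` (default): cohort hypoxia criterion = mean log2
#'   intensity in tumors > 6 AND hypoxia-association adjusted p < 0.001.
#' * `"methods-loose"`: hypoxia criterion additionally requires a
#'   tumor/healthy expression ratio >= 1.6-fold with BH FDR < 0.05, and
#'   relaxes the association cut to adjusted p < 0.05.
#'
#' Both share the overall-survival criterion (quartile log-rank p < 0.05) and
#' the in-vitro criterion (|log2(hypoxia/normoxia)| > 0.5, log2 intensity > 6,
#' adjusted p < 0.05). Every threshold can be overridden.
#'
#' @param preset `"figure-strict"` or `"methods-loose"`.
#' @param ... Named threshold overrides (must match existing fields).
#' @return list of thresholds (class `screen_config`).
#' @export
screen_config <- function(preset = c("figure-strict", "methods-loose"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    min_intensity = 6,            # strict >, mean log2 intensity over tumors
    hypoxia_adj_p = if (preset == "figure-strict") 0.001 else 0.05,  # strict <
    ratio_fold = if (preset == "figure-strict") NA_real_ else 1.6,   # >=, linear fold
    ratio_fdr = if (preset == "figure-strict") NA_real_ else 0.05,   # strict <
    os_p = 0.05,                  # strict <, quartile log-rank
    os_groups = 4,                # 4 = quartiles, 2 = median split
    invitro_min_abs_lfc = 0.5,    # strict >
    invitro_min_intensity = 6,    # strict >
    invitro_max_p = 0.05,         # strict <
    invitro_p_type = "adj"        # "adj" or "raw"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown screen_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "screen_config")
}

#' Evaluate the three selection criteria for each screened transcript
#'
#' Fills, per transcript: tumor/healthy log2 ratio and BH FDR (Welch t over
#' the cohort), mean log2 intensity in tumors, Spearman association with the
#' hypoxia score (BH-adjusted across the screened set), quartile log-rank
#' overall-survival p, and the in-vitro contrast statistics, then sets one
#' boolean flag per criterion from the `screen_config` thresholds. Flags are
#' pure functions of the stored statistics and the thresholds.
#'
#' Transcripts absent from the cohort matrix or from the in-vitro table are
#' flagged `missing` and excluded from set algebra rather than silently
#' counted false.
#'
#' @param cohort An `lnc_cohort`.
#' @param scores Hypoxia score table from [hypoxia_score()].
#' @param invitro_de `de_table` of the paired normoxia/hypoxia contrast
#'   (group2 = hypoxia, so positive log2FC = induced by hypoxia).
#' @param transcripts Transcript universe to screen (e.g. lncRNA ids).
#' @param config A [screen_config()].
#' @return data.frame (class `candidate_criteria`) with statistics, flags
#'   `flag_hypoxia`, `flag_os`, `flag_invitro`, `direction`
#'   (positive/negative, defined only when the hypoxia flag is true) and
#'   `missing`; attribute `config`.
#' @export
evaluate_criteria <- function(cohort, scores, invitro_de, transcripts,
                              config = screen_config()) {
  stopifnot(inherits(cohort, "lnc_cohort"), inherits(config, "screen_config"))
  transcripts <- as.character(transcripts)
  in_cohort <- transcripts %in% rownames(cohort$expr)
  in_invitro <- transcripts %in% invitro_de$gene
  missing <- !(in_cohort & in_invitro)
  if (any(missing))
    message("evaluate_criteria: ", sum(missing),
            " transcript(s) missing from an input; flagged and excluded from sets")
  present <- transcripts[in_cohort]

  out <- data.frame(transcript = transcripts,
                    mean_intensity_tumor = NA_real_,
                    tumor_healthy_log2_ratio = NA_real_,
                    tumor_healthy_fdr = NA_real_,
                    hypoxia_rho = NA_real_, hypoxia_p = NA_real_,
                    hypoxia_adj_p = NA_real_,
                    os_chisq = NA_real_, os_p = NA_real_,
                    invitro_log2_fc = NA_real_,
                    invitro_mean_intensity = NA_real_,
                    invitro_p = NA_real_, invitro_adj_p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  idx <- match(present, transcripts)

  out$mean_intensity_tumor[idx] <-
    rowMeans(cohort$expr[present, cohort$tumor_ids, drop = FALSE])

  th <- two_group_de(cohort$expr[present, , drop = FALSE],
                     cohort$healthy_ids, cohort$tumor_ids)
  out$tumor_healthy_log2_ratio[idx] <- th$log2_fc
  out$tumor_healthy_fdr[idx] <- th$adj_p

  hx <- hypoxia_association_screen(cohort, present, scores)
  out$hypoxia_rho[idx] <- hx$rho
  out$hypoxia_p[idx] <- hx$p_value
  out$hypoxia_adj_p[idx] <- hx$adj_p

  surv_ids <- survival_samples(cohort)
  for (k in seq_along(present)) {
    tr <- present[k]
    os <- tryCatch(os_quartile_test(cohort, tr, n_groups = config$os_groups),
                   error = function(e) NULL)
    if (!is.null(os)) {
      out$os_chisq[idx[k]] <- os$test$chisq
      out$os_p[idx[k]] <- os$test$p_value
    }
  }

  iv <- match(transcripts, invitro_de$gene)
  out$invitro_log2_fc <- invitro_de$log2_fc[iv]
  out$invitro_mean_intensity <- invitro_de$mean_intensity[iv]
  out$invitro_p <- invitro_de$p_value[iv]
  out$invitro_adj_p <- invitro_de$adj_p[iv]

  flag_hx <- !is.na(out$mean_intensity_tumor) &
    out$mean_intensity_tumor > config$min_intensity &
    !is.na(out$hypoxia_adj_p) & out$hypoxia_adj_p < config$hypoxia_adj_p
  if (!is.na(config$ratio_fold))
    flag_hx <- flag_hx & !is.na(out$tumor_healthy_log2_ratio) &
      abs(out$tumor_healthy_log2_ratio) >= log2(config$ratio_fold)
  if (!is.na(config$ratio_fdr))
    flag_hx <- flag_hx & !is.na(out$tumor_healthy_fdr) &
      out$tumor_healthy_fdr < config$ratio_fdr

  flag_os <- !is.na(out$os_p) & out$os_p < config$os_p

  iv_p <- if (config$invitro_p_type == "adj") out$invitro_adj_p else out$invitro_p
  flag_iv <- !is.na(out$invitro_log2_fc) &
    abs(out$invitro_log2_fc) > config$invitro_min_abs_lfc &
    !is.na(out$invitro_mean_intensity) &
    out$invitro_mean_intensity > config$invitro_min_intensity &
    !is.na(iv_p) & iv_p < config$invitro_max_p

  out$flag_hypoxia <- flag_hx & !missing
  out$flag_os <- flag_os & !missing
  out$flag_invitro <- flag_iv & !missing
  out$direction <- ifelse(out$flag_hypoxia,
                          ifelse(out$hypoxia_rho > 0, "positive", "negative"),
                          NA_character_)
  out$missing <- missing
  attr(out, "config") <- config
  class(out) <- c("candidate_criteria", "data.frame")
  out
}

#' Set algebra over the three screen criteria
#'
#' Computes per-criterion sets, all pairwise and the triple intersection
#' (Venn counts consistent by inclusion-exclusion), the cohort-level
#' signature (hypoxia AND overall-survival criteria) with its
#' positive/negative direction split, and the final candidate list (triple
#' intersection) ordered by hypoxia-association p-value.
#'
#' @param criteria A `candidate_criteria` table from [evaluate_criteria()].
#' @return list (class `candidate_sets`): `sets` (hypoxia, os, invitro,
#'   hypoxia_os, hypoxia_invitro, os_invitro, triple), `counts` (same names,
#'   plus `n_screened`), `cohort_signature` (data.frame with direction),
#'   `direction_counts`, `final` (triple-intersection rows ordered by
#'   hypoxia p).
#' @export
intersect_candidates <- function(criteria) {
  stopifnot(inherits(criteria, "candidate_criteria"))
  if (nrow(criteria) == 0L) stop("empty criteria matrix")
  cc <- criteria[!criteria$missing, , drop = FALSE]
  A <- cc$transcript[cc$flag_hypoxia]
  B <- cc$transcript[cc$flag_os]
  C <- cc$transcript[cc$flag_invitro]
  sets <- list(hypoxia = A, os = B, invitro = C,
               hypoxia_os = intersect(A, B),
               hypoxia_invitro = intersect(A, C),
               os_invitro = intersect(B, C),
               triple = Reduce(intersect, list(A, B, C)))
  counts <- c(lapply(sets, length), list(n_screened = nrow(cc)))
  sig <- cc[cc$transcript %in% sets$hypoxia_os, , drop = FALSE]
  sig <- sig[order(sig$hypoxia_adj_p, sig$hypoxia_p, sig$transcript), ]
  dir_counts <- c(positive = sum(sig$direction == "positive", na.rm = TRUE),
                  negative = sum(sig$direction == "negative", na.rm = TRUE))
  final <- cc[cc$transcript %in% sets$triple, , drop = FALSE]
  final <- final[order(final$hypoxia_adj_p, final$hypoxia_p, final$transcript), ]
  structure(list(sets = sets, counts = counts, cohort_signature = sig,
                 direction_counts = dir_counts, final = final),
            class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("candidate screen over", x$counts$n_screened, "transcripts\n")
  cat("  hypoxia:", x$counts$hypoxia, " OS:", x$counts$os,
      " in-vitro:", x$counts$invitro, "\n")
  cat("  cohort signature (hypoxia & OS):", x$counts$hypoxia_os,
      "(", x$direction_counts["positive"], "positive,",
      x$direction_counts["negative"], "negative )\n")
  cat("  final candidates (triple intersection):", x$counts$triple, "\n")
  if (nrow(x$final) > 0L)
    cat("   ", paste(utils::head(x$final$transcript, 10L), collapse = ", "), "\n")
  invisible(x)
}

#' Write Venn-style counts of a candidate screen as JSON
#' @param sets A `candidate_sets` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_venn_counts <- function(sets, path) {
  stopifnot(inherits(sets, "candidate_sets"))
  jsonlite::write_json(c(sets$counts,
                         list(direction = as.list(sets$direction_counts),
                              final = sets$final$transcript)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
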