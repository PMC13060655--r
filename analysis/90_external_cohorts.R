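#!/usr/bin/env Rscript
# OPTIONAL external-data reproductions. These require datasets that are not
# bundled (some are access-controlled) and are therefore wired as a documented
# script, not as tests. Expected published reference points:
#
#   * TCGA LUAD bulk RNA-seq (DESeq2-normalized, log2), 531 tumors +
#     59 healthy: hypoxia count score classes Low n = 428 / High n = 103.
#   * Local LUAD microarray cohort, 57 tumors +
#     11 healthy lungs: scored subset Low n = 12 / High n = 20.
#   * Cohort-level lncRNA signature: 13 transcripts associated with hypoxic
#     status and prognosis, 8 positively / 5 negatively correlated.
#   * Xenograft knockdown contrast: 74 DEGs (63 down) at log2 intensity > 6,
#     |log2FC| > 0.5, adjusted p < 0.05.
#
# Usage: place the downloaded files under data-external/ as
#   tcga_expression.tsv  tcga_clinical.tsv      (gene x sample log2 TSV +
#   local_expression.tsv local_clinical.tsv      clinical TSV per README
#   local_transcripts.txt                        column conventions)
#   invitro_expression.tsv invitro_groups.txt
#   xenograft_expression.tsv xenograft_groups.txt
# then run: Rscript analysis/90_external_cohorts.R

suppressPackageStartupMessages(library(lncscreen))
root <- "data-external"
need <- function(...) {
  f <- file.path(root, c(...))
  ok <- file.exists(f)
  if (!all(ok)) {
    cat("skipping: missing", paste(f[!ok], collapse = ", "), "\n")
    return(NULL)
  }
  f
}
sig <- read_signature(signature_fixture("hypoxia_metagene_27"))

score_cohort <- function(label, expr_path, clin_path) {
  cohort <- align_cohort(read_expression_matrix(expr_path),
                         read_clinical_table(clin_path))
  scores <- hypoxia_score(compute_fold_changes(cohort, sig))
  cat(sprintf("[%s] Low n = %d, High n = %d\n", label,
              sum(scores$class == "Low"), sum(scores$class == "High")))
  invisible(list(cohort = cohort, scores = scores))
}

if (!is.null(f <- need("tcga_expression.tsv", "tcga_clinical.tsv")))
  score_cohort("TCGA LUAD", f[1], f[2])

if (!is.null(f <- need("local_expression.tsv", "local_clinical.tsv",
                       "local_transcripts.txt",
                       "invitro_expression.tsv", "invitro_groups.txt"))) {
  local <- score_cohort("local cohort", f[1], f[2])
  transcripts <- readLines(f[3])
  groups <- readLines(f[5])
  nx <- strsplit(sub("# normoxia: ", "", groups[1]), ",")[[1]]
  hx <- strsplit(sub("# hypoxia: ", "", groups[2]), ",")[[1]]
  de <- two_group_de(read_expression_matrix(f[4]), nx, hx)
  cc <- evaluate_criteria(local$cohort, local$scores, de, transcripts)
  sets <- intersect_candidates(cc)
  print(sets)
  cat(sprintf("cohort signature: %d transcripts (%d positive, %d negative)\n",
              sets$counts$hypoxia_os, sets$direction_counts["positive"],
              sets$direction_counts["negative"]))
}

if (!is.null(f <- need("xenograft_expression.tsv", "xenograft_groups.txt"))) {
  groups <- readLines(f[2])
  g1 <- strsplit(sub("# control: ", "", groups[1]), ",")[[1]]
  g2 <- strsplit(sub("# knockdown: ", "", groups[2]), ",")[[1]]
  sel <- select_degs(two_group_de(read_expression_matrix(f[1]), g1, g2))
  print(sel)
}
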