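#!/usr/bin/env Rscript
# The three-criterion candidate screen: intersect (i) hypoxia-score
# association in tumors, (ii) quartile overall-survival log-rank, and
# (iii) in-vitro hypoxia induction, at both threshold presets.
# Run 01_simulate_cohort.R first.

suppressPackageStartupMessages(library(lncscreen))
out <- file.path("results", "screen")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
sig <- read_signature(signature_fixture("hypoxia_metagene_27"))

expr <- read_expression_matrix(file.path("results", "sim", "screening_expression.tsv"))
clin <- read_clinical_table(file.path("results", "sim", "screening_clinical.tsv"))
cohort <- align_cohort(expr, clin)
transcripts <- readLines(file.path("results", "sim", "screening_transcripts.txt"))
scores <- hypoxia_score(compute_fold_changes(cohort, sig))

iv_expr <- read_expression_matrix(file.path("results", "sim", "invitro_expression.tsv"))
groups <- readLines(file.path("results", "sim", "invitro_groups.txt"))
nx <- strsplit(sub("# normoxia: ", "", groups[1]), ",")[[1]]
hx <- strsplit(sub("# hypoxia: ", "", groups[2]), ",")[[1]]
invitro_de <- two_group_de(iv_expr, nx, hx)

for (preset in c("figure-strict", "methods-loose")) {
  cc <- evaluate_criteria(cohort, scores, invitro_de, transcripts,
                          screen_config(preset))
  sets <- intersect_candidates(cc)
  cat("==", preset, "==\n")
  print(sets)
  utils::write.table(cc, file.path(out, paste0(preset, "_criteria.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_venn_counts(sets, file.path(out, paste0(preset, "_venn.json")))
}
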