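#!/usr/bin/env Rscript
# Generate the synthetic study inputs used throughout the analysis:
# a bulk cohort (expression + clinical), a paired normoxia/hypoxia in-vitro
# experiment, and a clustered single-cell count matrix, all with known
# ground truth. Bulk files are written under results/sim/; the single-cell
# matrix is regenerated on demand by later scripts (it is large but cheap).
#
# Two designs are materialized:
#   * cohort-scale  : 11 healthy / 57 tumor, the motivating cohort's size
#   * screening-scale: 11 healthy / 250 tumor, the validation design at which
#     the strict screen has power (see the methods vignette)

suppressPackageStartupMessages(library(lncscreen))
seed <- 1L
out <- file.path("results", "sim")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (design in c("cohort", "screening")) {
  p <- if (design == "cohort") sim_params() else sim_params(n_tumor = 250)
  sim <- simulate_cohort(p, seed = seed)
  write_expression_matrix(sim$cohort$expr,
                          file.path(out, paste0(design, "_expression.tsv")))
  write_clinical_table(sim$cohort$clinical,
                       file.path(out, paste0(design, "_clinical.tsv")))
  writeLines(sim$truth$transcripts$transcript,
             file.path(out, paste0(design, "_transcripts.txt")))
  utils::write.table(
    data.frame(sample = names(sim$truth$h), h = sim$truth$h,
               f_lec = sim$truth$f_lec, f_immune = sim$truth$f_immune),
    file.path(out, paste0(design, "_truth.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] %d healthy / %d tumor samples, %d genes -> %s\n",
              design, length(sim$cohort$healthy_ids),
              length(sim$cohort$tumor_ids), nrow(sim$cohort$expr), out))
}

iv <- simulate_invitro(sim_params(n_tumor = 250), seed = seed)
write_expression_matrix(iv$expr, file.path(out, "invitro_expression.tsv"))
writeLines(c(paste0("# normoxia: ", paste(iv$normoxia_ids, collapse = ",")),
             paste0("# hypoxia: ", paste(iv$hypoxia_ids, collapse = ","))),
           file.path(out, "invitro_groups.txt"))
cat(sprintf("[invitro] %d + %d replicates, %d genes; planted induced: %s\n",
            length(iv$normoxia_ids), length(iv$hypoxia_ids), nrow(iv$expr),
            paste(setdiff(iv$truth$induced,
                          read_signature(signature_fixture("hypoxia_metagene_27"))$genes),
                  collapse = ", ")))
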