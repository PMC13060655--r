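#!/usr/bin/env Rscript
# Score every tumor of the simulated cohorts with the 27-gene hypoxia
# metagene count (fold change > 2 over the mean healthy baseline; 0-14 Low,
# 15-27 High) and check the score against the generator's latent hypoxia.
# Run 01_simulate_cohort.R first.

suppressPackageStartupMessages(library(lncscreen))
out <- file.path("results", "hypoxia")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
sig <- read_signature(signature_fixture("hypoxia_metagene_27"))

for (design in c("cohort", "screening")) {
  expr <- read_expression_matrix(file.path("results", "sim",
                                           paste0(design, "_expression.tsv")))
  clin <- read_clinical_table(file.path("results", "sim",
                                        paste0(design, "_clinical.tsv")))
  cohort <- align_cohort(expr, clin)
  scores <- hypoxia_score(compute_fold_changes(cohort, sig))
  utils::write.table(scores, file.path(out, paste0(design, "_scores.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- utils::read.table(file.path("results", "sim",
                                       paste0(design, "_truth.tsv")),
                             header = TRUE, sep = "\t")
  h <- truth$h[match(scores$sample, truth$sample)]
  cat(sprintf("[%s] %d Low / %d High; classification vs latent hypoxia: %.0f%% of h > 0.8 High, %.0f%% of h < 0.2 Low\n",
              design, sum(scores$class == "Low"), sum(scores$class == "High"),
              100 * mean(scores$class[h > 0.8] == "High"),
              100 * mean(scores$class[h < 0.2] == "Low")))

  # stroma / immune cumulative z-scores and their planted-fraction recovery
  stroma <- zscore_signature_score(cohort, read_signature(signature_fixture("stroma_141")))
  immune <- zscore_signature_score(cohort, read_signature(signature_fixture("immune_141")))
  utils::write.table(
    data.frame(sample = stroma$sample, stroma = stroma$score, immune = immune$score),
    file.path(out, paste0(design, "_signature_scores.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] z-score recovery: stroma r = %.2f (LEC fraction), immune r = %.2f (immune fraction)\n",
              design,
              cor(stroma$score, truth$f_lec[match(stroma$sample, truth$sample)]),
              cor(immune$score, truth$f_immune[match(immune$sample, truth$sample)])))

  # candidate transcript vs scores: the negative immune association
  pt <- pearson_test(cohort$expr["LNC0001", immune$sample], immune$score)
  cat(sprintf("[%s] candidate vs immune z-score: r = %.2f, p = %.2g\n",
              design, pt$r, pt$p_value))
}
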