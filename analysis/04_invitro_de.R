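#!/usr/bin/env Rscript
# Differential expression of the paired normoxia/hypoxia in-vitro experiment
# (Welch t per gene, BH adjustment) and threshold-based DEG selection with the
# in-vitro dialect (|log2FC| > 0.5, log2 intensity > 6, adjusted p < 0.05).
# Also rebuilds a xenograft-style contrast with 74 planted genes (63 down) to
# exercise the selection rules at their other published dialect.
# Run 01_simulate_cohort.R first.

suppressPackageStartupMessages(library(lncscreen))
out <- file.path("results", "de")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression_matrix(file.path("results", "sim", "invitro_expression.tsv"))
groups <- readLines(file.path("results", "sim", "invitro_groups.txt"))
nx <- strsplit(sub("# normoxia: ", "", groups[1]), ",")[[1]]
hx <- strsplit(sub("# hypoxia: ", "", groups[2]), ",")[[1]]

de <- two_group_de(expr, nx, hx)   # log2FC = hypoxia - normoxia
utils::write.table(de, file.path(out, "invitro_de.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sel <- select_degs(de, min_intensity = 6, min_abs_lfc = 0.5,
                   max_p = 0.05, p_type = "adj")
print(sel)
lnc_hits <- grep("^LNC", sel$genes, value = TRUE)
cat("lncRNAs passing the in-vitro criterion:",
    if (length(lnc_hits)) paste(lnc_hits, collapse = ", ") else "none", "\n")

# xenograft-style contrast: 74 planted DEGs, 63 of them down
lfc <- c(rep(1.5, 11), rep(-1.5, 63))
names(lfc) <- sprintf("XEN%02d", seq_along(lfc))
xen <- simulate_de_experiment(n_genes = 1000, planted_lfc = lfc,
                              n_per_group = 4, noise_sd = 0.15, seed = 46)
xde <- two_group_de(xen$expr, xen$group1_ids, xen$group2_ids)
xsel <- select_degs(xde)
cat(sprintf("xenograft-style selection: %d genes (%d up, %d down); planted recovered exactly: %s\n",
            length(xsel$genes), xsel$n_up, xsel$n_down,
            setequal(xsel$genes, names(lfc))))
utils::write.table(xsel$table, file.path(out, "xenograft_style_degs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
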