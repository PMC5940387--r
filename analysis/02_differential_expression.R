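#!/usr/bin/env Rscript
# Stage 2 — standardize each sample and call differentially expressed
# genes with the empirical-Bayes moderated t (raw p < 0.05 and
# |log2FC| > log2(1.5)), then check recall of the planted genes.

suppressPackageStartupMessages(library(xtalksig))
p <- function(f) file.path("results/analysis", f)

es <- standardize(read_expression(p("expression.tsv"), p("labels.tsv")))
de <- moderated_de_test(es, p_cut = 0.05, fc_cut = 1.5)
write.table(de[, c("gene", "log2fc", "t_mod", "p_value", "q_value", "direction")],
            p("de_table.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.table(p("truth.tsv"), header = TRUE, sep = "\t")
planted <- truth$gene[truth$role %in% c("up", "down")]
flagged <- de_genes(de)
cat(sprintf("prior df %.1f, prior variance %.3f\n",
            attr(de, "df_prior"), attr(de, "var_prior")))
cat(sprintf("flagged %d genes (%d up, %d down)\n", length(flagged),
            sum(de$direction == "up"), sum(de$direction == "down")))
cat(sprintf("recall of planted genes: %.3f; false-positive rate: %.4f\n",
            mean(planted %in% flagged),
            mean(setdiff(de$gene, planted) %in% flagged)))
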