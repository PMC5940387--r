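#!/usr/bin/env Rscript
# Stage 5 — genes shared by at least two enriched pathways are the
# cross-talk candidates; correlation-based feature subset selection
# reduces them to a compact signature (at most 45 genes).

suppressPackageStartupMessages(library(xtalksig))
p <- function(f) file.path("results/analysis", f)

dp <- read_pathway_members(p("pathway_members.tsv"))
ct <- find_crosstalk(dp, min_membership = 2)
write.table(ct, p("crosstalk_genes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

es <- standardize(read_expression(p("expression.tsv"), p("labels.tsv")))
sig <- select_signature(ct, es, max_size = 45)
writeLines(sig$genes, p("signature_genes.txt"))
write.table(sig$trace, p("signature_trace.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.table(p("truth.tsv"), header = TRUE, sep = "\t")
shared <- truth$gene[truth$role == "crosstalk"]
cat(sprintf("genes in >= 2 enriched pathways: %d (of %d designated: %.2f recovered)\n",
            nrow(ct), length(shared), mean(shared %in% ct$gene)))
cat(sprintf("signature: %d genes, CFS merit %.3f\n", length(sig$genes), sig$merit))
cat(sprintf("planted genes in the signature: %.2f\n",
            mean(sig$genes %in% truth$gene[truth$role %in% c("up", "down")])))
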