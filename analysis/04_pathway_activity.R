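#!/usr/bin/env Rscript
# Stage 4 — hypergeometric enrichment of the up/down important genes over
# the gene-set collection, directional pathway annotation, per-sample
# pathway activity scores, and two-group clustering of the samples.

suppressPackageStartupMessages(library(xtalksig))
p <- function(f) file.path("results/analysis", f)

es <- standardize(read_expression(p("expression.tsv"), p("labels.tsv")))
st <- read.table(p("state_scores.tsv"), header = TRUE, sep = "\t")
sets <- read_gmt(p("pathways.gmt"))
up_imp <- st$gene[st$W > 0]
down_imp <- st$gene[st$W < 0]

e_up <- enrich(up_imp, sets, background = nrow(es$values), q_cut = 0.05)
e_down <- if (length(down_imp) > 0) {
  enrich(down_imp, sets, background = nrow(es$values), q_cut = 0.05)
} else e_up[0, ]
enr_out <- rbind(cbind(query = "up", e_up[, 1:6]),
                 cbind(query = "down", e_down[, 1:6]))
write.table(enr_out, p("enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

dp <- annotate_directions(e_up, e_down, up_imp, down_imp)
write_pathway_members(dp, p("pathway_members.tsv"))
psm <- score_matrix(dp, es, eps = 1)
write.table(data.frame(pathway = rownames(psm$scores), psm$scores,
                       check.names = FALSE),
            p("pathway_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
cl <- cluster_samples(psm, es$labels)

classes <- vapply(dp, `[[`, character(1), "class")
cat(sprintf("enriched pathways: %d (%d both, %d up-only, %d down-only)\n",
            length(dp), sum(classes == "both"), sum(classes == "up_only"),
            sum(classes == "down_only")))
tum <- samples_of(es, "tumor")
cat(sprintf("median pathway score, tumor vs control: %.2f vs %.2f\n",
            median(psm$scores[, tum]),
            median(psm$scores[, setdiff(colnames(psm$scores), tum)])))
cat(sprintf("two-group clustering agreement with labels (ARI): %.3f\n",
            cl$agreement))
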