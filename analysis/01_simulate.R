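#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs with planted truth.
#
# Emulates a two-cohort case/control microarray design: a training cohort
# and a validation cohort sharing the same 50 up- / 10 down-regulated
# genes (|log2FC| = 1, noise sd 0.5), a 10000-edge protein-interaction
# style background network with 20 planted well-connected neighbors, six
# overlapping gene sets with 10 designated cross-talk genes, and a
# 200-patient survival cohort whose altered half carries hazard ratio 2.5.

suppressPackageStartupMessages(library(xtalksig))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(seed = 1)
seeds <- derive_seeds(cfg$seed, 10)

train <- generate_expression(cfg$n_genes, cfg$n_tumor, cfg$n_control,
                             cfg$n_up, cfg$n_down, cfg$effect_log2fc,
                             cfg$noise_sd, seed = seeds[1], sample_prefix = "TR")
test <- generate_expression(cfg$n_genes, cfg$n_tumor, cfg$n_control,
                            cfg$n_up, cfg$n_down, cfg$effect_log2fc,
                            cfg$noise_sd, seed = seeds[2],
                            up_genes = train$truth$up_genes,
                            down_genes = train$truth$down_genes,
                            baseline = train$truth$baseline,
                            sample_prefix = "TE")
planted <- c(train$truth$up_genes, train$truth$down_genes)
net <- generate_network(rownames(train$expr$values), cfg$n_edges, planted,
                        cfg$n_connected_neighbors, cfg$min_links,
                        seed = seeds[3])
n_down_sets <- max(1, round(cfg$n_sets * cfg$n_down / (cfg$n_up + cfg$n_down)))
set.seed(seeds[4])
shared_pick <- sample(train$truth$up_genes, cfg$n_shared)
sets <- generate_pathways(
  rownames(train$expr$values), cfg$n_sets, cfg$set_size, cfg$n_shared,
  seed = seeds[4],
  shared_genes = shared_pick,
  member_pool = c(rep(list(train$truth$up_genes), cfg$n_sets - n_down_sets),
                  rep(list(train$truth$down_genes), n_down_sets)),
  pool_frac = 0.5)
surv <- generate_expression(cfg$n_genes, cfg$surv_n_altered,
                            cfg$surv_n_unaltered, cfg$n_up, cfg$n_down,
                            cfg$effect_log2fc, cfg$noise_sd, seed = seeds[5],
                            up_genes = train$truth$up_genes,
                            down_genes = train$truth$down_genes,
                            baseline = train$truth$baseline,
                            sample_prefix = "PT")
true_group <- setNames(ifelse(surv$expr$labels == "tumor", "altered", "unaltered"),
                       names(surv$expr$labels))
clinical <- generate_survival(names(true_group), true_group,
                              cfg$hazard_ratio, cfg$censor_frac, seed = seeds[6])

p <- function(f) file.path("results/analysis", f)
write_expression(train$expr, p("expression.tsv"), p("labels.tsv"))
write_expression(test$expr, p("expression_test.tsv"), p("labels_test.tsv"))
write_expression(surv$expr, p("expression_surv.tsv"), p("labels_surv.tsv"))
write_edge_file(net$edges, p("background_edges.tsv"))
write_gmt(sets, p("pathways.gmt"))
write_clinical(clinical, p("clinical.tsv"))
truth <- rbind(data.frame(gene = train$truth$up_genes, role = "up"),
               data.frame(gene = train$truth$down_genes, role = "down"),
               data.frame(gene = net$neighbors, role = "neighbor"),
               data.frame(gene = attr(sets, "shared"), role = "crosstalk"))
write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("training cohort: %d genes x %d samples\n",
            nrow(train$expr$values), ncol(train$expr$values)))
cat(sprintf("background network: %d nodes, %d edges; %d planted neighbors\n",
            length(unique(unlist(net$edges))), nrow(net$edges),
            length(net$neighbors)))
cat(sprintf("gene sets: %d sets of %d genes, %d designated cross-talk genes\n",
            length(sets), cfg$set_size, length(attr(sets, "shared"))))
cat(sprintf("survival cohort: %d patients (%d altered), %.0f%% censored\n",
            nrow(clinical), sum(clinical$group == "altered"),
            100 * mean(clinical$event == 0)))
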