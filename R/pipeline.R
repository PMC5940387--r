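# Config-driven orchestration of the whole workflow on synthetic data:
# simulate -> diffexpr -> network -> state_score -> pathway -> crosstalk
# -> classifier_eval -> survival. Every stage writes its table under the
# output directory and a JSON manifest records artifacts, parameters,
# seed and stage runtimes. A single master seed is fanned out to fixed
# per-stage child seeds, so reruns are reproducible stage by stage.

#' Default pipeline configuration
#'
#' The synthetic defaults define the reference study conditions: a
#' 2000-gene two-cohort design with 60 tumor / 60 control samples per
#' cohort, 50 up- and 10 down-regulated genes planted at |log2FC| = 1
#' with noise sd 0.5; a 10000-edge preferential-attachment background
#' network with 20 planted neighbors at >= 5 DE links; 6 gene sets of 20
#' genes with 10 designated shared (cross-talk) genes; and a 100 + 100
#' patient survival cohort with hazard ratio 2.5 and 20% censoring.
#'
#' @param seed Master seed.
#' @param outdir Output directory for stage artifacts.
#' @param ... Overrides of any default listed below.
#' @return Named list of class `xt_config`.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("xtalksig_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    # synthetic study conditions
    n_genes = 2000L, n_tumor = 60L, n_control = 60L,
    n_up = 50L, n_down = 10L, effect_log2fc = 1.0, noise_sd = 0.5,
    n_edges = 10000L, n_connected_neighbors = 20L,
    n_sets = 6L, set_size = 20L, n_shared = 10L,
    surv_n_altered = 100L, surv_n_unaltered = 100L,
    hazard_ratio = 2.5, censor_frac = 0.2,
    # analysis thresholds
    p_cut = 0.05, fc_cut = 1.5, min_links = 5L, q_cut = 0.05,
    eps = 1.0, z_cut = 3.0, max_signature = 45L, B = 100L,
    n_trees = 500L, bootstrap_fraction = 0.70, feature_fraction = 0.30)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    .stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("xt_config", "list"))
}

.stage_file <- function(cfg, name) file.path(cfg$outdir, name)

#' Run the full cross-talk signature pipeline
#'
#' Executes all stages on synthetic data generated under the
#' configuration's study conditions, writes one or more TSV artifacts per
#' stage plus a `manifest.json`, and returns the in-memory stage results
#' (including the planted truth, so callers can measure recovery).
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a list with the stage outputs: `truth`, `expr`
#'   (training), `test_expr`, `de`, `background`, `subnet`, `state`,
#'   `pathways`, `psm`, `clustering`, `crosstalk`, `signature`, `model`,
#'   `roc`, `perm`, `surv` (tags, clinical, logrank, km), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 10L)
  manifest <- list(parameters = unclass(cfg), seed = cfg$seed,
                   stages = list())
  artifacts <- character(0)
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- list(runtime_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  add_artifact <- function(...) artifacts <<- c(artifacts, unlist(list(...)))

  ## simulate: training cohort, validation cohort, network, gene sets,
  ## survival cohort sharing the planted genes and baselines
  sim <- stage("simulate", {
    train <- generate_expression(cfg$n_genes, cfg$n_tumor, cfg$n_control,
                                 cfg$n_up, cfg$n_down, cfg$effect_log2fc,
                                 cfg$noise_sd, seed = seeds[1],
                                 sample_prefix = "TR")
    test <- generate_expression(cfg$n_genes, cfg$n_tumor, cfg$n_control,
                                cfg$n_up, cfg$n_down, cfg$effect_log2fc,
                                cfg$noise_sd, seed = seeds[2],
                                up_genes = train$truth$up_genes,
                                down_genes = train$truth$down_genes,
                                baseline = train$truth$baseline,
                                sample_prefix = "TE")
    planted <- c(train$truth$up_genes, train$truth$down_genes)
    net <- generate_network(rownames(train$expr$values), cfg$n_edges,
                            planted, cfg$n_connected_neighbors,
                            cfg$min_links, seed = seeds[3])
    # shared genes drawn from the planted up genes so downstream
    # cross-talk recovery is measurable against the truth; per-set pools
    # keep each generated set direction-coherent (real pathway
    # collections are mostly single-direction), split in proportion to
    # the planted up/down balance
    n_down_sets <- max(1L, round(cfg$n_sets * cfg$n_down / (cfg$n_up + cfg$n_down)))
    pools <- c(rep(list(train$truth$up_genes), cfg$n_sets - n_down_sets),
               rep(list(train$truth$down_genes), n_down_sets))
    sets <- generate_pathways(rownames(train$expr$values), cfg$n_sets,
                              cfg$set_size, cfg$n_shared, seed = seeds[4],
                              shared_genes = .with_seed(seeds[4],
                                sample(train$truth$up_genes, cfg$n_shared)),
                              member_pool = pools, pool_frac = 0.5)
    surv <- generate_expression(cfg$n_genes, cfg$surv_n_altered,
                                cfg$surv_n_unaltered, cfg$n_up, cfg$n_down,
                                cfg$effect_log2fc, cfg$noise_sd,
                                seed = seeds[5],
                                up_genes = train$truth$up_genes,
                                down_genes = train$truth$down_genes,
                                baseline = train$truth$baseline,
                                sample_prefix = "PT")
    true_group <- stats::setNames(
      ifelse(surv$expr$labels == "tumor", "altered", "unaltered"),
      names(surv$expr$labels))
    clinical <- generate_survival(names(true_group), true_group,
                                  cfg$hazard_ratio, cfg$censor_frac,
                                  seed = seeds[6])
    add_artifact(write_expression(train$expr, .stage_file(cfg, "expression.tsv"),
                                  .stage_file(cfg, "labels.tsv")))
    add_artifact(write_expression(test$expr, .stage_file(cfg, "expression_test.tsv"),
                                  .stage_file(cfg, "labels_test.tsv")))
    add_artifact(write_edge_file(net$edges, .stage_file(cfg, "background_edges.tsv")))
    add_artifact(write_gmt(sets, .stage_file(cfg, "pathways.gmt")))
    add_artifact(write_clinical(clinical, .stage_file(cfg, "clinical.tsv")))
    list(train = train, test = test, net = net, sets = sets,
         surv = surv, clinical = clinical)
  })
  truth <- sim$train$truth
  truth$crosstalk_genes <- attr(sim$sets, "shared")
  truth$network_neighbors <- sim$net$neighbors

  ## diffexpr
  expr_std <- standardize(sim$train$expr)
  de <- stage("diffexpr", moderated_de_test(expr_std, cfg$p_cut, cfg$fc_cut))
  add_artifact(.write_tsv(de[, c("gene", "log2fc", "t_mod", "p_value",
                                 "q_value", "direction")],
                          .stage_file(cfg, "de_table.tsv")))

  ## network
  bg <- gene_network(sim$net$edges)
  subnet <- stage("network", extract_specific_network(bg, de, cfg$min_links))
  add_artifact(write_network(subnet, .stage_file(cfg, "subnetwork_edges.tsv"),
                             .stage_file(cfg, "subnetwork_nodes.tsv")))

  ## state score
  state <- stage("state_score", state_scores(expr_std, subnet))
  add_artifact(.write_tsv(state, .stage_file(cfg, "state_scores.tsv")))

  ## pathway
  pw <- stage("pathway", {
    up_imp <- important_genes(state, "up")
    down_imp <- important_genes(state, "down")
    enr_up <- enrich(up_imp, sim$sets, background = cfg$n_genes, q_cut = cfg$q_cut)
    enr_down <- if (length(down_imp) > 0L)
      enrich(down_imp, sim$sets, background = cfg$n_genes, q_cut = cfg$q_cut)
    else .null_enrich(sim$sets)
    dirs <- annotate_directions(enr_up, enr_down, up_imp, down_imp)
    if (length(dirs) == 0L) .stopf("pathway stage: no enriched pathways")
    psm <- score_matrix(dirs, expr_std, eps = cfg$eps)
    clus <- cluster_samples(psm, expr_std$labels)
    list(enr_up = enr_up, enr_down = enr_down, dirs = dirs,
         psm = psm, clustering = clus)
  })
  enr_out <- rbind(cbind(query = "up", pw$enr_up[, 1:6]),
                   cbind(query = "down", pw$enr_down[, 1:6]))
  add_artifact(.write_tsv(enr_out, .stage_file(cfg, "enrichment.tsv")))
  add_artifact(.write_tsv(
    data.frame(pathway = rownames(pw$psm$scores), pw$psm$scores,
               check.names = FALSE), .stage_file(cfg, "pathway_scores.tsv")))

  ## crosstalk + signature
  ct <- stage("crosstalk", {
    tab <- find_crosstalk(pw$dirs)
    if (nrow(tab) == 0L) .stopf("crosstalk stage: no shared genes")
    sig <- select_signature(tab, expr_std, cfg$max_signature)
    list(table = tab, signature = sig)
  })
  add_artifact(.write_tsv(ct$table, .stage_file(cfg, "crosstalk_genes.tsv")))
  add_artifact(.write_tsv(ct$signature$trace, .stage_file(cfg, "signature_trace.tsv")))
  writeLines(ct$signature$genes, .stage_file(cfg, "signature_genes.txt"))
  add_artifact(.stage_file(cfg, "signature_genes.txt"))

  ## classifier evaluation
  test_std <- standardize(sim$test$expr)
  cls <- stage("classifier_eval", {
    fcfg <- forest_config(cfg$n_trees, cfg$bootstrap_fraction,
                          cfg$feature_fraction, seed = seeds[7])
    model <- train_forest(expr_std, ct$signature$genes, fcfg)
    roc <- evaluate(model, test_std)
    perm <- permutation_significance(expr_std, test_std,
                                     rownames(expr_std$values),
                                     k = length(ct$signature$genes),
                                     observed_auc = roc$auc, B = cfg$B,
                                     cfg = fcfg, seed = seeds[8])
    list(model = model, roc = roc, perm = perm)
  })
  add_artifact(.write_tsv(data.frame(threshold = cls$roc$thresholds,
                                     tpr = cls$roc$tpr, fpr = cls$roc$fpr),
                          .stage_file(cfg, "roc_points.tsv")))
  add_artifact(.write_tsv(data.frame(observed_auc = cls$roc$auc,
                                     p_value = cls$perm$p_value,
                                     p_value_strict = cls$perm$p_value_strict,
                                     B = cls$perm$B),
                          .stage_file(cfg, "classifier_summary.tsv")))

  ## survival
  sv <- stage("survival", {
    ctl <- samples_of(expr_std, "control")
    ref_x <- expr_std$values[, ctl, drop = FALSE]
    surv_std <- standardize(sim$surv$expr)
    tags <- tag_altered(surv_std, ct$signature$genes, z_cut = cfg$z_cut,
                        ref_means = rowMeans(ref_x),
                        ref_sds = apply(ref_x, 1, stats::sd))
    rec <- sim$clinical
    rec$group <- unname(tags[rec$sample])
    lr <- if (length(unique(rec$group)) == 2L) logrank(rec) else {
      .warnf("survival stage: a single tagged group; log-rank skipped")
      list(statistic = NA_real_, p_value = NA_real_, n = table(rec$group))
    }
    km <- lapply(stats::setNames(nm = unique(rec$group)),
                 function(g) km_curve(rec, g))
    list(tags = tags, records = rec, logrank = lr, km = km)
  })
  add_artifact(.write_tsv(data.frame(sample = names(sv$tags),
                                     group = unname(sv$tags)),
                          .stage_file(cfg, "survival_tags.tsv")))
  km_df <- do.call(rbind, lapply(names(sv$km), function(g)
    cbind(group = g, sv$km[[g]])))
  add_artifact(.write_tsv(km_df, .stage_file(cfg, "km_curves.tsv")))
  add_artifact(.write_tsv(data.frame(statistic = sv$logrank$statistic,
                                     p_value = sv$logrank$p_value),
                          .stage_file(cfg, "logrank.tsv")))

  manifest$artifacts <- sort(basename(artifacts))
  manifest$total_runtime_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, .stage_file(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    config = cfg, truth = truth,
    expr = expr_std, test_expr = test_std,
    de = de, background = bg, subnet = subnet, state = state,
    enrichment = list(up = pw$enr_up, down = pw$enr_down),
    pathways = pw$dirs, psm = pw$psm, clustering = pw$clustering,
    crosstalk = ct$table, signature = ct$signature,
    model = cls$model, roc = cls$roc, perm = cls$perm,
    surv = sv, manifest = manifest))
}
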