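# Random-forest signature evaluation. Each tree is grown on a 70%
# subsample of training cases and splits consider a random 30% of the
# signature genes; the prediction score of a sample is the fraction of
# trees voting tumor, swept into a ROC curve. Significance comes from a
# permutation null: forests trained on random same-size gene sets.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param bootstrap_fraction Fraction of training cases per tree, sampled
#'   without replacement (default 0.70).
#' @param feature_fraction Fraction of features considered at each split
#'   (default 0.30).
#' @param seed Integer seed for tree growing.
#' @return List of class `xt_forest_config`.
#' @export
forest_config <- function(n_trees = 500, bootstrap_fraction = 0.70,
                          feature_fraction = 0.30, seed = 1) {
  n_trees <- .check_count(n_trees, "n_trees", 1L)
  bootstrap_fraction <- .check_frac(bootstrap_fraction, "bootstrap_fraction", 0, 1, lo_open = TRUE)
  feature_fraction <- .check_frac(feature_fraction, "feature_fraction", 0, 1, lo_open = TRUE)
  structure(list(n_trees = n_trees, bootstrap_fraction = bootstrap_fraction,
                 feature_fraction = feature_fraction, seed = as.integer(seed)),
            class = "xt_forest_config")
}

#' Train the signature random forest
#'
#' @param es Training `xt_expr` (both classes present).
#' @param signature Gene symbols the model may use.
#' @param cfg An [forest_config()].
#' @return List of class `xt_forest`: the fitted ensemble, the gene list,
#'   per-gene training control means (used to impute genes missing from a
#'   test cohort), and the configuration.
#' @export
train_forest <- function(es, signature, cfg = forest_config()) {
  signature <- toupper(signature)
  if (!all(signature %in% rownames(es$values)))
    .stopf("signature genes missing from the training matrix: %s",
           paste(setdiff(signature, rownames(es$values))[1:3], collapse = ", "))
  y <- factor(es$labels, levels = c("control", "tumor"))
  if (nlevels(droplevels(y)) < 2L) .stopf("training set has a single class")
  x <- t(es$values[signature, , drop = FALSE])
  mtry <- max(1L, floor(cfg$feature_fraction * length(signature)))
  dat <- data.frame(x, check.names = FALSE)
  dat$.class <- y
  rf <- ranger::ranger(
    dependent.variable.name = ".class", data = dat,
    num.trees = cfg$n_trees, mtry = mtry,
    sample.fraction = cfg$bootstrap_fraction, replace = FALSE,
    seed = cfg$seed, num.threads = 1L)
  ctl <- samples_of(es, "control")
  ctrl_means <- rowMeans(es$values[signature, ctl, drop = FALSE])
  structure(list(rf = rf, genes = signature, ctrl_means = ctrl_means,
                 cfg = cfg), class = "xt_forest")
}

#' Vote-fraction scores of a forest on new samples
#'
#' @param model An `xt_forest`.
#' @param es Test `xt_expr`. Signature genes absent from the test matrix
#'   are imputed at the training control mean (with a warning).
#' @return Named numeric vector: per sample, the fraction of trees voting
#'   tumor.
#' @export
forest_scores <- function(model, es) {
  miss <- setdiff(model$genes, rownames(es$values))
  have <- intersect(model$genes, rownames(es$values))
  x <- matrix(NA_real_, nrow = ncol(es$values), ncol = length(model$genes),
              dimnames = list(colnames(es$values), model$genes))
  x[, have] <- t(es$values[have, , drop = FALSE])
  if (length(miss) > 0L) {
    .warnf("%d signature genes absent from the test matrix; imputed at training control means (%s...)",
           length(miss), miss[1])
    for (g in miss) x[, g] <- model$ctrl_means[[g]]
  }
  pred <- stats::predict(model$rf, data = data.frame(x, check.names = FALSE),
                         predict.all = TRUE, num.threads = 1L)
  votes <- pred$predictions  # samples x trees, integer level codes
  tumor_code <- which(model$rf$forest$levels == "tumor")
  stats::setNames(rowMeans(votes == tumor_code), colnames(es$values))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (score >= threshold calls
#' tumor) and integrates by the trapezoid rule, which equals the
#' normalized Mann-Whitney U statistic with midrank tie handling.
#'
#' @param scores Numeric vector.
#' @param labels Vector of `"tumor"`/`"control"` aligned with `scores`.
#' @return List of class `xt_roc`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == "tumor"; neg <- !pos
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) .stopf("need both positive and negative cases")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t), numeric(1)) / n1
  fpr <- vapply(thr, function(t) sum(scores[neg] >= t), numeric(1)) / n0
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  thr <- c(Inf, thr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "xt_roc")
}

#' Evaluate a forest on a test cohort
#'
#' @param model An `xt_forest`.
#' @param es Test `xt_expr` with labels and both classes present.
#' @return An `xt_roc` with an extra element `scores`.
#' @export
evaluate <- function(model, es) {
  scores <- forest_scores(model, es)
  roc <- roc_curve(scores, es$labels[names(scores)])
  roc$scores <- scores
  roc
}

#' Permutation significance of an observed AUC
#'
#' Repeats the whole train/evaluate procedure on `B` random gene sets of
#' the signature's size, drawn from the genes common to both cohorts; the
#' primary p-value counts null AUCs `>= observed` (ties against
#' significance); the strict `>` count is also reported.
#'
#' @param train_es,test_es Training and test `xt_expr` objects.
#' @param universe Candidate genes for the random sets (restricted to
#'   genes present in both matrices).
#' @param k Random set size (the signature size).
#' @param observed_auc The signature model's AUC.
#' @param B Number of permutations (default 1000; 100 is a practical
#'   desk-scale value).
#' @param cfg Forest configuration for the null models.
#' @param seed Integer seed; each permutation derives its own child seed.
#' @return List of class `xt_perm`: `observed_auc`, `null_aucs`,
#'   `p_value` (>=), `p_value_strict` (>), `B`.
#' @export
permutation_significance <- function(train_es, test_es, universe, k,
                                     observed_auc, B = 1000,
                                     cfg = forest_config(), seed = 1) {
  universe <- intersect(intersect(toupper(universe), rownames(train_es$values)),
                        rownames(test_es$values))
  k <- .check_count(k, "k", 1L)
  B <- .check_count(B, "B", 1L)
  if (length(universe) < k)
    .stopf("universe (%d genes) smaller than k = %d", length(universe), k)
  seeds <- derive_seeds(seed, 2L * B)
  null_aucs <- numeric(B)
  for (b in seq_len(B)) {
    genes_b <- .with_seed(seeds[b], sample(universe, k))
    cfg_b <- cfg; cfg_b$seed <- seeds[B + b]
    model_b <- train_forest(train_es, genes_b, cfg_b)
    null_aucs[b] <- evaluate(model_b, test_es)$auc
  }
  structure(list(observed_auc = observed_auc, null_aucs = null_aucs,
                 p_value = mean(null_aucs >= observed_auc),
                 p_value_strict = mean(null_aucs > observed_auc),
                 B = B), class = "xt_perm")
}
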