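sim_cohorts <- function(seed = 91, n = 30, n_genes = 60, n_up = 10,
                        effect = 1.5) {
  tr <- generate_expression(n_genes, n, n, n_up, 0, effect, 0.5, seed = seed)
  te <- generate_expression(n_genes, n, n, n_up, 0, effect, 0.5, seed = seed + 1,
                            up_genes = tr$truth$up_genes,
                            down_genes = tr$truth$down_genes,
                            baseline = tr$truth$baseline)
  list(train = tr, test = te)
}

test_that("forest training is deterministic and separates planted signal", {
  co <- sim_cohorts()
  sig <- co$train$truth$up_genes
  cfg <- forest_config(n_trees = 200, seed = 5)
  m1 <- train_forest(co$train$expr, sig, cfg)
  m2 <- train_forest(co$train$expr, sig, cfg)
  s1 <- forest_scores(m1, co$test$expr)
  s2 <- forest_scores(m2, co$test$expr)
  expect_identical(s1, s2)
  roc <- evaluate(m1, co$test$expr)
  expect_gte(roc$auc, 0.9)
  # vote fractions live in [0, 1]
  expect_true(all(s1 >= 0 & s1 <= 1))
  # single-class training is rejected
  es_one <- co$train$expr
  es_one$labels[] <- "tumor"
  expect_error(train_forest(es_one, sig, cfg), "single class")
})

test_that("genes missing from a test cohort are mean-imputed, not dropped", {
  co <- sim_cohorts()
  sig <- co$train$truth$up_genes
  model <- train_forest(co$train$expr, sig, forest_config(n_trees = 100, seed = 2))
  test_small <- subset_genes(co$test$expr, setdiff(rownames(co$test$expr$values),
                                                   sig[1:2]))
  expect_warning(roc <- evaluate(model, test_small), "imputed")
  expect_gte(roc$auc, 0.8)
})

test_that("the ROC sweep reproduces the Mann-Whitney AUC on random score vectors", {
  set.seed(92)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    labels <- sample(c("tumor", "control"), n, TRUE)
    if (length(unique(labels)) < 2) labels <- c("tumor", "control", labels[-(1:2)])
    scores <- sample(seq(0, 1, by = 0.05), n, TRUE)  # ties guaranteed
    auc <- roc_curve(scores, labels)$auc
    expect_equal(auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(roc_curve(c(1, 1, 0, 0), c("tumor", "tumor", "control", "control"))$auc, 1)
  expect_error(roc_curve(1:3, rep("tumor", 3)), "both positive and negative")
})

test_that("label-independent scores give a central AUC", {
  set.seed(93)
  scores <- runif(500)
  labels <- sample(rep(c("tumor", "control"), each = 250))
  auc <- roc_curve(scores, labels)$auc
  expect_gt(auc, 0.43); expect_lt(auc, 0.57)
  # permutation-null mean of the AUC is 0.5 within 3 standard errors
  aucs <- replicate(200, roc_curve(scores, sample(labels))$auc)
  se <- sd(aucs) / sqrt(200)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("permutation significance behaves at its logical extremes and is monotone", {
  co <- sim_cohorts(n = 15, n_genes = 40, n_up = 5)
  cfg <- forest_config(n_trees = 50, seed = 3)
  noise_universe <- setdiff(rownames(co$train$expr$values), co$train$truth$up_genes)
  pr_lo <- permutation_significance(co$train$expr, co$test$expr, noise_universe,
                                    k = 5, observed_auc = 0, B = 10,
                                    cfg = cfg, seed = 7)
  expect_equal(pr_lo$p_value, 1)   # every null ties or beats zero
  pr_hi <- permutation_significance(co$train$expr, co$test$expr, noise_universe,
                                    k = 5, observed_auc = 1 + 1e-9, B = 10,
                                    cfg = cfg, seed = 7)
  expect_equal(pr_hi$p_value, 0)
  # same nulls, higher observed AUC -> no larger p
  expect_identical(pr_lo$null_aucs, pr_hi$null_aucs)
  pr_mid <- permutation_significance(co$train$expr, co$test$expr, noise_universe,
                                     k = 5, observed_auc = 0.6, B = 10,
                                     cfg = cfg, seed = 7)
  expect_lte(pr_mid$p_value, pr_lo$p_value)
  expect_lte(pr_hi$p_value, pr_mid$p_value)
  expect_gte(pr_mid$p_value, pr_mid$p_value_strict)
  expect_error(permutation_significance(co$train$expr, co$test$expr,
                                        noise_universe[1:3], k = 5,
                                        observed_auc = 0.5, B = 2, cfg = cfg),
               "smaller than k")
})
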