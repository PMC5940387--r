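test_that("hypergeometric enrichment matches exact combinatorics", {
  sets <- list(FULLHIT = sprintf("Q%d", 1:5), MISS = sprintf("X%d", 1:5))
  res <- enrich(sprintf("Q%d", 1:5), sets, background = 20)
  # all five query genes inside a 5-gene set from a 20-gene universe
  expect_equal(res$p_value[res$pathway == "FULLHIT"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$pathway == "MISS"], 1)  # overlap 0 -> P(X>=0)=1
  expect_equal(res$overlap[res$pathway == "MISS"], 0)

  set.seed(71)
  for (rep in 1:20) {
    bg_n <- sample(50:200, 1)
    universe <- sprintf("U%03d", seq_len(bg_n))
    set_g <- sample(universe, sample(5:20, 1))
    query <- sample(universe, sample(5:20, 1))
    res <- enrich(query, list(S = set_g), background = bg_n)
    expect_equal(res$p_value, oracle_hyper_tail(res$overlap, length(set_g),
                                                bg_n, length(query)),
                 tolerance = 1e-12)
  }
  expect_error(enrich(character(0), sets, 20), "empty query")
  expect_error(enrich("A", sets, 2), "background")
})

test_that("directional annotation classifies pathways and partitions them", {
  sets <- list(P1 = c("A", "B", "X1"), P2 = c("C", "D", "X2"), P3 = c("A", "D"))
  up <- c("A", "B"); down <- c("C", "D")
  e_up <- enrich(up, sets, background = 10, q_cut = 1.1)    # everything "enriched"
  e_down <- enrich(down, sets, background = 10, q_cut = 1.1)
  dp <- annotate_directions(e_up, e_down, up, down)
  expect_identical(dp[["P1"]]$class, "up_only")
  expect_equal(dp[["P1"]]$up_members, c("A", "B"))
  expect_length(dp[["P1"]]$down_members, 0)
  expect_identical(dp[["P2"]]$class, "down_only")
  expect_identical(dp[["P3"]]$class, "both")
  classes <- vapply(dp, `[[`, character(1), "class")
  expect_equal(sum(classes == "both") + sum(classes == "up_only") +
                 sum(classes == "down_only"), length(dp))
})

test_that("the pathway score evaluates the log squared-deviation ratio", {
  p <- list(name = "P", up_members = "U", down_members = "D", class = "both")
  sample_values <- c(U = 5, D = 4)
  mu <- c(U = 3, D = 3)  # d-mu: up 2, down 1
  expect_equal(pathway_score(p, sample_values, mu), log(4), tolerance = 1e-12)
  # swapping roles negates the score
  p_swap <- list(name = "P", up_members = "D", down_members = "U", class = "both")
  expect_equal(pathway_score(p_swap, sample_values, mu), -log(4), tolerance = 1e-12)
})

test_that("pathway score is antisymmetric and shifts correctly under scaling", {
  set.seed(72)
  for (rep in 1:10) {
    up <- sprintf("U%d", 1:4); down <- sprintf("D%d", 1:3)
    vals <- stats::setNames(rnorm(7, 5, 2), c(up, down))
    mu <- stats::setNames(rnorm(7, 5, 1), c(up, down))
    p <- list(name = "P", up_members = up, down_members = down, class = "both")
    p_rev <- list(name = "P", up_members = down, down_members = up, class = "both")
    s <- pathway_score(p, vals, mu)
    expect_equal(pathway_score(p_rev, vals, mu), -s, tolerance = 1e-12)
    # scaling all deviations by c: 'both' scores unchanged, up_only shifts 2 ln c
    c_ <- 3
    vals_scaled <- mu + c_ * (vals - mu)
    expect_equal(pathway_score(p, vals_scaled, mu), s, tolerance = 1e-12)
    p_up <- list(name = "P", up_members = up, down_members = character(0),
                 class = "up_only")
    expect_equal(pathway_score(p_up, vals_scaled, mu),
                 pathway_score(p_up, vals, mu) + 2 * log(c_), tolerance = 1e-12)
  }
})

test_that("degenerate deviations are guarded", {
  p_up <- list(name = "P", up_members = "U", down_members = character(0),
               class = "up_only")
  # zero up deviation against the eps denominator: large negative sentinel
  expect_warning(s <- pathway_score(p_up, c(U = 3), c(U = 3)), "guarded")
  expect_lt(s, -700)
  p <- list(name = "P", up_members = "U", down_members = "D", class = "both")
  expect_warning(s0 <- pathway_score(p, c(U = 3, D = 2), c(U = 3, D = 2)), "zero deviation")
  expect_equal(s0, 0)
})

test_that("score matrices are deterministic per column and separate planted groups", {
  g <- generate_expression(100, 15, 15, 20, 0, effect_log2fc = 1.2,
                           noise_sd = 0.5, seed = 73)
  up <- g$truth$up_genes
  dp <- structure(list(
    PA = list(name = "PA", up_members = up[1:10], down_members = character(0),
              class = "up_only"),
    PB = list(name = "PB", up_members = up[11:20], down_members = character(0),
              class = "up_only")), class = "xt_pathways")
  psm <- score_matrix(dp, g$expr)
  tum <- samples_of(g$expr, "tumor")
  expect_gt(median(psm$scores["PA", tum]), 0)
  expect_gt(median(psm$scores["PA", tum]),
            median(psm$scores["PA", setdiff(colnames(psm$scores), tum)]))
  # duplicating a sample duplicates its score column
  es2 <- g$expr
  es2$values[, 2] <- es2$values[, 1]
  es2$labels[2] <- es2$labels[1]
  psm2 <- score_matrix(dp, es2)
  expect_identical(unname(psm2$scores[, 1]), unname(psm2$scores[, 2]))
  expect_identical(unname(psm$pattern == "active"), unname(psm$scores > 0))
})

test_that("clustering separates well-separated blocks and survives permutation", {
  set.seed(74)
  scores <- cbind(matrix(rnorm(5 * 20, 3, 0.4), 5), matrix(rnorm(5 * 20, 0, 0.4), 5))
  rownames(scores) <- sprintf("P%d", 1:5)
  colnames(scores) <- sprintf("S%02d", 1:40)
  labels <- stats::setNames(rep(c("tumor", "control"), each = 20), colnames(scores))
  psm <- structure(list(scores = scores,
                        pattern = ifelse(scores > 0, "active", "inactive")),
                   class = "xt_psm")
  cl <- cluster_samples(psm, labels)
  expect_gte(cl$agreement, 0.9)
  # permuting columns relabels but does not change the partition
  perm <- sample(ncol(scores))
  psm_p <- structure(list(scores = scores[, perm], pattern = psm$pattern[, perm]),
                     class = "xt_psm")
  cl_p <- cluster_samples(psm_p, labels)
  expect_identical(cl_p$clusters[colnames(scores)][order(colnames(scores))] ==
                     cl_p$clusters[[colnames(scores)[1]]],
                   cl$clusters[order(colnames(scores))] ==
                     cl$clusters[[colnames(scores)[1]]])
  # identical columns: degenerate, agreement undefined
  flat <- structure(list(scores = matrix(1, 3, 4,
                                         dimnames = list(sprintf("P%d", 1:3),
                                                         sprintf("S%d", 1:4))),
                         pattern = matrix("active", 3, 4)), class = "xt_psm")
  expect_warning(cf <- cluster_samples(flat), "indistinguishable")
  expect_true(is.na(cf$agreement))
})
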