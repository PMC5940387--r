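make_dp <- function(...) {
  sets <- list(...)
  out <- lapply(names(sets), function(nm)
    list(name = nm, up_members = sets[[nm]], down_members = character(0),
         class = "up_only"))
  names(out) <- names(sets)
  structure(out, class = "xt_pathways")
}

test_that("cross-talk genes are exactly those shared by two or more pathways", {
  dp <- make_dp(P1 = c("A", "B"), P2 = c("B", "C"))
  ct <- find_crosstalk(dp)
  expect_identical(ct$gene, "B")
  expect_equal(ct$n_pathways, 2L)
  expect_identical(ct$pathways, "P1;P2")
  # disjoint pathways share nothing
  expect_equal(nrow(find_crosstalk(make_dp(P1 = c("A", "B"), P2 = c("C", "D")))), 0)
})

test_that("membership counting matches brute force and ignores pathway order", {
  set.seed(81)
  for (rep in 1:5) {
    genes <- sprintf("G%02d", 1:50)
    sets <- lapply(1:20, function(i) sample(genes, sample(3:10, 1)))
    names(sets) <- sprintf("P%02d", 1:20)
    dp <- do.call(make_dp, sets)
    ct <- find_crosstalk(dp)
    expect_identical(sort(ct$gene), oracle_crosstalk(dp))
    dp_shuffled <- dp[sample(length(dp))]
    class(dp_shuffled) <- "xt_pathways"
    ct2 <- find_crosstalk(dp_shuffled)
    expect_identical(ct[order(ct$gene), c("gene", "n_pathways", "pathways")],
                     ct2[order(ct2$gene), c("gene", "n_pathways", "pathways")],
                     ignore_attr = TRUE)
  }
})

test_that("the CFS merit formula and its edge cases are exact", {
  # k=2, mean r_cf = 0.5, r_ff = 0.5 -> 1/sqrt(3)
  expect_equal(cfs_merit_formula(2, mean(c(0.6, 0.4)), 0.5), 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(cfs_merit_formula(2, 0.5, 0.5), 0.5773503, tolerance = 1e-6)

  set.seed(82)
  y <- rep(c(1, 0), each = 15)
  m <- rbind(INF = y * 2 + rnorm(30, 0, 0.5),
             NOISE = rnorm(30))
  es <- make_es(m, ifelse(y == 1, "tumor", "control"))
  # singleton merit is |point-biserial correlation|
  expect_equal(cfs_merit("INF", es),
               abs(cor(m["INF", ], y)), tolerance = 1e-12)
  # an exact duplicate adds nothing: with r_ff = 1 the pair merit collapses
  # to the singleton merit, and a noisy near-duplicate is strictly worse
  m2 <- rbind(m, INF2 = m["INF", ], INF3 = m["INF", ] * 0.7 + rnorm(30, 0, 1))
  es2 <- make_es(m2, ifelse(y == 1, "tumor", "control"))
  expect_equal(cfs_merit(c("INF", "INF2"), es2), cfs_merit("INF", es2),
               tolerance = 1e-12)
  expect_lt(cfs_merit(c("INF", "INF3"), es2), cfs_merit("INF", es2))
  # zero-variance gene warned and treated as uncorrelated
  m3 <- rbind(m, FLAT = rep(1, 30))
  es3 <- make_es(m3, ifelse(y == 1, "tumor", "control"))
  expect_warning(mer <- cfs_merit(c("INF", "FLAT"), es3), "zero-variance")
  expect_true(is.finite(mer))
})

test_that("greedy selection keeps one informative gene out of pure noise", {
  hits <- 0
  for (s in 1:10) {
    set.seed(900 + s)
    y <- rep(c(1, 0), each = 20)
    m <- rbind(matrix(rnorm(8 * 40), 8), INF = y * 2 + rnorm(40, 0, 0.5))
    rownames(m)[1:8] <- sprintf("N%d", 1:8)
    es <- make_es(m, ifelse(y == 1, "tumor", "control"))
    sig <- select_signature(rownames(m), es, max_size = 9)
    if (identical(sig$genes, "INF")) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("selection is deterministic, capped, and matches exhaustive search on easy instances", {
  set.seed(83)
  y <- rep(c(1, 0), each = 25)
  m <- rbind(matrix(y * 1.5, 6, 50, byrow = TRUE) + matrix(rnorm(6 * 50, 0, 0.6), 6),
             matrix(rnorm(4 * 50), 4))
  rownames(m) <- c(sprintf("I%d", 1:6), sprintf("N%d", 1:4))
  es <- make_es(m, ifelse(y == 1, "tumor", "control"))
  s1 <- select_signature(rownames(m), es)
  s2 <- select_signature(rownames(m), es)
  expect_identical(s1$genes, s2$genes)
  # the returned subset is the best prefix of the search walk
  expect_identical(s1$genes, s1$trace$gene[seq_along(s1$genes)])
  expect_equal(s1$merit, max(s1$trace$merit), tolerance = 1e-12)
  # max_size=1 returns the single best-correlated candidate
  best1 <- select_signature(rownames(m), es, max_size = 1)
  r_all <- abs(apply(m, 1, function(v) cor(v, y)))
  expect_identical(best1$genes, names(which.max(r_all)))
  # exhaustive search over independent informative features agrees
  small <- rownames(m)[c(1:4, 7, 8)]
  ex <- oracle_best_cfs(small, es)
  gr <- select_signature(small, es, max_size = 6)
  expect_equal(gr$merit, ex$merit, tolerance = 1e-9)
  expect_identical(sort(gr$genes), ex$genes)
})

test_that("strong planted candidates are recovered over noise candidates", {
  g <- generate_expression(300, 60, 60, 45, 0, effect_log2fc = 1,
                           noise_sd = 0.5, seed = 84)
  informative <- g$truth$up_genes
  noise <- setdiff(rownames(g$expr$values), informative)[1:20]
  sig <- select_signature(c(informative, noise), standardize(g$expr),
                          max_size = 45)
  expect_gte(mean(informative %in% sig$genes), 0.8)
})
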