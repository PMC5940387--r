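test_that("expression generator plants the promised signal and is deterministic", {
  g <- generate_expression(200, 20, 20, n_up = 10, n_down = 5,
                           effect_log2fc = 1, noise_sd = 0.5, seed = 7)
  g2 <- generate_expression(200, 20, 20, n_up = 10, n_down = 5,
                            effect_log2fc = 1, noise_sd = 0.5, seed = 7)
  expect_identical(g$expr$values, g2$expr$values)
  expect_length(intersect(g$truth$up_genes, g$truth$down_genes), 0)
  expect_true(all(c(g$truth$up_genes, g$truth$down_genes) %in% rownames(g$expr$values)))
  tum <- samples_of(g$expr, "tumor"); ctl <- samples_of(g$expr, "control")
  diff_up <- rowMeans(g$expr$values[g$truth$up_genes, tum]) -
    rowMeans(g$expr$values[g$truth$up_genes, ctl])
  diff_dn <- rowMeans(g$expr$values[g$truth$down_genes, tum]) -
    rowMeans(g$expr$values[g$truth$down_genes, ctl])
  expect_true(all(abs(diff_up - 1) < 0.6))
  expect_true(all(abs(diff_dn + 1) < 0.6))
  g3 <- generate_expression(200, 20, 20, n_up = 10, n_down = 5,
                            effect_log2fc = 1, noise_sd = 0.5, seed = 8)
  expect_false(identical(g$expr$values, g3$expr$values))
})

test_that("a zero effect size gives a null dataset", {
  set.seed(301)
  seeds <- sample.int(1e6, 50)
  nonsig <- vapply(seeds, function(s) {
    g <- generate_expression(20, 15, 15, n_up = 1, n_down = 0,
                             effect_log2fc = 0, noise_sd = 0.5, seed = s)
    gene <- g$truth$up_genes
    p <- t.test(g$expr$values[gene, samples_of(g$expr, "tumor")],
                g$expr$values[gene, samples_of(g$expr, "control")])$p.value
    p >= 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("expression generator validates its parameters", {
  expect_error(generate_expression(10, 0, 5, 1, 1, 1, 0.5, 1), "n_tumor")
  expect_error(generate_expression(10, 5, 5, 1, 1, 1, -1, 1), "noise_sd")
  expect_error(generate_expression(10, 5, 5, 8, 8, 1, 0.5, 1), "exceeds")
  expect_error(generate_expression(10, 5, 5, 1, 1, 1, 0.5, 1,
                                   up_genes = "G00001", down_genes = "G00001"),
               "disjoint")
})

test_that("network generator emits a simple graph with guaranteed neighbors", {
  genes <- sprintf("G%05d", 1:300)
  de <- genes[1:40]
  net <- generate_network(genes, 1500, de, n_connected_neighbors = 15,
                          min_links = 5, seed = 3)
  e <- net$edges
  expect_equal(nrow(e), 1500)
  expect_true(all(e$from != e$to))
  expect_false(any(duplicated(paste(e$from, e$to))))
  expect_true(all(e$from < e$to))  # canonical order implies no (b,a) twins
  # brute-force DE-link count for every planted neighbor
  for (nb in net$neighbors) {
    nbrs <- c(e$to[e$from == nb], e$from[e$to == nb])
    expect_gte(sum(nbrs %in% de), 5)
  }
  expect_length(net$neighbors, 15)
  expect_false(any(net$neighbors %in% de))
  # determinism
  net2 <- generate_network(genes, 1500, de, 15, 5, seed = 3)
  expect_identical(net$edges, net2$edges)
})

test_that("network generator rejects infeasible requests", {
  genes <- sprintf("G%05d", 1:50)
  expect_error(generate_network(genes, 10, genes[1:5], 10, 5, seed = 1),
               "edge budget")
  expect_error(generate_network(genes, 100, genes[1:3], 2, 5, seed = 1),
               "min_links")
  expect_error(generate_network(genes, 5000, genes[1:5], 0, 5, seed = 1),
               "maximum")
})

test_that("pathway generator produces exactly the designated sharing structure", {
  genes <- sprintf("G%05d", 1:500)
  sets <- generate_pathways(genes, n_sets = 8, set_size = 15, n_shared = 10,
                            seed = 5)
  shared <- attr(sets, "shared")
  expect_length(shared, 10)
  cnt <- table(unlist(sets))
  expect_true(all(cnt[shared] >= 2))
  others <- setdiff(names(cnt), shared)
  expect_true(all(cnt[others] == 1))
  expect_true(all(lengths(sets) == 15))
  # per-set member pools stay inside their pool plus shared/filler
  pools <- rep(list(genes[1:60]), 8)
  sets2 <- generate_pathways(genes, 8, 15, 4, seed = 6, member_pool = pools,
                             pool_frac = 0.5)
  expect_true(all(table(unlist(sets2))[attr(sets2, "shared")] >= 2))
})

test_that("pathway generator raises on infeasible sharing", {
  genes <- sprintf("G%05d", 1:100)
  expect_error(generate_pathways(genes, 1, 10, 5, seed = 1), "single set")
  expect_error(generate_pathways(genes, 2, 10, 12, seed = 1), "n_shared exceeds")
  expect_error(generate_pathways(genes, 20, 40, 0, seed = 1), "too small")
})

test_that("survival generator separates hazards and validates input", {
  samp <- sprintf("P%03d", 1:400)
  grp <- stats::setNames(rep(c("altered", "unaltered"), each = 200), samp)
  cl <- generate_survival(samp, grp, hazard_ratio = 3, censor_frac = 0.2, seed = 9)
  expect_equal(nrow(cl), 400)
  expect_true(all(cl$time_days >= 0))
  expect_true(all(cl$event %in% c(0, 1)))
  # exponential means scale inversely with hazard
  mean_alt <- mean(cl$time_days[cl$group == "altered"])
  mean_un <- mean(cl$time_days[cl$group == "unaltered"])
  expect_lt(mean_alt, mean_un)
  expect_equal(mean(cl$event == 0), 0.2, tolerance = 0.1)
  expect_error(generate_survival(samp, grp[1:10], 2, 0.2, 1), "group")
  expect_error(generate_survival(samp, grp, -1, 0.2, 1), "hazard_ratio")
  expect_error(generate_survival(character(0), grp, 2, 0.2, 1), "empty")
})

test_that("generated data survive a TSV/GMT round trip unchanged", {
  g <- generate_expression(50, 6, 6, 5, 2, 1, 0.5, seed = 21)
  vp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(g$expr, vp, lp)
  back <- read_expression(vp, lp)
  expect_equal(back$values, g$expr$values, tolerance = 1e-12)
  expect_identical(back$labels, g$expr$labels)

  sets <- generate_pathways(rownames(g$expr$values), 3, 8, 2, seed = 2)
  gp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gp)
  back_sets <- read_gmt(gp)
  expect_identical(back_sets, stats::setNames(lapply(sets, identity), names(sets)))

  grp <- stats::setNames(rep_len(c("altered", "unaltered"),
                                 ncol(g$expr$values)),
                         colnames(g$expr$values))
  cl <- generate_survival(colnames(g$expr$values), grp, 2, 0.1, seed = 4)
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(cl, cp)
  back_cl <- read_clinical(cp)
  expect_equal(back_cl$time_days, cl$time_days, tolerance = 1e-12)
  expect_identical(back_cl$event, cl$event)
})
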