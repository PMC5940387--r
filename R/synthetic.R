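# Synthetic data with planted truth: a two-group expression matrix with
# known up/down genes, a preferential-attachment background network with
# planted well-connected neighbors, overlapping gene sets with designated
# shared (cross-talk) genes, and exponential survival with a
# group-dependent hazard. Every generator is deterministic under its seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a two-group expression matrix with planted differential genes
#'
#' Background genes are drawn `Normal(baseline_g, noise_sd)` in both groups;
#' planted genes are additionally shifted by `+effect_log2fc` (up genes) or
#' `-effect_log2fc` (down genes) in tumor samples only. Per-gene baselines
#' emulate log2 intensity levels and are drawn `Normal(8, 1)` unless
#' supplied, so that per-sample standardization keeps a planted
#' `|log2FC| = 1` above the `log2(1.5)` fold-change threshold.
#'
#' @param n_genes,n_tumor,n_control Positive counts.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes
#'   (`n_up + n_down <= n_genes`).
#' @param effect_log2fc Planted absolute log2 fold change (>= 0; 0 gives a
#'   null dataset).
#' @param noise_sd Within-group standard deviation (> 0).
#' @param seed Integer RNG seed.
#' @param up_genes,down_genes Optional explicit planted gene identities
#'   (subsets of the symbol universe `G00001..`); used to share planted
#'   structure across cohorts. Overrides `n_up`/`n_down`.
#' @param baseline Optional named numeric vector of per-gene baselines to
#'   reuse across cohorts.
#' @param sample_prefix Prefix for sample IDs.
#' @return List with `expr` (an [expr_set()]) and `truth` (class
#'   `xt_truth`: planted genes, effect, noise, baselines, seed).
#' @export
generate_expression <- function(n_genes, n_tumor, n_control,
                                n_up, n_down, effect_log2fc, noise_sd,
                                seed,
                                up_genes = NULL, down_genes = NULL,
                                baseline = NULL,
                                sample_prefix = "S") {
  n_genes <- .check_count(n_genes, "n_genes", 1L)
  n_tumor <- .check_count(n_tumor, "n_tumor", 1L)
  n_control <- .check_count(n_control, "n_control", 1L)
  if (!is.numeric(effect_log2fc) || effect_log2fc < 0)
    .stopf("'effect_log2fc' must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    .stopf("'noise_sd' must be > 0")
  genes <- sprintf("G%05d", seq_len(n_genes))
  .with_seed(seed, {
    if (is.null(up_genes) || is.null(down_genes)) {
      n_up <- .check_count(n_up, "n_up")
      n_down <- .check_count(n_down, "n_down")
      if (n_up + n_down > n_genes)
        .stopf("n_up + n_down exceeds n_genes")
      planted <- sample(genes, n_up + n_down)
      up_genes <- planted[seq_len(n_up)]
      down_genes <- setdiff(planted, up_genes)
    } else {
      up_genes <- toupper(up_genes); down_genes <- toupper(down_genes)
      if (length(intersect(up_genes, down_genes)) > 0L)
        .stopf("up_genes and down_genes must be disjoint")
      if (!all(c(up_genes, down_genes) %in% genes))
        .stopf("planted genes must lie in the symbol universe G00001..G%05d", n_genes)
    }
    if (is.null(baseline)) {
      baseline <- stats::setNames(stats::rnorm(n_genes, mean = 8, sd = 1), genes)
    } else {
      if (!all(genes %in% names(baseline)))
        .stopf("'baseline' must cover every gene")
      baseline <- baseline[genes]
    }
    n <- n_tumor + n_control
    samples <- sprintf("%s%03d", sample_prefix, seq_len(n))
    labels <- stats::setNames(rep(c("tumor", "control"), c(n_tumor, n_control)), samples)
    m <- matrix(stats::rnorm(n_genes * n, mean = 0, sd = noise_sd),
                nrow = n_genes, dimnames = list(genes, samples))
    m <- m + baseline
    tum <- labels == "tumor"
    m[up_genes, tum] <- m[up_genes, tum] + effect_log2fc
    m[down_genes, tum] <- m[down_genes, tum] - effect_log2fc
    truth <- structure(list(up_genes = up_genes, down_genes = down_genes,
                            effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                            baseline = baseline, seed = seed),
                       class = "xt_truth")
    list(expr = expr_set(m, labels), truth = truth)
  })
}

#' Generate a background interaction network with planted neighbors
#'
#' Exactly `n_connected_neighbors` non-DE genes are first guaranteed at
#' least `min_links` edges to distinct DE genes; the remaining edge budget
#' is filled by preferential attachment (endpoint probability proportional
#' to degree + 1), which produces the heavy-tailed degree distribution of
#' protein-interaction networks. The result is a simple undirected graph.
#'
#' @param genes Gene symbol universe.
#' @param n_edges Total number of edges.
#' @param de_genes Planted differentially expressed genes (subset of
#'   `genes`).
#' @param n_connected_neighbors Number of non-DE genes planted with
#'   guaranteed DE connectivity.
#' @param min_links Minimum DE links per planted neighbor.
#' @param seed Integer RNG seed.
#' @return List with `edges` (data frame `from`/`to`, canonical order) and
#'   `neighbors` (the planted neighbor symbols).
#' @export
generate_network <- function(genes, n_edges, de_genes,
                             n_connected_neighbors, min_links, seed) {
  genes <- toupper(genes); de_genes <- toupper(de_genes)
  n_edges <- .check_count(n_edges, "n_edges", 1L)
  n_nb <- .check_count(n_connected_neighbors, "n_connected_neighbors")
  min_links <- .check_count(min_links, "min_links", 1L)
  if (!all(de_genes %in% genes)) .stopf("de_genes must be a subset of genes")
  non_de <- setdiff(genes, de_genes)
  if (n_nb > length(non_de))
    .stopf("not enough non-DE genes for %d planted neighbors", n_nb)
  if (min_links > length(de_genes))
    .stopf("min_links exceeds the number of DE genes")
  if (n_nb * min_links > n_edges)
    .stopf("edge budget %d cannot hold %d neighbors x %d links", n_edges, n_nb, min_links)
  max_edges <- choose(length(genes), 2)
  if (n_edges > max_edges) .stopf("n_edges exceeds the simple-graph maximum")

  .with_seed(seed, {
    idx <- stats::setNames(seq_along(genes), genes)
    deg <- integer(length(genes))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    from <- integer(n_edges); to <- integer(n_edges); k <- 0L
    add_edge <- function(a, b) {
      if (a == b) return(FALSE)
      key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
      if (!is.null(seen[[key]])) return(FALSE)
      assign(key, TRUE, envir = seen)
      k <<- k + 1L; from[k] <<- a; to[k] <<- b
      deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
      TRUE
    }
    neighbors <- if (n_nb > 0L) sample(non_de, n_nb) else character(0)
    for (nb in neighbors) {
      partners <- sample(de_genes, min_links)
      for (p in partners) add_edge(idx[[nb]], idx[[p]])
    }
    guard <- 0L
    while (k < n_edges) {
      w <- deg + 1
      a <- sample.int(length(genes), 1L, prob = w)
      b <- sample.int(length(genes), 1L, prob = w)
      if (!add_edge(a, b)) {
        guard <- guard + 1L
        if (guard > 50L * n_edges)
          .stopf("preferential attachment failed to place %d edges", n_edges)
      }
    }
    g_from <- genes[from]; g_to <- genes[to]
    a <- pmin(g_from, g_to); b <- pmax(g_from, g_to)
    list(edges = data.frame(from = a, to = b, stringsAsFactors = FALSE),
         neighbors = neighbors)
  })
}

#' Generate overlapping gene sets with designated shared genes
#'
#' Exactly `n_shared` designated genes are each placed in two distinct
#' sets; every other member gene appears in exactly one set, so the shared
#' genes are precisely the cross-talk genes of the collection.
#'
#' @param genes Gene symbol universe.
#' @param n_sets Number of sets (>= 2 when `n_shared > 0`).
#' @param set_size Members per set.
#' @param n_shared Number of designated shared genes (`<= set_size`).
#' @param seed Integer RNG seed.
#' @param shared_genes Optional explicit shared-gene identities.
#' @param member_pool Optional pool the non-shared members are drawn from
#'   first (e.g. planted signal genes), before filling from the remaining
#'   universe. Either one character vector for all sets, or a list of
#'   `n_sets` per-set pools (gene sets are usually functionally coherent,
#'   so a generator emulating real pathway collections gives each set a
#'   pool of one regulation direction).
#' @param pool_frac Fraction of each set's non-shared slots drawn from
#'   `member_pool` (subject to pool availability).
#' @return Named list of character vectors with attribute `shared` (the
#'   designated shared genes); writable with [write_gmt()].
#' @export
generate_pathways <- function(genes, n_sets, set_size, n_shared, seed,
                              shared_genes = NULL, member_pool = NULL,
                              pool_frac = 0.5) {
  genes <- toupper(genes)
  n_sets <- .check_count(n_sets, "n_sets", 1L)
  set_size <- .check_count(set_size, "set_size", 1L)
  n_shared <- .check_count(n_shared, "n_shared")
  if (n_shared > set_size) .stopf("n_shared exceeds set_size")
  if (n_shared > 0L && n_sets < 2L)
    .stopf("a single set cannot share genes: n_sets must be >= 2 when n_shared > 0")
  n_unique <- n_sets * set_size - 2L * n_shared
  if (n_unique < 0L)
    .stopf("sets cannot hold %d shared genes twice each", n_shared)
  if (n_shared + n_unique > length(genes))
    .stopf("gene universe (%d) too small for %d sets of %d with %d shared",
           length(genes), n_sets, set_size, n_shared)

  .with_seed(seed, {
    if (is.null(shared_genes)) {
      shared_genes <- if (n_shared > 0L) sample(genes, n_shared) else character(0)
    } else {
      shared_genes <- toupper(shared_genes)
      if (length(shared_genes) != n_shared || !all(shared_genes %in% genes))
        .stopf("'shared_genes' must be %d genes from the universe", n_shared)
    }
    # each shared gene goes into two distinct sets, round-robin so no set
    # overflows its shared capacity
    slots <- rep(set_size, n_sets)
    assign_sets <- vector("list", n_sets)
    if (n_shared > 0L) {
      pair_idx <- cbind(rep(seq_len(n_sets), length.out = n_shared),
                        rep(seq_len(n_sets), length.out = n_shared + 1L)[-1])
      for (i in seq_len(n_shared)) {
        s1 <- pair_idx[i, 1]; s2 <- pair_idx[i, 2]
        if (s1 == s2) s2 <- s2 %% n_sets + 1L
        assign_sets[[s1]] <- c(assign_sets[[s1]], shared_genes[i])
        assign_sets[[s2]] <- c(assign_sets[[s2]], shared_genes[i])
        slots[s1] <- slots[s1] - 1L; slots[s2] <- slots[s2] - 1L
      }
      if (any(slots < 0L))
        .stopf("n_shared too large relative to n_sets * set_size")
    }
    pools <- if (is.list(member_pool)) {
      if (length(member_pool) != n_sets)
        .stopf("a list 'member_pool' needs one pool per set")
      lapply(member_pool, function(p) intersect(setdiff(toupper(p), shared_genes), genes))
    } else {
      p <- intersect(setdiff(toupper(member_pool %||% character(0)), shared_genes), genes)
      rep(list(p), n_sets)
    }
    all_pool <- unique(unlist(pools))
    rest <- sample(setdiff(genes, c(shared_genes, all_pool)))
    used <- character(0)
    sets <- vector("list", n_sets)
    for (s in seq_len(n_sets)) {
      avail <- sample(setdiff(pools[[s]], used))
      want_pool <- min(floor(pool_frac * slots[s]), length(avail))
      take_pool <- if (want_pool > 0L) avail[seq_len(want_pool)] else character(0)
      used <- c(used, take_pool)
      need <- slots[s] - length(take_pool)
      if (need > length(rest)) .stopf("ran out of unique member genes")
      take_rest <- if (need > 0L) rest[seq_len(need)] else character(0)
      rest <- setdiff(rest, take_rest)
      sets[[s]] <- sort(c(assign_sets[[s]], take_pool, take_rest))
    }
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    attr(sets, "shared") <- sort(shared_genes)
    sets
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate exponential survival times with a group-dependent hazard
#'
#' Event times are exponential with rate `base_rate` for the unaltered
#' group and `base_rate * hazard_ratio` for the altered group; censoring
#' indicators are drawn independently of group and time.
#'
#' @param samples Sample IDs.
#' @param group Named character vector mapping each sample to `"altered"`
#'   or `"unaltered"`.
#' @param hazard_ratio Positive hazard multiplier for the altered group.
#' @param censor_frac Probability a record is censored, in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param base_rate Baseline event rate per day.
#' @return Data frame `sample`, `time_days`, `event` (0/1), `group`.
#' @export
generate_survival <- function(samples, group, hazard_ratio, censor_frac,
                              seed, base_rate = 1 / 1000) {
  if (length(samples) == 0L) .stopf("empty sample list")
  group <- group[samples]
  if (any(is.na(group)) || !all(group %in% c("altered", "unaltered")))
    .stopf("every sample needs a group in {altered, unaltered}")
  if (!any(group == "altered") || !any(group == "unaltered"))
    .stopf("both groups must be non-empty")
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    .stopf("'hazard_ratio' must be > 0")
  censor_frac <- .check_frac(censor_frac, "censor_frac", 0, 1 - 1e-12)
  .with_seed(seed, {
    rate <- base_rate * ifelse(group == "altered", hazard_ratio, 1)
    time <- stats::rexp(length(samples), rate = rate)
    event <- stats::rbinom(length(samples), 1L, prob = 1 - censor_frac)
    data.frame(sample = samples, time_days = time, event = event,
               group = unname(group), stringsAsFactors = FALSE)
  })
}
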