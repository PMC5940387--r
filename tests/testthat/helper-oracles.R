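# Brute-force oracles and small fixture builders shared across tests.
# Every oracle is written independently of the implementation it checks.

# tiny expression set from a plain matrix and a label vector
make_es <- function(m, labels) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  expr_set(m, stats::setNames(labels, colnames(m)))
}

# random simple undirected graph as an edge data frame
random_edges <- function(n_nodes, n_edges, prefix = "N") {
  nodes <- sprintf("%s%03d", prefix, seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  pick <- sample(nrow(pairs), n_edges)
  data.frame(from = pairs[pick, 1], to = pairs[pick, 2],
             stringsAsFactors = FALSE)
}

# oracle: disease-specific subnetwork by literal per-node neighbor scan
oracle_subnetwork <- function(edges, de, min_links) {
  nodes <- unique(c(edges$from, edges$to))
  nbrs <- function(v) unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  de_in <- intersect(de, nodes)
  introduced <- character(0)
  for (v in setdiff(nodes, de)) {
    if (sum(nbrs(v) %in% de_in) >= min_links) introduced <- c(introduced, v)
  }
  keep_nodes <- c(de_in, introduced)
  keep <- edges$from %in% keep_nodes & edges$to %in% keep_nodes
  a <- pmin(edges$from[keep], edges$to[keep])
  b <- pmax(edges$from[keep], edges$to[keep])
  list(nodes = sort(keep_nodes),
       edges = sort(paste(a, b, sep = "|")))
}

# oracle: AUC as Mann-Whitney U by explicit pair counting with ties = 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "tumor"]; neg <- scores[labels == "control"]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# oracle: hypergeometric upper tail by pmf summation with choose()
oracle_hyper_tail <- function(overlap, set_size, background, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(vapply(ks, function(k)
    choose(set_size, k) * choose(background - set_size, query_size - k),
    numeric(1))) / choose(background, query_size)
}

# oracle: two-group log-rank by hand-tabulated risk sets
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# oracle: membership counts over pathway member lists
oracle_crosstalk <- function(pathways, min_membership = 2) {
  genes <- unlist(lapply(pathways, function(p) unique(c(p$up_members, p$down_members))))
  cnt <- table(genes)
  sort(names(cnt)[cnt >= min_membership])
}

# oracle: exhaustive CFS search over all non-empty subsets
oracle_best_cfs <- function(genes, es) {
  best <- -Inf; best_set <- NULL
  for (k in seq_along(genes)) {
    combs <- combn(genes, k, simplify = FALSE)
    for (s in combs) {
      m <- cfs_merit(s, es)
      if (m > best) { best <- m; best_set <- s }
    }
  }
  list(merit = best, genes = sort(best_set))
}
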