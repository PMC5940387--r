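# Pathway stage: hypergeometric enrichment of the up- and down-regulated
# important genes over a GMT collection, directional annotation of the
# enriched pathways, a per-sample pathway activity score (log-ratio of
# summed squared deviations of up members over down members relative to
# control means), and hierarchical clustering of samples on the scores.

#' Hypergeometric gene-set enrichment
#'
#' One-sided tail `P(X >= overlap)` for each set, with Benjamini-Hochberg
#' correction across the collection; sets with `q_value < q_cut` are
#' flagged enriched.
#'
#' @param query Gene symbols (the up or down important genes).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Size of the gene universe.
#' @param q_cut Enrichment call threshold on the q-value (default 0.05).
#' @return Data frame (class `xt_enrich`) with one row per set: `pathway`,
#'   `set_size`, `overlap`, `p_value`, `q_value`, `enriched`, and a
#'   list-column `hit_genes`.
#' @export
enrich <- function(query, collection, background, q_cut = 0.05) {
  query <- unique(toupper(query))
  if (length(query) == 0L) .stopf("empty query gene list")
  if (length(collection) == 0L) .stopf("empty gene-set collection")
  background <- .check_count(background, "background", 1L)
  universe_need <- length(unique(c(unlist(collection), query)))
  if (background < universe_need)
    .stopf("background (%d) smaller than the union of sets and query (%d)",
           background, universe_need)
  hits <- lapply(collection, function(s) intersect(toupper(s), query))
  set_size <- lengths(collection)
  overlap <- lengths(hits)
  # P(X >= k) for X ~ Hypergeometric(set_size, background - set_size, |query|)
  p <- stats::phyper(overlap - 1, set_size, background - set_size,
                     length(query), lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pathway = names(collection), set_size = set_size,
                    overlap = overlap, p_value = p, q_value = q,
                    enriched = q < q_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$hit_genes <- unname(hits)
  class(out) <- c("xt_enrich", "data.frame")
  out
}

# enrichment result for an empty query: nothing overlaps, nothing enriched
.null_enrich <- function(collection) {
  out <- data.frame(pathway = names(collection), set_size = lengths(collection),
                    overlap = 0L, p_value = 1, q_value = 1, enriched = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$hit_genes <- replicate(length(collection), character(0), simplify = FALSE)
  class(out) <- c("xt_enrich", "data.frame")
  out
}

#' Annotate enriched pathways with directional membership
#'
#' Unions the pathways enriched in the up run and the down run; each
#' pathway's members are the query hits of the two runs, classified as up
#' or down by the input lists, giving a class of `both`, `up_only` or
#' `down_only`.
#'
#' @param enriched_up,enriched_down `xt_enrich` tables from [enrich()] for
#'   the up and down queries.
#' @param up_genes,down_genes The up and down query gene lists.
#' @return List of directed pathways (class `xt_pathways`); each element
#'   has `name`, `up_members`, `down_members`, `class`.
#' @export
annotate_directions <- function(enriched_up, enriched_down,
                                up_genes, down_genes) {
  up_genes <- toupper(up_genes); down_genes <- toupper(down_genes)
  take <- function(tab) tab$pathway[tab$enriched]
  sel <- union(take(enriched_up), take(enriched_down))
  hit_of <- function(tab, pw) {
    i <- match(pw, tab$pathway)
    if (is.na(i)) character(0) else tab$hit_genes[[i]]
  }
  out <- lapply(sel, function(pw) {
    up_m <- sort(intersect(unique(c(hit_of(enriched_up, pw),
                                    hit_of(enriched_down, pw))), up_genes))
    down_m <- sort(intersect(unique(c(hit_of(enriched_up, pw),
                                      hit_of(enriched_down, pw))), down_genes))
    cls <- if (length(up_m) > 0L && length(down_m) > 0L) "both"
           else if (length(up_m) > 0L) "up_only" else "down_only"
    list(name = pw, up_members = up_m, down_members = down_m, class = cls)
  })
  names(out) <- sel
  structure(out, class = "xt_pathways")
}

#' Write directed pathways as a long member table
#' @param pathways An `xt_pathways` list.
#' @param path Output TSV path (columns pathway, gene, direction, class).
#' @export
write_pathway_members <- function(pathways, path) {
  rows <- do.call(rbind, lapply(pathways, function(p) {
    data.frame(pathway = p$name,
               gene = c(p$up_members, p$down_members),
               direction = rep(c("up", "down"),
                               c(length(p$up_members), length(p$down_members))),
               class = p$class, stringsAsFactors = FALSE)
  }))
  .write_tsv(rows, path)
}

#' Read directed pathways from a member table
#' @param path TSV written by [write_pathway_members()].
#' @return An `xt_pathways` list.
#' @export
read_pathway_members <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$pathway), function(d)
    list(name = d$pathway[1],
         up_members = sort(d$gene[d$direction == "up"]),
         down_members = sort(d$gene[d$direction == "down"]),
         class = d$class[1]))
  structure(out[unique(df$pathway)], class = "xt_pathways")
}

# sentinel used when a zero numerator or denominator would give +-Inf
.SCORE_SENTINEL <- 745

#' Per-sample activity score of a directed pathway
#'
#' `score = ln( sum_up (d_i - mu_i)^2 / sum_down (d_j - mu_j)^2 )`, where
#' `d` is the sample's expression of a member gene and `mu` the gene's
#' mean over control samples. A pathway with no up (or no down) members
#' has that sum replaced by `eps`, keeping the ratio defined. A positive
#' score is an active pattern, a negative score inactive.
#'
#' @param p A directed pathway (element of [annotate_directions()] output).
#' @param sample_values Named numeric vector: one sample's expression.
#' @param control_means Named numeric vector of per-gene control means.
#' @param eps Substitute for an empty up or down sum (default 1).
#' @return A single score. A zero sum over a non-empty member list gives
#'   the guarded value `+-745` with a warning; both sums zero gives 0 with
#'   a warning.
#' @export
pathway_score <- function(p, sample_values, control_means, eps = 1.0) {
  sq_sum <- function(members) {
    members <- intersect(members, names(sample_values))
    members <- intersect(members, names(control_means))
    if (length(members) == 0L) return(NULL)
    sum((sample_values[members] - control_means[members])^2)
  }
  up <- sq_sum(p$up_members)
  down <- sq_sum(p$down_members)
  if (!is.null(up) && !is.null(down) && up == 0 && down == 0) {
    .warnf("pathway '%s': zero deviation in both member lists; score 0", p$name)
    return(0)
  }
  num <- up %||% eps
  den <- down %||% eps
  if (num == 0) {
    .warnf("pathway '%s': zero up-member deviation; score guarded at -%g",
           p$name, .SCORE_SENTINEL)
    return(-.SCORE_SENTINEL)
  }
  if (den == 0) {
    .warnf("pathway '%s': zero down-member deviation; score guarded at %g",
           p$name, .SCORE_SENTINEL)
    return(.SCORE_SENTINEL)
  }
  log(num / den)
}

#' Pathway score matrix over all samples
#'
#' Control means are taken from the control samples of `es` (or supplied
#' for scoring an external cohort against a reference).
#'
#' @param pathways An `xt_pathways` list.
#' @param es An `xt_expr` object.
#' @param eps Passed to [pathway_score()].
#' @param control_means Optional reference means; defaults to the row
#'   means over the control samples of `es`.
#' @return List of class `xt_psm`: `scores` (pathways x samples matrix)
#'   and `pattern` (`"active"` where score > 0, `"inactive"` where < 0,
#'   `"neutral"` at 0).
#' @export
score_matrix <- function(pathways, es, eps = 1.0, control_means = NULL) {
  if (length(pathways) == 0L) .stopf("no pathways to score")
  if (is.null(control_means)) {
    ctl <- samples_of(es, "control")
    if (length(ctl) == 0L) .stopf("no control samples to define reference means")
    control_means <- rowMeans(es$values[, ctl, drop = FALSE])
  }
  scores <- matrix(NA_real_, nrow = length(pathways), ncol = ncol(es$values),
                   dimnames = list(names(pathways), colnames(es$values)))
  for (s in colnames(es$values)) {
    col <- es$values[, s]
    for (pw in names(pathways))
      scores[pw, s] <- pathway_score(pathways[[pw]], col, control_means, eps)
  }
  pattern <- ifelse(scores > 0, "active", ifelse(scores < 0, "inactive", "neutral"))
  structure(list(scores = scores, pattern = pattern), class = "xt_psm")
}

#' Cluster samples on their pathway scores
#'
#' Agglomerative clustering (Euclidean distance) of the sample columns,
#' cut into two groups; when true labels are given the agreement of the
#' cut with them is reported as the adjusted Rand index. By default each
#' pathway row is standardized first (as expression heatmap clustering
#' conventionally does), so that pathways with large score variance do
#' not dominate the distance, and Ward's minimum-variance linkage is
#' used: its two-group cut targets compact balanced groups, whereas the
#' complete-linkage cut (also available) tends to split off one or two
#' outlying samples.
#'
#' @param psm An `xt_psm` from [score_matrix()].
#' @param true_labels Optional named vector of sample labels.
#' @param scale_rows Standardize each pathway row to mean 0, sd 1 before
#'   computing distances (default `TRUE`; constant rows are left as 0).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return List: `hclust`, `clusters` (named 1/2), `agreement` (adjusted
#'   Rand index, or `NA` when the columns are indistinguishable or labels
#'   are absent).
#' @export
cluster_samples <- function(psm, true_labels = NULL, scale_rows = TRUE,
                            method = "ward.D2") {
  if (ncol(psm$scores) < 2L) .stopf("need >= 2 samples to cluster")
  x <- psm$scores
  if (scale_rows) {
    sds <- apply(x, 1, stats::sd)
    x <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  }
  d <- stats::dist(t(x), method = "euclidean")
  if (all(d == 0)) {
    .warnf("all sample columns indistinguishable; clustering degenerate")
    cl <- stats::setNames(rep(1L, ncol(psm$scores)), colnames(psm$scores))
    return(list(hclust = NULL, clusters = cl, agreement = NA_real_))
  }
  hc <- stats::hclust(d, method = method)
  cl <- stats::cutree(hc, k = 2)
  agreement <- NA_real_
  if (!is.null(true_labels)) {
    lab <- true_labels[names(cl)]
    agreement <- mclust::adjustedRandIndex(cl, lab)
  }
  list(hclust = hc, clusters = cl, agreement = agreement)
}
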