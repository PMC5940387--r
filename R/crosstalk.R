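# Cross-talk genes and signature selection. A cross-talk gene belongs to
# the directional member lists of at least two enriched pathways. The
# signature is chosen from the cross-talk candidates by correlation-based
# feature subset selection (CFS): greedy forward search on the merit
# k * mean|r_cf| / sqrt(k + k(k-1) * mean|r_ff|), which rewards genes
# correlated with the tumor/control label and penalizes redundancy.

#' Find genes shared by enriched pathways
#'
#' Counts each gene's memberships over the union of up and down member
#' lists per pathway and keeps genes in at least `min_membership`
#' pathways.
#'
#' @param pathways An `xt_pathways` list ([annotate_directions()]).
#' @param min_membership Minimum number of pathways (default 2).
#' @return Data frame `gene`, `n_pathways`, `pathways` (semicolon-joined),
#'   sorted by count descending then symbol.
#' @export
find_crosstalk <- function(pathways, min_membership = 2) {
  if (length(pathways) < 2L) .stopf("need >= 2 pathways to find shared genes")
  min_membership <- .check_count(min_membership, "min_membership", 1L)
  memb <- lapply(pathways, function(p) unique(c(p$up_members, p$down_members)))
  long <- data.frame(
    gene = unlist(memb, use.names = FALSE),
    pathway = rep(names(pathways), lengths(memb)),
    stringsAsFactors = FALSE)
  if (nrow(long) == 0L)
    return(data.frame(gene = character(0), n_pathways = integer(0),
                      pathways = character(0), stringsAsFactors = FALSE))
  cnt <- table(long$gene)
  keep <- names(cnt)[cnt >= min_membership]
  out <- data.frame(
    gene = keep,
    n_pathways = as.integer(cnt[keep]),
    pathways = vapply(keep, function(g)
      paste(sort(long$pathway[long$gene == g]), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_pathways, out$gene), ]
  rownames(out) <- NULL
  out
}

#' CFS merit from summary correlations
#'
#' `merit = k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)` for a subset of
#' `k` features with mean absolute feature-class correlation `rcf_bar`
#' and mean absolute feature-feature correlation `rff_bar`.
#'
#' @param k Subset size.
#' @param rcf_bar Mean absolute feature-class correlation.
#' @param rff_bar Mean absolute pairwise feature correlation (ignored for
#'   `k = 1`).
#' @return The merit (larger is better).
#' @export
cfs_merit_formula <- function(k, rcf_bar, rff_bar = 0) {
  k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
}

# correlation pieces used by cfs_merit/select_signature; class correlation
# is point-biserial (Pearson against the 0/1 tumor indicator).
.cfs_correlations <- function(genes, es) {
  y <- as.numeric(es$labels == "tumor")
  x <- t(es$values[genes, , drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    .warnf("zero-variance gene(s) in CFS: %s (correlations set to 0)",
           paste(genes[sds == 0][1:3], collapse = ", "))
  safe_cor <- function(m, v) {
    r <- suppressWarnings(stats::cor(m, v))
    r[is.na(r)] <- 0
    r
  }
  r_cf <- abs(as.numeric(safe_cor(x, y)))
  r_ff <- abs(suppressWarnings(stats::cor(x)))
  r_ff[is.na(r_ff)] <- 0
  diag(r_ff) <- 1
  list(r_cf = stats::setNames(r_cf, genes), r_ff = r_ff)
}

#' CFS merit of a gene subset
#'
#' @param subset Gene symbols (non-empty, present in `es`).
#' @param es An `xt_expr` object.
#' @return The merit; for a singleton it equals the absolute point-biserial
#'   correlation of that gene with the class.
#' @export
cfs_merit <- function(subset, es) {
  subset <- toupper(subset)
  if (length(subset) == 0L) .stopf("empty subset")
  if (!all(subset %in% rownames(es$values)))
    .stopf("subset genes missing from the matrix")
  co <- .cfs_correlations(subset, es)
  k <- length(subset)
  rcf_bar <- mean(co$r_cf)
  rff_bar <- if (k > 1L) mean(co$r_ff[upper.tri(co$r_ff)]) else 0
  cfs_merit_formula(k, rcf_bar, rff_bar)
}

#' Select a compact signature by greedy forward CFS
#'
#' Starting from the empty set, repeatedly adds the candidate that
#' maximizes the CFS merit. As in the canonical best-first CFS search,
#' the walk tolerates up to `patience` consecutive non-improving
#' additions before stopping (so it can cross shallow dips of the noisy
#' merit surface), and the returned signature is the prefix of the walk
#' with the highest merit, capped at `max_size` genes. Ties break on the
#' gene symbol, so the procedure is deterministic.
#'
#' @param candidates A cross-talk table from [find_crosstalk()] or a
#'   character vector of candidate genes.
#' @param es An `xt_expr` object.
#' @param max_size Signature size cap (default 45).
#' @param patience Consecutive non-improving additions tolerated before
#'   the search stops (default 5, the conventional search termination;
#'   0 gives a strictly improving greedy search).
#' @return List of class `xt_signature`: `genes` (in selection order),
#'   `merit` (of the returned subset), `trace` (data frame `gene`,
#'   `merit` for every step of the walk, including explored steps beyond
#'   the returned prefix).
#' @export
select_signature <- function(candidates, es, max_size = 45, patience = 5) {
  genes <- if (is.data.frame(candidates)) candidates$gene else candidates
  genes <- sort(unique(toupper(genes)))
  genes <- intersect(genes, rownames(es$values))
  if (length(genes) == 0L) .stopf("no candidate gene present in the matrix")
  max_size <- .check_count(max_size, "max_size", 1L)
  patience <- .check_count(patience, "patience")
  co <- .cfs_correlations(genes, es)
  path <- character(0)
  path_merit <- numeric(0)
  sum_rcf <- 0; sum_rff <- 0
  best_merit <- -Inf; best_len <- 0L; fails <- 0L
  remaining <- genes
  while (length(path) < max_size && length(remaining) > 0L) {
    k <- length(path) + 1L
    cand_rcf <- unname(sum_rcf + co$r_cf[remaining])
    cand_rff_sum <- if (k == 1L) rep(0, length(remaining)) else
      unname(sum_rff + colSums(co$r_ff[path, remaining, drop = FALSE]))
    n_pairs <- k * (k - 1) / 2
    rff_bar <- if (n_pairs > 0) cand_rff_sum / n_pairs else rep(0, length(remaining))
    merits <- cfs_merit_formula(k, cand_rcf / k, rff_bar)
    best <- which(merits == max(merits))[1]  # remaining is sorted: ties -> symbol order
    g <- remaining[best]
    sum_rcf <- cand_rcf[best]
    sum_rff <- cand_rff_sum[best]
    path <- c(path, g)
    path_merit <- c(path_merit, merits[best])
    remaining <- setdiff(remaining, g)
    if (merits[best] > best_merit) {
      best_merit <- merits[best]; best_len <- k; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > patience) break
    }
  }
  structure(list(genes = path[seq_len(best_len)], merit = unname(best_merit),
                 trace = data.frame(gene = path, merit = path_merit,
                                    stringsAsFactors = FALSE)),
            class = "xt_signature")
}

#' @export
print.xt_signature <- function(x, ...) {
  cat(sprintf("xt_signature: %d genes, merit %.4f\n", length(x$genes), x$merit))
  invisible(x)
}
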