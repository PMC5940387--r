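# The state score: W = E * D, where E measures how far a gene's tumor
# expression falls outside the control interval [mean - sd, mean + sd]
# and D is the gene's degree in the disease-specific subnetwork. Genes
# with positive W are called up-regulated, negative W down-regulated;
# genes with W = 0 carry no direction and are not "important".

#' Control interval of one gene
#'
#' @param es An `xt_expr` object with >= 2 control samples.
#' @param gene Gene symbol.
#' @return List of class `xt_interval`: `gene`, `mean_ctrl`, `sd_ctrl`,
#'   `M` (mean + sd), `N` (mean - sd), `I` (M - N). The sd uses the n-1
#'   denominator.
#' @export
control_interval <- function(es, gene) {
  gene <- toupper(gene)
  if (!gene %in% rownames(es$values)) .stopf("gene '%s' not in the matrix", gene)
  ctl <- samples_of(es, "control")
  if (length(ctl) < 2L) .stopf("need >= 2 control samples")
  x <- es$values[gene, ctl]
  m <- mean(x); s <- stats::sd(x)
  structure(list(gene = gene, mean_ctrl = m, sd_ctrl = s,
                 M = m + s, N = m - s, I = 2 * s),
            class = "xt_interval")
}

# Vectorized intervals for all genes: one row per gene.
.control_intervals <- function(es) {
  ctl <- samples_of(es, "control")
  if (length(ctl) < 2L) .stopf("need >= 2 control samples")
  x <- es$values[, ctl, drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (length(ctl) - 1))
  data.frame(gene = rownames(es$values), mean_ctrl = m, sd_ctrl = s,
             M = m + s, N = m - s, I = 2 * s,
             row.names = rownames(es$values), stringsAsFactors = FALSE)
}

#' Deviation of an expression value from a control interval
#'
#' Zero while the value stays inside `[N, M]`; `exp - M` (positive) above
#' the interval; `exp - N` (negative) below it. Continuous in `exp`, with
#' both boundaries mapping to 0.
#'
#' @param exp Numeric expression value(s).
#' @param iv An `xt_interval` from [control_interval()], or any list with
#'   `M` and `N`.
#' @return Numeric deviation(s), same length as `exp`.
#' @export
sample_deviation <- function(exp, iv) {
  ifelse(exp > iv$M, exp - iv$M, ifelse(exp < iv$N, exp - iv$N, 0))
}

#' State scores W = E * D over a subnetwork
#'
#' E is the per-gene aggregate (mean by default) of [sample_deviation()]
#' over tumor samples; D is the gene's degree in `net`. Genes in the
#' network but absent from the matrix are dropped with a message.
#'
#' @param es An `xt_expr` object.
#' @param net An `xt_network` (the disease-specific subnetwork; D is the
#'   degree within it).
#' @param aggregate `"mean"` (default) or `"median"` over tumor samples.
#' @return Data frame (class `xt_state`) with columns `gene`, `E`, `D`,
#'   `W`, `direction` (`up` if W > 0, `down` if W < 0, else `none`),
#'   ordered by decreasing `|W|`. The rows with `W != 0` form the
#'   important-gene set.
#' @export
state_scores <- function(es, net, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  tum <- samples_of(es, "tumor")
  if (length(tum) == 0L) .stopf("no tumor samples")
  genes <- intersect(net$nodes, rownames(es$values))
  dropped <- setdiff(net$nodes, genes)
  if (length(dropped) > 0L)
    message(sprintf("%d network nodes absent from the expression matrix were dropped",
                    length(dropped)))
  if (length(genes) == 0L) .stopf("no network node is present in the matrix")
  iv <- .control_intervals(es)[genes, ]
  x <- es$values[genes, tum, drop = FALSE]
  dev <- sample_deviation(x, list(M = iv$M, N = iv$N))
  dim(dev) <- dim(x)
  E <- if (aggregate == "mean") rowMeans(dev) else apply(dev, 1, stats::median)
  D <- degrees(net)[genes]
  W <- E * D
  out <- data.frame(gene = genes, E = unname(E), D = unname(D), W = unname(W),
                    direction = ifelse(W > 0, "up", ifelse(W < 0, "down", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$W), out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("xt_state", "data.frame")
  out
}

#' Important genes of a state-score table
#' @param st An `xt_state` table.
#' @param direction `"both"`, `"up"` (W > 0) or `"down"` (W < 0).
#' @return Character vector of gene symbols.
#' @export
important_genes <- function(st, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") st$W != 0 else st$direction == direction
  st$gene[keep]
}
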