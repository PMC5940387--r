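# Interaction-network assembly and disease-specific subnetwork extraction.
# Networks are simple undirected graphs stored as a canonical edge table
# (from < to lexicographically) plus a node vector and, for subnetworks, a
# node provenance (de_up / de_down / introduced).

.canonical_edges <- function(from, to) {
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- a != b
  df <- unique(data.frame(from = a[keep], to = b[keep],
                          stringsAsFactors = FALSE))
  df[order(df$from, df$to), , drop = FALSE]
}

#' Construct a gene network from an edge table
#' @param edges Data frame with columns `from`, `to`.
#' @param provenance Optional named character vector over the nodes.
#' @param nodes Optional node set (defaults to the edge endpoints); lets a
#'   network carry isolated nodes.
#' @return An object of class `xt_network` with `nodes`, `edges`,
#'   `provenance`.
#' @export
gene_network <- function(edges, provenance = NULL, nodes = NULL) {
  edges <- .canonical_edges(toupper(edges$from), toupper(edges$to))
  rownames(edges) <- NULL
  nodes <- sort(unique(c(toupper(nodes %||% character(0)),
                         edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "xt_network")
}

#' @export
print.xt_network <- function(x, ...) {
  cat(sprintf("xt_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (!is.null(x$provenance))
    print(table(x$provenance))
  invisible(x)
}

#' Assemble a background network from edge-list files
#'
#' Takes the union over all files, upper-cases symbols, drops self-loops
#' and deduplicates undirected pairs (`a-b` equals `b-a`).
#'
#' @param edge_files Character vector of two-column TSV paths.
#' @return An `xt_network`.
#' @export
build_background <- function(edge_files) {
  if (length(edge_files) == 0L) .stopf("no edge files given")
  all_edges <- do.call(rbind, lapply(edge_files, read_edge_file))
  net <- gene_network(all_edges)
  if (nrow(net$edges) == 0L)
    .stopf("the union of the edge files contains no valid edges")
  net
}

#' Extract the disease-specific subnetwork around DE genes
#'
#' The node set is the flagged DE genes present in the background plus
#' every other gene with at least `min_links` direct background neighbors
#' among the DE genes; the edge set is the full induced subgraph
#' (introduced-introduced edges are retained). Node provenance records
#' `de_up` / `de_down` / `introduced`.
#'
#' @param bg Background `xt_network`.
#' @param de An `xt_de` table ([moderated_de_test()]) or a list with
#'   elements `up` and `down` of gene symbols.
#' @param min_links Minimum direct DE interactions for a non-DE gene to be
#'   introduced (default 5).
#' @return An `xt_network` with provenance.
#' @export
extract_specific_network <- function(bg, de, min_links = 5) {
  min_links <- .check_count(min_links, "min_links", 1L)
  if (inherits(de, "xt_de") || is.data.frame(de)) {
    up <- toupper(de$gene[de$direction == "up"])
    down <- toupper(de$gene[de$direction == "down"])
  } else {
    up <- toupper(de$up); down <- toupper(de$down)
  }
  de_all <- c(up, down)
  de_in_bg <- intersect(de_all, bg$nodes)
  if (length(de_in_bg) == 0L)
    .stopf("no DE gene is present in the background network")
  missing <- setdiff(de_all, bg$nodes)
  if (length(missing) > 0L)
    message(sprintf("%d DE genes absent from the background network", length(missing)))
  # count DE neighbors per node over the background edges
  is_de_from <- bg$edges$from %in% de_in_bg
  is_de_to <- bg$edges$to %in% de_in_bg
  cnt <- table(c(bg$edges$from[is_de_to], bg$edges$to[is_de_from]))
  introduced <- setdiff(names(cnt)[cnt >= min_links], de_all)
  nodes <- c(de_in_bg, introduced)
  keep <- bg$edges$from %in% nodes & bg$edges$to %in% nodes
  prov <- stats::setNames(
    ifelse(nodes %in% up, "de_up",
           ifelse(nodes %in% down, "de_down", "introduced")),
    nodes)
  gene_network(bg$edges[keep, , drop = FALSE], provenance = prov,
               nodes = nodes)
}

#' Node degrees of a network
#' @param net An `xt_network`.
#' @return Named integer vector over all nodes (isolated nodes get 0);
#'   sums to twice the edge count.
#' @export
degrees <- function(net) {
  d <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  stats::setNames(as.integer(d), net$nodes)
}

#' Write a subnetwork as an edge list plus node attributes
#' @param net An `xt_network`.
#' @param edges_path,nodes_path Output TSV paths.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  write_edge_file(net$edges, edges_path)
  deg <- degrees(net)
  prov <- net$provenance %||% stats::setNames(rep(NA_character_, length(net$nodes)), net$nodes)
  .write_tsv(data.frame(node = net$nodes,
                        provenance = unname(prov[net$nodes]),
                        degree = unname(deg[net$nodes]),
                        stringsAsFactors = FALSE), nodes_path)
  invisible(c(edges_path, nodes_path))
}
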