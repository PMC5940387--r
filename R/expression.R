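#' Construct an expression set
#'
#' The central data container: a genes x samples matrix of log-scale
#' expression values together with a tumor/control label for every sample.
#' Gene symbols are upper-cased and must be unique; both classes must be
#' non-empty for any two-group operation downstream.
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required). Values are on the log2 scale
#'   (log intensities or log-CPM).
#' @param labels Named character vector mapping each sample to `"tumor"`
#'   or `"control"`; names must cover `colnames(values)`.
#' @return An object of class `xt_expr` with elements `values` and `labels`.
#' @export
expr_set <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("'values' needs gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate gene symbols after upper-casing: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))])[1:3], collapse = ", "))
  if (any(is.na(rownames(values))) || any(rownames(values) == ""))
    .stopf("missing gene symbols are not allowed")
  labels <- labels[colnames(values)]
  if (any(is.na(labels)))
    .stopf("every sample needs a label; missing for: %s",
           paste(colnames(values)[is.na(labels)][1:3], collapse = ", "))
  if (!all(labels %in% c("tumor", "control")))
    .stopf("labels must be 'tumor' or 'control'")
  structure(list(values = values, labels = labels), class = "xt_expr")
}

#' @export
print.xt_expr <- function(x, ...) {
  cat(sprintf("xt_expr: %d genes x %d samples (%d tumor, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "control")))
  invisible(x)
}

#' Sample names of one class
#' @param es An `xt_expr` object.
#' @param class `"tumor"` or `"control"`.
#' @return Character vector of sample names.
#' @export
samples_of <- function(es, class) {
  names(es$labels)[es$labels == class]
}

#' Subset an expression set to a gene list
#' @param es An `xt_expr` object.
#' @param genes Gene symbols to keep (upper-cased before matching).
#' @return An `xt_expr` restricted to the genes found.
#' @export
subset_genes <- function(es, genes) {
  genes <- toupper(genes)
  keep <- intersect(genes, rownames(es$values))
  if (length(keep) == 0L) .stopf("none of the requested genes are present")
  expr_set(es$values[keep, , drop = FALSE], es$labels)
}
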