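# Plain-text interchange: expression/label TSV, two-column edge lists,
# GMT gene sets, clinical tables. All writers are deterministic (fixed
# column order, no quoting, "." decimal) so identical inputs give
# byte-identical files.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an expression set to TSV
#'
#' Two files: the matrix (first column `gene`, then one column per sample)
#' and a two-column label table (`sample`, `group`).
#'
#' @param es An `xt_expr` object.
#' @param values_path,labels_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(es, values_path, labels_path) {
  df <- data.frame(gene = rownames(es$values), es$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, values_path)
  .write_tsv(data.frame(sample = names(es$labels), group = unname(es$labels),
                        stringsAsFactors = FALSE), labels_path)
  invisible(c(values_path, labels_path))
}

#' Read an expression set from TSV
#' @param values_path,labels_path Paths written by [write_expression()].
#' @return An `xt_expr` object.
#' @export
read_expression <- function(values_path, labels_path) {
  df <- utils::read.table(values_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expr_set(m, stats::setNames(lab$group, lab$sample))
}

#' Read a two-column interaction edge list
#'
#' Lines must contain exactly two tab-separated gene symbols; a header line
#' is optional and detected by the names `from`/`to` (case-insensitive).
#'
#' @param path TSV path.
#' @return Data frame with columns `from`, `to` (upper-cased, unmodified
#'   otherwise — deduplication happens in [build_background()]).
#' @export
read_edge_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) .stopf("edge file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(parts[[1]]) == 2L &&
      all(tolower(trimws(parts[[1]])) %in% c("from", "to", "gene1", "gene2")))
    start <- 2L
  out <- vector("list", length(lines))
  for (i in seq(start, length(lines))) {
    p <- trimws(parts[[i]])
    if (length(p) != 2L || any(p == ""))
      .stopf("malformed edge line %d in '%s': expected two tab-separated symbols", i, path)
    out[[i]] <- p
  }
  m <- do.call(rbind, out[start:length(lines)])
  data.frame(from = toupper(m[, 1]), to = toupper(m[, 2]),
             stringsAsFactors = FALSE)
}

#' Write an edge list to TSV
#' @param edges Data frame with columns `from`, `to`.
#' @param path Output path.
#' @export
write_edge_file <- function(edges, path) {
  .write_tsv(edges[, c("from", "to")], path)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    .stopf("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT format
#' @param path GMT path.
#' @return Named list of character vectors (members upper-cased).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    .stopf("malformed GMT line %d in '%s': need name, description, >=1 member", bad[1], path)
  sets <- lapply(parts, function(p) toupper(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write a clinical table to TSV
#' @param clinical Data frame with columns `sample`, `time_days`, `event`
#'   (and optionally `group`).
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  cols <- intersect(c("sample", "time_days", "event", "group"), names(clinical))
  .write_tsv(clinical[, cols], path)
}

#' Read a clinical table from TSV
#' @param path Path written by [write_clinical()].
#' @return Data frame with columns `sample`, `time_days`, `event`.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "time_days", "event") %in% names(cl)))
    .stopf("clinical table needs columns sample, time_days, event")
  if (any(cl$time_days < 0)) .stopf("negative survival times in '%s'", path)
  if (!all(cl$event %in% c(0L, 1L))) .stopf("event must be 0/1 in '%s'", path)
  cl
}
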