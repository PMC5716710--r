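# Tab-delimited interchange formats.
#
# Expression TSV:  feature_id  class  [length]  <sample...>
# Group map TSV:   sample_id  group
# Target-pair TSV: mirna_id  target_id  target_class  n_sites  score
# Differential TSV mirrors the published table layout:
#   feature_id  foldChange  log2FoldChange  pval  padj  up_down
# Edge TSV:        source_id  target_id  source_class  target_class  r  pval  n
# Network export:  nodes (id  class  direction) + edges
#   (source  target  edge_type  weight)

#' Read an expression matrix and its sample-group map
#'
#' @param path expression TSV: header row of `feature_id`, `class`,
#'   optionally `length`, then one column per sample.
#' @param groups_path group-map TSV with columns `sample_id`, `group`
#'   (`control`/`treatment`).
#' @return An [expression_matrix()]; row order of the file is preserved.
#' @export
read_expression <- function(path, groups_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("feature_id", "class") %in% names(df)))
    stop("expression file must start with feature_id and class columns: ",
         path, call. = FALSE)
  has_len <- "length" %in% names(df)
  meta_cols <- c("feature_id", "class", if (has_len) "length")
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols))
    stop("no sample columns found in ", path, call. = FALSE)

  dup <- duplicated(df$feature_id)
  if (any(dup))
    stop("duplicate feature_id at line ",
         paste(which(dup) + 1L, collapse = ", "), " of ", path,
         call. = FALSE)
  v <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(v))
    stop("non-numeric expression values in ", path, call. = FALSE)
  neg <- which(apply(v < 0, 1, any))
  if (length(neg))
    stop("negative expression value at line ",
         paste(neg + 1L, collapse = ", "), " of ", path, call. = FALSE)
  rownames(v) <- df$feature_id

  gm <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gm)))
    stop("group map must have sample_id and group columns: ", groups_path,
         call. = FALSE)
  missing <- setdiff(sample_cols, gm$sample_id)
  if (length(missing))
    stop("no group mapping for sample(s): ",
         paste(missing, collapse = ", "), " (", groups_path, ")",
         call. = FALSE)
  grp <- gm$group[match(sample_cols, gm$sample_id)]
  expression_matrix(v, df$class, grp,
                    feature_length = if (has_len) df$length else NULL)
}

#' Write an expression matrix and its sample-group map
#'
#' @param m an [expression_matrix()].
#' @param path output expression TSV.
#' @param groups_path output group-map TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, groups_path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(feature_id = m$features$feature_id,
                   class = m$features$class,
                   stringsAsFactors = FALSE)
  if (!all(is.na(m$features$length))) df$length <- m$features$length
  df <- cbind(df, as.data.frame(m$values))
  write_tsv(df, path)
  write_tsv(m$samples, groups_path)
  invisible(path)
}

#' Read a sequence-predicted miRNA-target pair list
#'
#' Consumes the tab-delimited summary of a target-prediction run (one row
#' per predicted miRNA recognition element pair). Multiple rows for one
#' (miRNA, target) are collapsed to a single pair with summed `n_sites`
#' (and the best `score`, if present).
#'
#' @param path TSV with columns `mirna_id`, `target_id`, `target_class`,
#'   `n_sites` and optionally `score`.
#' @return data.frame of de-duplicated target pairs.
#' @export
read_target_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_class", "n_sites")
  if (!all(need %in% names(df)))
    stop("target-pair file must have columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  validate_target_pairs(df)
}

#' Validate and de-duplicate a target-pair data.frame
#'
#' @param df data.frame with `mirna_id`, `target_id`, `target_class`,
#'   `n_sites`, optional `score`.
#' @return The validated data.frame, one row per (miRNA, target).
#' @export
validate_target_pairs <- function(df) {
  bad <- setdiff(unique(df$target_class), c("mRNA", "lncRNA"))
  if (length(bad))
    stop("target_class must be mRNA or lncRNA, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$n_sites < 1))
    stop("n_sites must be >= 1", call. = FALSE)
  key <- paste(df$mirna_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    ns <- tapply(df$n_sites, key, sum)
    sc <- if ("score" %in% names(df)) tapply(df$score, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    k <- paste(df$mirna_id, df$target_id, sep = "\r")
    df$n_sites <- as.numeric(ns[k])
    if (!is.null(sc)) df$score <- as.numeric(sc[k])
  }
  rownames(df) <- NULL
  df
}

#' Write a target-pair list
#' @param pairs data.frame as returned by [read_target_pairs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_target_pairs <- function(pairs, path) {
  write_tsv(pairs, path)
  invisible(path)
}

#' Read / write a differential table
#'
#' The differential TSV mirrors the published table layout
#' (`feature_id  foldChange  log2FoldChange  pval  padj  up_down`), with
#' `Inf`/`-Inf` literals for zero-baseline features.
#'
#' @param path TSV path.
#' @return data.frame of differential records.
#' @export
read_differential <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "foldChange", "log2FoldChange", "pval", "up_down")
  if (!all(need %in% names(df)))
    stop("differential file must have columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  df
}

#' @rdname read_differential
#' @param de differential data.frame.
#' @export
write_differential <- function(de, path) {
  write_tsv(de, path)
  invisible(path)
}

#' Read / write correlation edge tables
#' @param path TSV path.
#' @return data.frame of correlation edges.
#' @export
read_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_edges
#' @param edges edge data.frame from [correlate_classes()].
#' @export
write_edges <- function(edges, path) {
  write_tsv(edges, path)
  invisible(path)
}

#' Write / read a ceRNA network as node + edge tables
#'
#' Two-file convention importable by common network viewers: a node table
#' (`id  class  direction`) and an edge table
#' (`source  target  edge_type  weight`, weights to 6 dp).
#'
#' @param net a `cerna_network` from [build_cerna_network()].
#' @param nodes_path,edges_path output TSV paths.
#' @return `nodes_path`, invisibly.
#' @export
write_network <- function(net, nodes_path, edges_path) {
  stopifnot(inherits(net, "cerna_network"))
  e <- net$edges
  e$weight <- round(e$weight, 6)
  write_tsv(net$nodes, nodes_path)
  write_tsv(e, edges_path)
  invisible(nodes_path)
}

#' @rdname write_network
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  new_cerna_network(nodes, edges)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
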