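new_cerna_network <- function(nodes, edges) {
  stopifnot(all(c("id", "class", "direction") %in% names(nodes)),
            all(c("source", "target", "edge_type", "weight") %in%
                  names(edges)))
  if (nrow(edges)) {
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing))
      stop("edge endpoint(s) missing from node table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(edges$source == edges$target))
      stop("self-loops are not allowed", call. = FALSE)
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  if (nrow(x$edges))
    cat("  edge types:",
        paste(sprintf("%s=%d", names(table(x$edges$edge_type)),
                      table(x$edges$edge_type)), collapse = ", "), "\n")
  invisible(x)
}

direction_of <- function(ids, annotations) {
  if (is.null(annotations)) return(rep("Unknown", length(ids)))
  d <- annotations$up_down[match(ids, annotations$feature_id)]
  if (anyNA(d))
    warning("no differential annotation for: ",
            paste(ids[is.na(d)], collapse = ", "),
            "; direction set to Unknown")
  d[is.na(d)] <- "Unknown"
  d
}

#' Build the ceRNA (lncRNA-mRNA) network
#'
#' One `competes` edge per called ceRNA candidate (duplicated pairs
#' collapse to one edge), weighted by the ceRNA score; nodes are the
#' union of endpoints, annotated with their differential direction.
#' Node and edge ordering is lexicographic, so output is deterministic.
#'
#' @param cernas candidate data.frame ([predict_cernas()] /
#'   [call_shared_cernas()] output).
#' @param annotations optional differential records (rbind of
#'   [differential_table()] outputs) supplying `feature_id` and
#'   `up_down`; candidates missing from it are annotated `Unknown` with
#'   a warning.
#' @return A `cerna_network`: list with `nodes` (`id`, `class`,
#'   `direction`) and `edges` (`source`, `target`, `edge_type`,
#'   `weight`).
#' @export
build_cerna_network <- function(cernas, annotations = NULL) {
  key <- paste(cernas$lncrna_id, cernas$mrna_id, sep = "\r")
  cernas <- cernas[!duplicated(key), , drop = FALSE]
  nodes <- data.frame(
    id = c(unique(cernas$lncrna_id), unique(cernas$mrna_id)),
    class = rep(c("lncRNA", "mRNA"),
                c(length(unique(cernas$lncrna_id)),
                  length(unique(cernas$mrna_id)))),
    stringsAsFactors = FALSE)
  nodes$direction <- direction_of(nodes$id, annotations)
  edges <- data.frame(source = cernas$lncrna_id,
                      target = cernas$mrna_id,
                      edge_type = rep("competes", nrow(cernas)),
                      weight = cernas$cerna_score,
                      stringsAsFactors = FALSE)
  new_cerna_network(nodes, edges)
}

#' Build the tripartite ceRNA-miRNA network
#'
#' The ceRNA network of [build_cerna_network()] plus `binds` edges for
#' every shared miRNA-target pair whose target participates in at least
#' one called ceRNA; miRNAs paired only with uncalled targets are
#' excluded. `binds` edges are weighted by the pair's expression
#' correlation `r` when the pair table carries one, `NA` otherwise.
#'
#' @inheritParams build_cerna_network
#' @param mrna_pairs,lncrna_pairs shared miRNA-mRNA / miRNA-lncRNA pair
#'   data.frames (`mirna_id`, `target_id`, optional `r`).
#' @return A `cerna_network` with `competes` and `binds` edges.
#' @export
build_tripartite_network <- function(cernas, mrna_pairs, lncrna_pairs,
                                     annotations = NULL) {
  base <- build_cerna_network(cernas, annotations)
  called <- base$nodes$id
  pairs <- rbind(
    normalize_pairs(mrna_pairs), normalize_pairs(lncrna_pairs))
  pairs <- pairs[pairs$target_id %in% called, , drop = FALSE]
  pairs <- pairs[!duplicated(paste(pairs$mirna_id, pairs$target_id,
                                   sep = "\r")), , drop = FALSE]
  mir_ids <- unique(pairs$mirna_id)
  mir_nodes <- data.frame(id = mir_ids,
                          class = rep("miRNA", length(mir_ids)),
                          stringsAsFactors = FALSE)
  mir_nodes$direction <- direction_of(mir_nodes$id, annotations)
  nodes <- rbind(base$nodes, mir_nodes)
  binds <- data.frame(source = pairs$mirna_id,
                      target = pairs$target_id,
                      edge_type = rep("binds", nrow(pairs)),
                      weight = pairs$r,
                      stringsAsFactors = FALSE)
  new_cerna_network(nodes, rbind(base$edges, binds))
}

normalize_pairs <- function(df) {
  data.frame(mirna_id = mirna_col(df),
             target_id = df$target_id,
             r = if ("r" %in% names(df)) df$r else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-node degree report
#'
#' Degree of every node split by edge type, sorted by descending
#' `competes` degree then id — the view that surfaces hub lncRNAs
#' competing for the most mRNA partners. The handshake identity holds
#' per type: each degree column sums to twice the matching edge count.
#'
#' @param net a `cerna_network`.
#' @return data.frame with columns `node`, `class`, `competes_degree`,
#'   `binds_degree`.
#' @export
degree_report <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  nodes <- net$nodes
  if (!nrow(nodes))
    return(data.frame(node = character(), class = character(),
                      competes_degree = integer(),
                      binds_degree = integer(),
                      stringsAsFactors = FALSE))
  deg <- function(type) {
    e <- net$edges[net$edges$edge_type == type, , drop = FALSE]
    ends <- c(e$source, e$target)
    as.integer(vapply(nodes$id, function(id) sum(ends == id),
                      integer(1)))
  }
  out <- data.frame(node = nodes$id, class = nodes$class,
                    competes_degree = deg("competes"),
                    binds_degree = deg("binds"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$competes_degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
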