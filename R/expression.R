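#' Three-class expression matrix
#'
#' Container for a feature-by-sample abundance matrix carrying, per feature,
#' an RNA class (`mRNA`, `miRNA` or `lncRNA`) and optionally a transcript
#' length, and, per sample, a two-level group label (`control` = baseline
#' phase, `treatment` = contrast phase).
#'
#' @param values nonnegative numeric matrix; rownames are feature ids,
#'   colnames are sample ids.
#' @param feature_class character vector, one of `"mRNA"`, `"miRNA"`,
#'   `"lncRNA"` per row of `values`.
#' @param group character vector, one of `"control"`, `"treatment"` per
#'   column of `values`.
#' @param feature_length optional positive integer vector of transcript
#'   lengths (nt) per feature; required only for [compute_rpkm()] and
#'   length-normalised [compute_tpm()].
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix), `features` (data.frame: `feature_id`, `class`, `length`)
#'   and `samples` (data.frame: `sample_id`, `group`).
#' @export
#' @examples
#' v <- matrix(1:12, nrow = 3,
#'             dimnames = list(c("g1", "g2", "l1"),
#'                             c("s1", "s2", "s3", "s4")))
#' m <- expression_matrix(v, c("mRNA", "mRNA", "lncRNA"),
#'                        c("control", "control", "treatment", "treatment"))
expression_matrix <- function(values, feature_class, group,
                              feature_length = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  # R stores zero-length dimnames as NULL, so only non-empty dimensions
  # can require names
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(values < 0))
    stop("`values` must be nonnegative", call. = FALSE)
  feature_class <- as.character(feature_class)
  if (length(feature_class) != nrow(values))
    stop("`feature_class` must have one entry per feature", call. = FALSE)
  bad <- setdiff(unique(feature_class), RNA_CLASSES)
  if (length(bad))
    stop("unknown RNA class: ", paste(bad, collapse = ", "),
         " (expected ", paste(RNA_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must have one entry per sample", call. = FALSE)
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  if (!is.null(feature_length)) {
    if (length(feature_length) != nrow(values))
      stop("`feature_length` must have one entry per feature", call. = FALSE)
    if (any(!is.finite(feature_length)) || any(feature_length <= 0))
      stop("`feature_length` must be positive and finite", call. = FALSE)
  }
  structure(list(
    values = values,
    features = data.frame(
      feature_id = rownames(values) %||% character(0),
      class = feature_class,
      length = if (is.null(feature_length)) NA_real_ else
        as.numeric(feature_length),
      stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = colnames(values),
      group = group,
      stringsAsFactors = FALSE)
  ), class = "expr_matrix")
}

RNA_CLASSES <- c("mRNA", "miRNA", "lncRNA")
GROUP_LEVELS <- c("control", "treatment")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(table(x$features$class)),
                    table(x$features$class)), collapse = ", "), "\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(table(x$samples$group)),
                    table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature id and/or sample id
#'
#' @param m an [expression_matrix()].
#' @param features optional character vector of feature ids to keep
#'   (order preserved as given).
#' @param samples optional character vector of sample ids to keep.
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(m, features = NULL, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  fi <- if (is.null(features)) m$features$feature_id else features
  si <- if (is.null(samples)) m$samples$sample_id else samples
  missing_f <- setdiff(fi, m$features$feature_id)
  if (length(missing_f))
    stop("unknown feature ids: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  missing_s <- setdiff(si, m$samples$sample_id)
  if (length(missing_s))
    stop("unknown sample ids: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  rows <- match(fi, m$features$feature_id)
  cols <- match(si, m$samples$sample_id)
  expression_matrix(m$values[rows, cols, drop = FALSE],
                    m$features$class[rows],
                    m$samples$group[cols],
                    feature_length = if (all(is.na(m$features$length))) NULL
                    else m$features$length[rows])
}

#' RPKM quantification
#'
#' Converts read counts to reads per kilobase of transcript model per
#' million mapped reads: `rpkm[i,j] = count[i,j] * 1e9 /
#' (length[i] * column_total[j])`. The standard abundance unit for genes
#' and lncRNAs from RNA-seq.
#'
#' @param m an [expression_matrix()] of raw counts with feature lengths.
#' @return An `expr_matrix` of RPKM values.
#' @export
compute_rpkm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  len <- m$features$length
  if (any(is.na(len)))
    stop("feature lengths are required for RPKM", call. = FALSE)
  totals <- colSums(m$values)
  if (any(totals == 0))
    stop("zero column total for sample(s): ",
         paste(m$samples$sample_id[totals == 0], collapse = ", "),
         call. = FALSE)
  v <- m$values * 1e9 / outer(len, totals)
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, m$features$class, m$samples$group,
                    feature_length = len)
}

#' TPM quantification
#'
#' Transcripts per million: per-feature rates scaled so every column sums
#' to 1e6. For miRNA profiling (the unit used for small-RNA libraries
#' here) length normalisation is skipped and the rate is the raw count;
#' set `normalize_length = TRUE` for conventional length-normalised TPM.
#'
#' @param m an [expression_matrix()] of raw counts.
#' @param normalize_length divide counts by feature length before scaling
#'   (default `FALSE`, the miRNA convention).
#' @return An `expr_matrix` of TPM values; columns sum to 1e6.
#' @export
compute_tpm <- function(m, normalize_length = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  rate <- m$values
  if (normalize_length) {
    len <- m$features$length
    if (any(is.na(len)))
      stop("feature lengths are required for length-normalised TPM",
           call. = FALSE)
    rate <- rate / len
  }
  totals <- colSums(rate)
  if (any(totals == 0))
    stop("zero column total for sample(s): ",
         paste(m$samples$sample_id[totals == 0], collapse = ", "),
         call. = FALSE)
  v <- sweep(rate, 2, totals, "/") * 1e6
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, m$features$class, m$samples$group,
                    feature_length = if (all(is.na(m$features$length))) NULL
                    else m$features$length)
}
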