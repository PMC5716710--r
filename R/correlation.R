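#' Pearson correlation with a t-based two-sided p-value
#'
#' Sample Pearson coefficient between two expression profiles and the
#' two-sided p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom
#' (as computed by [stats::cor.test()]); `r = +-1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, neither constant.
#' @return list with elements `r`, `pval`, `n`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 2, 4))  # r = 9/sqrt(84)
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3)
    stop("at least 3 paired samples are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, pval = if (abs(r) >= 1) 0 else unname(ct$p.value), n = n)
}

#' Correlate all pairs between two RNA classes
#'
#' Computes [pearson_cor()] for every (class_a feature, class_b feature)
#' pair — or only the pairs named in `restrict_to`, mirroring a
#' sequence-predicted pair universe — across all samples of both groups
#' pooled. Expression is log2-transformed (after adding `pseudocount`)
#' before correlating, the scale on which multiplicative regulation is
#' linear; set `log2_transform = FALSE` to correlate raw values. Features
#' with constant (zero-variance) profiles are dropped with a warning.
#'
#' @param m an [expression_matrix()].
#' @param class_a,class_b RNA classes for the source and target side.
#' @param restrict_to optional data.frame with columns `source_id`,
#'   `target_id` (or `mirna_id`, `target_id`): only these pairs are
#'   evaluated.
#' @param log2_transform correlate log2 abundances (default `TRUE`).
#' @param pseudocount added before the log2 transform (default 1e-2).
#' @return data.frame of correlation edges: `source_id`, `target_id`,
#'   `source_class`, `target_class`, `r`, `pval`, `n`.
#' @export
correlate_classes <- function(m, class_a, class_b, restrict_to = NULL,
                              log2_transform = TRUE, pseudocount = 1e-2) {
  stopifnot(inherits(m, "expr_matrix"))
  ids_a <- m$features$feature_id[m$features$class == class_a]
  ids_b <- m$features$feature_id[m$features$class == class_b]
  if (!length(ids_a)) stop("no features of class ", class_a, call. = FALSE)
  if (!length(ids_b)) stop("no features of class ", class_b, call. = FALSE)

  v <- m$values
  if (log2_transform) v <- log2(v + pseudocount)

  if (is.null(restrict_to)) {
    pairs <- expand.grid(source_id = ids_a, target_id = ids_b,
                         stringsAsFactors = FALSE)
  } else {
    src_col <- if ("source_id" %in% names(restrict_to)) "source_id"
      else "mirna_id"
    pairs <- data.frame(source_id = restrict_to[[src_col]],
                        target_id = restrict_to$target_id,
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source_id %in% ids_a &
                   pairs$target_id %in% ids_b, , drop = FALSE]
  }
  pairs <- pairs[pairs$source_id != pairs$target_id, , drop = FALSE]

  const <- rownames(v)[apply(v, 1, stats::sd) == 0]
  drop <- pairs$source_id %in% const | pairs$target_id %in% const
  if (any(drop)) {
    warning(sum(drop), " pair(s) dropped: constant expression profile(s) ",
            "give an undefined correlation")
    pairs <- pairs[!drop, , drop = FALSE]
  }
  n <- ncol(v)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pearson_cor(v[pairs$source_id[i], ], v[pairs$target_id[i], ])
  })
  data.frame(source_id = pairs$source_id,
             target_id = pairs$target_id,
             source_class = rep(class_a, nrow(pairs)),
             target_class = rep(class_b, nrow(pairs)),
             r = vapply(res, `[[`, numeric(1), "r"),
             pval = vapply(res, `[[`, numeric(1), "pval"),
             n = rep(n, nrow(pairs)),
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Keep strongly negatively correlated pairs
#'
#' The miRNA-target filter: an edge is kept iff `r < -r_threshold` AND
#' `pval < p_threshold` (strict inequalities). "Coefficient above the
#' threshold" is read on the magnitude, with the negative sign required —
#' the only reading consistent with selecting negatively correlated
#' repression pairs.
#'
#' @param edges edge data.frame from [correlate_classes()].
#' @param r_threshold magnitude cut in (0, 1), default 0.7.
#' @param p_threshold p-value cut in (0, 1), default 0.05.
#' @return Subset of `edges`.
#' @export
filter_negative <- function(edges, r_threshold = 0.7, p_threshold = 0.05) {
  check_threshold(r_threshold, "r_threshold")
  check_threshold(p_threshold, "p_threshold")
  edges[edges$r < -r_threshold & edges$pval < p_threshold, , drop = FALSE]
}

#' Keep strongly co-expressed pairs
#'
#' The lncRNA-mRNA co-expression filter. `mode = "absolute"` (default)
#' keeps `|r| > r_threshold`; `mode = "positive"` keeps only
#' `r > r_threshold`; both additionally require `pval < p_threshold`.
#' ceRNA partner pairs can be observed with either correlation sign
#' across a two-phase design, hence the absolute default.
#'
#' @inheritParams filter_negative
#' @param mode `"absolute"` or `"positive"`.
#' @return Subset of `edges`.
#' @export
filter_coexpressed <- function(edges, r_threshold = 0.7, p_threshold = 0.05,
                               mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  check_threshold(r_threshold, "r_threshold")
  check_threshold(p_threshold, "p_threshold")
  keep <- if (mode == "positive") edges$r > r_threshold
    else abs(edges$r) > r_threshold
  edges[keep & edges$pval < p_threshold, , drop = FALSE]
}

check_threshold <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1)
    stop(name, " must be a single value in (0, 1)", call. = FALSE)
}
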