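#' Intersect sequence-predicted and expression-derived pair sets
#'
#' Exact set intersection on (miRNA, target) keys, the Venn step that
#' keeps only miRNA-target relations supported both by predicted binding
#' sites and by expression correlation. Both inputs must refer to a
#' single common target class.
#'
#' @param predicted data.frame with columns `mirna_id`, `target_id`
#'   (optionally `target_class`); extra columns (e.g. `n_sites`) are
#'   carried through.
#' @param expression_derived data.frame with the same key columns, e.g.
#'   filtered output of [correlate_classes()] (whose `source_id` is taken
#'   as the miRNA); its `r` and `pval` columns, when present, are merged
#'   into the result.
#' @return data.frame of the intersecting pairs (subset of `predicted`
#'   rows, with correlation columns appended when available).
#' @export
intersect_pairs <- function(predicted, expression_derived) {
  pk <- pair_keys(predicted)
  ek <- pair_keys(expression_derived)
  cls_p <- pair_class(predicted)
  cls_e <- pair_class(expression_derived)
  cls <- unique(c(cls_p, cls_e))
  if (length(cls) > 1)
    stop("mixed target classes in one intersection: ",
         paste(cls, collapse = ", "), call. = FALSE)
  out <- predicted[pk %in% ek, , drop = FALSE]
  if (all(c("r", "pval") %in% names(expression_derived)) &&
      !"r" %in% names(out)) {
    i <- match(pair_keys(out), ek)
    out$r <- expression_derived$r[i]
    out$pval <- expression_derived$pval[i]
  }
  rownames(out) <- NULL
  out
}

pair_keys <- function(df) {
  mir <- if ("mirna_id" %in% names(df)) df$mirna_id else df$source_id
  paste(mir, df$target_id, sep = "\r")
}

pair_class <- function(df) {
  if ("target_class" %in% names(df)) unique(df$target_class)
  else character(0)
}

#' ceRNA score
#'
#' Fraction of the lncRNA's paired miRNAs that are shared with the
#' candidate mRNA partner: `m_c / m_n`. Vectorised.
#'
#' @param m_c number of shared miRNAs, `0 <= m_c <= m_n`.
#' @param m_n number of miRNAs paired with the lncRNA, `>= 1`.
#' @return Score(s) in `[0, 1]`.
#' @export
cerna_score <- function(m_c, m_n) {
  if (any(m_n < 1))
    stop("ceRNA score undefined: m_n must be >= 1", call. = FALSE)
  if (any(m_c < 0) || any(m_c > m_n))
    stop("m_c must lie in [0, m_n]", call. = FALSE)
  m_c / m_n
}

#' Hypergeometric shared-miRNA p-value
#'
#' Probability of observing at least `m_c` shared miRNAs between the
#' mRNA's miRNA set (size `m_p`) and the lncRNA's miRNA set (size `m_n`)
#' when both are drawn from a universe of `M_T` miRNAs:
#'
#' \deqn{p = \sum_{i = m_c}^{\min(m_p, m_n)}
#'   \frac{\binom{m_n}{i} \binom{M_T - m_n}{m_p - i}}{\binom{M_T}{m_p}}}
#'
#' Evaluated in log space (log binomial coefficients + log-sum-exp) so
#' large universes do not overflow. `m_c = 0` gives 1 by construction.
#'
#' @param M_T universe size (total miRNAs considered).
#' @param m_p miRNAs paired with the mRNA (`<= M_T`).
#' @param m_n miRNAs paired with the lncRNA (`<= M_T`).
#' @param m_c shared miRNAs (`0 <= m_c <= min(m_p, m_n)`).
#' @return The upper-tail probability, in (0, 1].
#' @export
#' @examples
#' hypergeom_pvalue(3, 1, 1, 1)    # 1/3
#' hypergeom_pvalue(10, 4, 5, 3)   # 55/210
hypergeom_pvalue <- function(M_T, m_p, m_n, m_c) {
  for (v in list(M_T, m_p, m_n, m_c))
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v))
      stop("arguments must be single nonnegative integers", call. = FALSE)
  if (m_p > M_T || m_n > M_T)
    stop("m_p and m_n cannot exceed M_T", call. = FALSE)
  if (m_c > min(m_p, m_n))
    stop("m_c cannot exceed min(m_p, m_n)", call. = FALSE)
  i <- seq.int(m_c, min(m_p, m_n))
  log_terms <- lchoose(m_n, i) + lchoose(M_T - m_n, m_p - i) -
    lchoose(M_T, m_p)
  log_terms <- log_terms[is.finite(log_terms)]
  if (!length(log_terms)) return(0)
  mx <- max(log_terms)
  min(1, exp(mx + log(sum(exp(log_terms - mx)))))
}

#' Predict ceRNA candidates from shared pair sets
#'
#' For every (lncRNA, mRNA) combination sharing at least `min_shared`
#' miRNAs across the two shared pair sets, computes the per-candidate
#' counts (`m_p`, `m_n`, `m_c`), the ceRNA score ([cerna_score()]) and
#' the overlap p-value ([hypergeom_pvalue()]), and keeps candidates with
#' `pval < p_threshold`. Setting `p_threshold = 1` disables the p filter
#' (useful when the miRNA universe is too small for the overlap test to
#' have power; see the methods vignette).
#'
#' @param mrna_pairs shared miRNA-mRNA pair data.frame (`mirna_id`,
#'   `target_id`).
#' @param lncrna_pairs shared miRNA-lncRNA pair data.frame.
#' @param M_T miRNA universe size; defaults to the number of distinct
#'   miRNAs appearing in either pair set. In a full run this should be
#'   the number of differentially expressed miRNAs in the universe.
#' @param min_shared minimum shared-miRNA count, default 1.
#' @param p_threshold cut on the overlap p-value, default 0.05.
#' @param site_weighted score on predicted binding-site counts
#'   (summing `n_sites`) instead of distinct miRNAs (default `FALSE`:
#'   miRNA granularity, consistent with the p-value).
#' @param bh_adjust apply Benjamini-Hochberg adjustment across all
#'   candidate p-values before the `p_threshold` filter (default
#'   `FALSE`: raw p-values, the convention of this analysis chain).
#' @return data.frame of ceRNA candidates: `lncrna_id`, `mrna_id`, `M_T`,
#'   `m_p`, `m_n`, `m_c`, `cerna_score`, `pval`, `shared_mirnas`
#'   (comma-joined), `source = "predicted"`, ordered by `pval` then ids.
#' @export
predict_cernas <- function(mrna_pairs, lncrna_pairs, M_T = NULL,
                           min_shared = 1, p_threshold = 0.05,
                           site_weighted = FALSE, bh_adjust = FALSE) {
  if (min_shared < 1)
    stop("min_shared must be >= 1", call. = FALSE)
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      M_T = integer(), m_p = integer(), m_n = integer(),
                      m_c = integer(), cerna_score = numeric(),
                      pval = numeric(), shared_mirnas = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (!nrow(mrna_pairs) || !nrow(lncrna_pairs)) return(empty)

  mir_of <- function(pairs) split(mirna_col(pairs), pairs$target_id)
  sites_of <- function(pairs) {
    if (!"n_sites" %in% names(pairs)) return(NULL)
    split(stats::setNames(pairs$n_sites, mirna_col(pairs)),
          pairs$target_id)
  }
  mp_sets <- mir_of(mrna_pairs)
  mn_sets <- mir_of(lncrna_pairs)
  mn_sites <- sites_of(lncrna_pairs)

  universe <- union(mirna_col(mrna_pairs), mirna_col(lncrna_pairs))
  if (is.null(M_T)) M_T <- length(universe)
  if (M_T < max(lengths(mp_sets), lengths(mn_sets)))
    stop("M_T (", M_T, ") is smaller than an observed per-target miRNA ",
         "set; pass the true universe size", call. = FALSE)

  rows <- list()
  for (lnc in names(mn_sets)) {
    for (mrna in names(mp_sets)) {
      shared <- intersect(mn_sets[[lnc]], mp_sets[[mrna]])
      m_c <- length(shared)
      if (m_c < min_shared) next
      m_p <- length(mp_sets[[mrna]])
      m_n <- length(mn_sets[[lnc]])
      score <- if (site_weighted && !is.null(mn_sites)) {
        s <- mn_sites[[lnc]]
        sum(s[shared]) / sum(s)
      } else cerna_score(m_c, m_n)
      p <- hypergeom_pvalue(M_T, m_p, m_n, m_c)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lnc, mrna_id = mrna, M_T = M_T,
        m_p = m_p, m_n = m_n, m_c = m_c,
        cerna_score = score, pval = p,
        shared_mirnas = paste(sort(shared), collapse = ","),
        source = "predicted", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (bh_adjust) out$pval <- stats::p.adjust(out$pval, method = "BH")
  if (p_threshold < 1)
    out <- out[out$pval < p_threshold, , drop = FALSE]
  out <- out[order(out$pval, out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mirna_col <- function(df) {
  if ("mirna_id" %in% names(df)) df$mirna_id else df$source_id
}

#' Call final shared ceRNAs
#'
#' Keeps predicted ceRNA candidates whose (lncRNA, mRNA) pair is also
#' supported by direct lncRNA-mRNA co-expression (the "calculated" set) —
#' the final intersection that defines the reported ceRNA pairs.
#'
#' @param predicted candidate data.frame from [predict_cernas()].
#' @param calculated lncRNA-mRNA correlation edges surviving
#'   [filter_coexpressed()] (`source_id` = lncRNA, `target_id` = mRNA;
#'   the reverse orientation is recognised via the class columns).
#' @return Subset of `predicted` with `source = "shared"`.
#' @export
call_shared_cernas <- function(predicted, calculated) {
  if (!nrow(predicted) || !nrow(calculated)) {
    out <- predicted[integer(0), , drop = FALSE]
    return(out)
  }
  lnc <- calculated$source_id
  mr <- calculated$target_id
  if (all(c("source_class", "target_class") %in% names(calculated))) {
    flip <- calculated$source_class == "mRNA" &
      calculated$target_class == "lncRNA"
    lnc[flip] <- calculated$target_id[flip]
    mr[flip] <- calculated$source_id[flip]
  }
  keys <- paste(lnc, mr, sep = "\r")
  keep <- paste(predicted$lncrna_id, predicted$mrna_id, sep = "\r") %in% keys
  out <- predicted[keep, , drop = FALSE]
  if (nrow(out)) out$source <- "shared"
  rownames(out) <- NULL
  out
}
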