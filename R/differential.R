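#' Fold change between two group means
#'
#' Ratio of treatment mean to control mean and its log2. Zero-baseline
#' features are reported as infinite rather than shifted by a pseudocount:
#' `control_mean = 0` gives `(Inf, Inf)`, `treat_mean = 0` gives
#' `(0, -Inf)`. Vectorised over both arguments.
#'
#' @param treat_mean,control_mean nonnegative means; not both zero.
#' @param pseudocount optional nonnegative shift added to both means for
#'   users who need finite ratios (default 0, i.e. off).
#' @return data.frame with columns `fc` and `log2fc`.
#' @export
#' @examples
#' fold_change(2.14, 1)            # fc 2.14, log2fc 1.098
#' fold_change(5, 0)               # Inf, Inf
fold_change <- function(treat_mean, control_mean, pseudocount = 0) {
  if (any(treat_mean < 0) || any(control_mean < 0))
    stop("means must be nonnegative", call. = FALSE)
  if (pseudocount < 0)
    stop("pseudocount must be nonnegative", call. = FALSE)
  both0 <- treat_mean == 0 & control_mean == 0
  if (any(both0) && pseudocount == 0)
    stop("fold change undefined: both means are zero", call. = FALSE)
  fc <- (treat_mean + pseudocount) / (control_mean + pseudocount)
  data.frame(fc = fc, log2fc = log2(fc))
}

#' Classify differential direction
#'
#' A feature is called `Up` when its fold change is at least
#' `fc_threshold` and the significance criterion is met, `Down` when the
#' fold change is at most `1/fc_threshold` (including fold change 0) with
#' the same criterion, and `NotSignificant` otherwise. A missing p-value
#' (`NA`) waives the significance criterion, so classification falls back
#' to the fold-change rule alone.
#'
#' @param fc fold-change vector (may contain `Inf`/0; `NA` gives
#'   `NotSignificant`).
#' @param pval p-value vector (or adjusted p-values).
#' @param fc_threshold fold-change cut, must be > 1 (default 2).
#' @param alpha significance cut on `pval` (default 0.05).
#' @return character vector in `{"Up", "Down", "NotSignificant"}`.
#' @export
classify_direction <- function(fc, pval, fc_threshold = 2, alpha = 0.05) {
  if (fc_threshold <= 1)
    stop("fc_threshold must be > 1", call. = FALSE)
  sig <- is.na(pval) | pval < alpha
  out <- rep("NotSignificant", length(fc))
  out[!is.na(fc) & sig & fc >= fc_threshold] <- "Up"
  out[!is.na(fc) & sig & fc <= 1 / fc_threshold] <- "Down"
  out
}

#' Per-feature differential table for a two-group design
#'
#' For every feature: treatment/control means, fold change and log2 fold
#' change ([fold_change()]), a Welch two-sample t-test on
#' `log2(value + pseudocount)` across replicates, Benjamini-Hochberg
#' adjustment within each RNA class, and an `Up`/`Down`/`NotSignificant`
#' call ([classify_direction()]).
#'
#' Features expressed in neither group are reported with `foldChange = NA`
#' and `NotSignificant`, with a warning. If either group has fewer than
#' two samples the t-test is skipped (`pval = NA`, warning) and
#' classification uses the fold-change rule alone.
#'
#' @param m an [expression_matrix()].
#' @param fc_threshold fold-change cut (> 1), default 2.
#' @param alpha significance cut, default 0.05.
#' @param use_adjusted classify on BH-adjusted p-values instead of raw
#'   p-values (default `FALSE`; the published tables are raw-p based).
#' @param pseudocount added before the log2 transform for testing
#'   (default 1e-2); does not affect the reported fold change.
#' @return data.frame with columns `feature_id`, `class`, `foldChange`,
#'   `log2FoldChange`, `pval`, `padj`, `up_down`.
#' @export
differential_table <- function(m, fc_threshold = 2, alpha = 0.05,
                               use_adjusted = FALSE, pseudocount = 1e-2) {
  stopifnot(inherits(m, "expr_matrix"))
  if (fc_threshold <= 1)
    stop("fc_threshold must be > 1", call. = FALSE)
  trt <- m$samples$group == "treatment"
  ctl <- m$samples$group == "control"
  if (!any(trt) || !any(ctl))
    stop("both groups must be present", call. = FALSE)
  tm <- rowMeans(m$values[, trt, drop = FALSE])
  cm <- rowMeans(m$values[, ctl, drop = FALSE])

  fc <- tm / cm                       # 0/0 -> NaN, x/0 -> Inf
  both0 <- tm == 0 & cm == 0
  if (any(both0)) {
    warning(sum(both0), " feature(s) unexpressed in both groups; ",
            "fold change reported as NA")
    fc[both0] <- NA_real_
  }
  log2fc <- log2(fc)

  if (sum(trt) < 2 || sum(ctl) < 2) {
    warning("fewer than 2 samples in a group; p-values omitted and ",
            "classification uses the fold-change rule alone")
    pv <- rep(NA_real_, nrow(m$values))
  } else {
    lv <- log2(m$values + pseudocount)
    pv <- apply(lv, 1, function(row) welch_p(row[trt], row[ctl]))
  }

  padj <- rep(NA_real_, length(pv))
  for (cl in unique(m$features$class)) {
    i <- m$features$class == cl
    padj[i] <- stats::p.adjust(pv[i], method = "BH")
  }

  up_down <- classify_direction(fc, if (use_adjusted) padj else pv,
                                fc_threshold = fc_threshold, alpha = alpha)
  up_down[both0] <- "NotSignificant"

  data.frame(feature_id = m$features$feature_id,
             class = m$features$class,
             foldChange = fc,
             log2FoldChange = log2fc,
             pval = pv,
             padj = padj,
             up_down = up_down,
             stringsAsFactors = FALSE)
}

# Welch t on two replicate vectors; degenerate (zero-variance) cases fall
# back to comparing means exactly.
welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}
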