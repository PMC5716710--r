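#' Pipeline run configuration
#'
#' Collects every input and threshold of the full inference chain
#' (differential filtering, correlation pairing, ceRNA scoring, network
#' export). Inputs are either in-memory objects or TSV paths; with
#' `simulate = TRUE` the synthetic generator supplies them instead.
#' Precedence when loading from a YAML file: explicit arguments >
#' file keys > defaults.
#'
#' @param expression an [expression_matrix()] or expression TSV path.
#' @param groups group-map TSV path (required when `expression` is a
#'   path).
#' @param target_pairs predicted-pair data.frame or TSV path.
#' @param simulate generate inputs with [generate_dataset()] (default
#'   `FALSE`).
#' @param sim list of [simulation_config()] overrides used when
#'   `simulate = TRUE`.
#' @param fc_threshold,alpha,use_adjusted differential thresholds
#'   ([differential_table()]).
#' @param r_threshold,p_threshold correlation filter thresholds
#'   ([filter_negative()] / [filter_coexpressed()]).
#' @param coexpression_mode `"absolute"` or `"positive"`
#'   ([filter_coexpressed()]).
#' @param min_shared,cerna_p ceRNA call thresholds ([predict_cernas()]);
#'   `cerna_p = 1` disables the overlap-p filter.
#' @param M_T miRNA universe size; `NULL` (default) uses the number of
#'   differentially expressed miRNAs in the run.
#' @param normalize apply [compute_rpkm()] (mRNA/lncRNA) and
#'   [compute_tpm()] (miRNA) before analysis; needs counts with lengths
#'   (default `FALSE`: inputs are already abundances).
#' @param outdir optional directory; when set, every intermediate table
#'   and the run summary are written there.
#' @param seed integer seed (simulation and any other randomness).
#' @param quiet suppress per-stage progress messages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(expression = NULL, groups = NULL,
                       target_pairs = NULL,
                       simulate = FALSE, sim = list(),
                       fc_threshold = 2, alpha = 0.05,
                       use_adjusted = FALSE,
                       r_threshold = 0.7, p_threshold = 0.05,
                       coexpression_mode = "absolute",
                       min_shared = 1, cerna_p = 0.05, M_T = NULL,
                       normalize = FALSE,
                       outdir = NULL, seed = 1, quiet = FALSE) {
  cfg <- list(expression = expression, groups = groups,
              target_pairs = target_pairs, simulate = simulate,
              sim = sim, fc_threshold = fc_threshold, alpha = alpha,
              use_adjusted = use_adjusted, r_threshold = r_threshold,
              p_threshold = p_threshold,
              coexpression_mode = coexpression_mode,
              min_shared = min_shared, cerna_p = cerna_p, M_T = M_T,
              normalize = normalize, outdir = outdir, seed = seed,
              quiet = quiet)
  if (cfg$fc_threshold <= 1)
    stop("fc_threshold must be > 1", call. = FALSE)
  for (f in c("alpha", "r_threshold", "p_threshold"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(f, " must lie in (0, 1)", call. = FALSE)
  if (cfg$cerna_p <= 0 || cfg$cerna_p > 1)
    stop("cerna_p must lie in (0, 1]", call. = FALSE)
  if (!cfg$coexpression_mode %in% c("absolute", "positive"))
    stop("coexpression_mode must be 'absolute' or 'positive'",
         call. = FALSE)
  if (cfg$min_shared < 1)
    stop("min_shared must be >= 1", call. = FALSE)
  if (!cfg$simulate) {
    if (is.null(cfg$expression) || is.null(cfg$target_pairs))
      stop("either supply expression + target_pairs or set ",
           "simulate = TRUE", call. = FALSE)
    for (f in c("expression", "groups", "target_pairs")) {
      p <- cfg[[f]]
      if (is.character(p) && !file.exists(p))
        stop("input file for `", f, "` does not exist: ", p,
             call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a flat YAML file
#'
#' Every key of the file corresponds to an argument of [run_config()]
#' (simulation overrides live under the `sim` mapping); arguments passed
#' through `...` override file keys.
#'
#' @param path YAML file.
#' @param ... overrides forwarded to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  keys <- yaml::read_yaml(path)
  keys <- utils::modifyList(keys, list(...))
  do.call(run_config, keys)
}

#' Run the full ceRNA inference pipeline
#'
#' Executes simulate/load -> differential filtering -> correlation
#' pairing -> predicted/expression pair intersection -> ceRNA scoring
#' and calling -> network assembly, and returns all intermediate tables
#' plus a stage-by-stage count summary. Mirrors the published chain:
#' only differentially expressed features enter the pairing stages, the
#' miRNA universe for the overlap test is the DE miRNA set, and the
#' final ceRNAs are the candidates supported by both the score test and
#' direct lncRNA-mRNA co-expression.
#'
#' @param config a [run_config()].
#' @return An object of class `cerna_run`: list with `summary` (named
#'   counts), `de` (differential table), `edges` (per-class filtered
#'   correlation edges), `shared_pairs`, `predicted`, `calculated`,
#'   `cernas`, `network` (tripartite), `degrees`, and `truth_eval`
#'   (precision/recall, simulated runs only).
#' @export
run_pipeline <- function(config = run_config(simulate = TRUE)) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!config$quiet) message("[cernatriad] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (config$simulate) {
    sim_args <- utils::modifyList(config$sim, list(seed = config$seed))
    ds <- stage("simulate",
                generate_dataset(do.call(simulation_config, sim_args)))
    expr <- ds$expression
    pairs <- ds$target_pairs
    truth <- ds$truth
    say("simulate: ", nrow(expr$values), " features, ",
        nrow(pairs), " predicted pairs")
  } else {
    expr <- stage("load", {
      if (inherits(config$expression, "expr_matrix")) config$expression
      else read_expression(config$expression, config$groups)
    })
    pairs <- stage("load", {
      if (is.data.frame(config$target_pairs))
        validate_target_pairs(config$target_pairs)
      else read_target_pairs(config$target_pairs)
    })
    say("load: ", nrow(expr$values), " features, ", nrow(pairs),
        " predicted pairs")
  }

  if (config$normalize) {
    expr <- stage("normalize", {
      mi <- expr$features$class == "miRNA"
      mi_ids <- expr$features$feature_id[mi]
      long <- subset_expression(expr, expr$features$feature_id[!mi])
      short <- subset_expression(expr, mi_ids)
      long <- compute_rpkm(long)
      short <- compute_tpm(short)
      v <- rbind(long$values, short$values)
      v <- v[match(expr$features$feature_id, rownames(v)), ,
             drop = FALSE]
      expression_matrix(v, expr$features$class, expr$samples$group,
                        feature_length = expr$features$length)
    })
  }

  de <- stage("de", differential_table(
    expr, fc_threshold = config$fc_threshold, alpha = config$alpha,
    use_adjusted = config$use_adjusted))
  de_ids <- de$feature_id[de$up_down != "NotSignificant"]
  de_expr <- subset_expression(expr, de_ids)
  de_counts <- table(factor(de$class[de$up_down != "NotSignificant"],
                            levels = RNA_CLASSES))
  say("de: ", paste(sprintf("%s=%d", RNA_CLASSES, de_counts),
                    collapse = ", "))
  if (sum(de_counts) == 0)
    say("de: no differential features; downstream stages will be empty")

  de_pairs <- pairs[pairs$mirna_id %in% de_ids &
                    pairs$target_id %in% de_ids, , drop = FALSE]
  corr <- stage("correlate", {
    run_class_corr <- function(target_class, predicted) {
      if (!sum(de_expr$features$class == "miRNA") ||
          !sum(de_expr$features$class == target_class))
        return(empty_edges())
      if (!nrow(predicted)) return(empty_edges())
      correlate_classes(de_expr, "miRNA", target_class,
                        restrict_to = predicted)
    }
    list(mrna = run_class_corr(
           "mRNA", de_pairs[de_pairs$target_class == "mRNA", ]),
         lncrna = run_class_corr(
           "lncRNA", de_pairs[de_pairs$target_class == "lncRNA", ]),
         lnc_mrna = if (sum(de_expr$features$class == "lncRNA") &&
                        sum(de_expr$features$class == "mRNA"))
           correlate_classes(de_expr, "lncRNA", "mRNA")
         else empty_edges())
  })
  neg_mrna <- filter_negative(corr$mrna, config$r_threshold,
                              config$p_threshold)
  neg_lncrna <- filter_negative(corr$lncrna, config$r_threshold,
                                config$p_threshold)
  coexpr <- filter_coexpressed(corr$lnc_mrna, config$r_threshold,
                               config$p_threshold,
                               mode = config$coexpression_mode)
  say("correlate: miRNA-mRNA ", nrow(neg_mrna), "/", nrow(corr$mrna),
      ", miRNA-lncRNA ", nrow(neg_lncrna), "/", nrow(corr$lncrna),
      ", lncRNA-mRNA ", nrow(coexpr), "/", nrow(corr$lnc_mrna))

  shared_mrna <- stage("intersect", intersect_pairs(
    de_pairs[de_pairs$target_class == "mRNA", , drop = FALSE], neg_mrna))
  shared_lncrna <- stage("intersect", intersect_pairs(
    de_pairs[de_pairs$target_class == "lncRNA", , drop = FALSE],
    neg_lncrna))

  M_T <- if (is.null(config$M_T)) as.integer(de_counts["miRNA"])
    else config$M_T
  predicted <- stage("cerna", {
    if (M_T >= 1 && nrow(shared_mrna) && nrow(shared_lncrna))
      predict_cernas(shared_mrna, shared_lncrna, M_T = M_T,
                     min_shared = config$min_shared,
                     p_threshold = config$cerna_p)
    else predict_cernas(shared_mrna[integer(0), , drop = FALSE],
                        shared_lncrna[integer(0), , drop = FALSE])
  })
  cernas <- stage("cerna", call_shared_cernas(predicted, coexpr))
  say("cerna: predicted ", nrow(predicted), ", calculated ",
      nrow(coexpr), ", shared ", nrow(cernas))

  net <- stage("network", build_tripartite_network(
    cernas, shared_mrna, shared_lncrna, annotations = de))
  degrees <- degree_report(net)

  summary <- c(
    n_features = nrow(expr$values),
    n_samples = ncol(expr$values),
    de_mirna = unname(de_counts["miRNA"]),
    de_mrna = unname(de_counts["mRNA"]),
    de_lncrna = unname(de_counts["lncRNA"]),
    predicted_mre_mrna = nrow(de_pairs[de_pairs$target_class == "mRNA", ]),
    predicted_mre_lncrna =
      nrow(de_pairs[de_pairs$target_class == "lncRNA", ]),
    calculated_mre_mrna = nrow(neg_mrna),
    calculated_mre_lncrna = nrow(neg_lncrna),
    shared_mre_mrna = nrow(shared_mrna),
    shared_mre_lncrna = nrow(shared_lncrna),
    predicted_cernas = nrow(predicted),
    calculated_cernas = nrow(coexpr),
    shared_cernas = nrow(cernas),
    network_nodes = nrow(net$nodes),
    network_edges = nrow(net$edges))

  truth_eval <- NULL
  if (!is.null(truth)) {
    truth_eval <- truth_confusion(cernas, truth,
                                  universe = expr$features$feature_id)
    summary <- c(summary, precision = truth_eval$precision,
                 recall = truth_eval$recall)
  }

  run <- structure(list(
    summary = summary, de = de,
    edges = list(mirna_mrna = neg_mrna, mirna_lncrna = neg_lncrna,
                 lncrna_mrna = coexpr),
    shared_pairs = list(mrna = shared_mrna, lncrna = shared_lncrna),
    predicted = predicted, calculated = coexpr, cernas = cernas,
    network = net, degrees = degrees, truth_eval = truth_eval,
    config = config), class = "cerna_run")

  if (!is.null(config$outdir)) write_run(run, config$outdir, expr,
                                         pairs, truth)
  run
}

empty_edges <- function() {
  data.frame(source_id = character(), target_id = character(),
             source_class = character(), target_class = character(),
             r = numeric(), pval = numeric(), n = integer(),
             stringsAsFactors = FALSE)
}

write_run <- function(run, dir, expr, pairs, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))
  write_target_pairs(pairs, file.path(dir, "target_pairs.tsv"))
  if (!is.null(truth))
    write_tsv(truth$planted_triplets,
              file.path(dir, "truth_triplets.tsv"))
  write_differential(run$de, file.path(dir, "differential.tsv"))
  write_edges(run$edges$mirna_mrna,
              file.path(dir, "edges_mirna_mrna.tsv"))
  write_edges(run$edges$mirna_lncrna,
              file.path(dir, "edges_mirna_lncrna.tsv"))
  write_edges(run$edges$lncrna_mrna,
              file.path(dir, "edges_lncrna_mrna.tsv"))
  write_tsv(run$cernas, file.path(dir, "cernas.tsv"))
  write_network(run$network, file.path(dir, "network_nodes.tsv"),
                file.path(dir, "network_edges.tsv"))
  write_tsv(data.frame(key = names(run$summary),
                       value = unname(run$summary),
                       stringsAsFactors = FALSE),
            file.path(dir, "summary.tsv"))
  writeLines(format_summary(run), file.path(dir, "summary.txt"))
  invisible(dir)
}

format_summary <- function(run) {
  s <- run$summary
  c("ceRNA inference run summary",
    sprintf("  input: %d features x %d samples", s["n_features"],
            s["n_samples"]),
    sprintf("  differential: %d miRNA, %d mRNA, %d lncRNA",
            s["de_mirna"], s["de_mrna"], s["de_lncrna"]),
    sprintf("  miRNA-mRNA MREs: predicted %d, calculated %d, shared %d",
            s["predicted_mre_mrna"], s["calculated_mre_mrna"],
            s["shared_mre_mrna"]),
    sprintf("  miRNA-lncRNA MREs: predicted %d, calculated %d, shared %d",
            s["predicted_mre_lncrna"], s["calculated_mre_lncrna"],
            s["shared_mre_lncrna"]),
    sprintf("  ceRNAs: predicted %d, calculated %d, shared %d",
            s["predicted_cernas"], s["calculated_cernas"],
            s["shared_cernas"]),
    if ("precision" %in% names(s))
      sprintf("  truth: precision %.3f, recall %.3f", s["precision"],
              s["recall"]))
}

#' @export
print.cerna_run <- function(x, ...) {
  writeLines(format_summary(x))
  invisible(x)
}
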