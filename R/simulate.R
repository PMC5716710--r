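#' Simulation configuration for planted ceRNA triplets
#'
#' Defines a two-group (3 vs 3 replicates by default, matching the
#' study design the generator emulates), three-class expression
#' simulation in which `n_planted_triplets` miRNAs each repress one mRNA
#' and one lncRNA. Planted miRNAs differ between groups by
#' `mirna_fold_change`; their targets respond multiplicatively with
#' exponent `-repression_strength`, giving the negative miRNA-target and
#' positive lncRNA-mRNA correlations the ceRNA method assumes. All other
#' features are independent log-normal decoys, and `extra_mre_rate`
#' plants spurious predicted pairs (between miRNAs and decoy targets,
#' which have no expression coupling) for the correlation filter to
#' reject.
#'
#' @param n_samples_per_group replicates per group (default 3).
#' @param n_mirna,n_mrna,n_lncrna feature counts per class (defaults
#'   20, 200, 50).
#' @param n_planted_triplets planted (miRNA, mRNA, lncRNA) triplets,
#'   at most `min(n_mirna, n_mrna, n_lncrna)` (default 5).
#' @param mirna_fold_change between-group fold change of planted miRNAs
#'   (default 4: comfortably past a 2-fold differential cut).
#' @param repression_strength exponent in `[0, 1]` coupling target to
#'   miRNA abundance (default 1: full repression).
#' @param noise_sd sd of log-scale (natural log) multiplicative noise
#'   (default 0.1).
#' @param baseline_mean median baseline abundance (default 100).
#' @param extra_mre_rate probability that a (miRNA, decoy target) pair
#'   appears in the predicted pair list (default 0.05).
#' @param seed integer seed governing all randomness (default 1).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_samples_per_group = 3,
                              n_mirna = 20, n_mrna = 200, n_lncrna = 50,
                              n_planted_triplets = 5,
                              mirna_fold_change = 4,
                              repression_strength = 1,
                              noise_sd = 0.1,
                              baseline_mean = 100,
                              extra_mre_rate = 0.05,
                              seed = 1) {
  cfg <- list(n_samples_per_group = n_samples_per_group,
              n_mirna = n_mirna, n_mrna = n_mrna, n_lncrna = n_lncrna,
              n_planted_triplets = n_planted_triplets,
              mirna_fold_change = mirna_fold_change,
              repression_strength = repression_strength,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              extra_mre_rate = extra_mre_rate, seed = seed)
  chk <- function(ok, field, what) {
    if (!isTRUE(ok))
      stop("invalid simulation config: `", field, "` ", what,
           call. = FALSE)
  }
  for (f in c("n_samples_per_group", "n_mirna", "n_mrna", "n_lncrna",
              "n_planted_triplets"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
          cfg[[f]] >= 1 && cfg[[f]] == round(cfg[[f]]),
        f, "must be a positive integer")
  chk(cfg$n_planted_triplets <=
        min(cfg$n_mirna, cfg$n_mrna, cfg$n_lncrna),
      "n_planted_triplets",
      "must not exceed min(n_mirna, n_mrna, n_lncrna)")
  chk(is.numeric(cfg$mirna_fold_change) && cfg$mirna_fold_change > 0,
      "mirna_fold_change", "must be positive")
  chk(is.numeric(cfg$repression_strength) &&
        cfg$repression_strength >= 0 && cfg$repression_strength <= 1,
      "repression_strength", "must lie in [0, 1]")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0,
      "noise_sd", "must be nonnegative")
  chk(is.numeric(cfg$baseline_mean) && cfg$baseline_mean > 0,
      "baseline_mean", "must be positive")
  chk(is.numeric(cfg$extra_mre_rate) && cfg$extra_mre_rate >= 0 &&
        cfg$extra_mre_rate <= 1,
      "extra_mre_rate", "must lie in [0, 1]")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
        cfg$seed == round(cfg$seed),
      "seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic three-class dataset with planted ceRNA triplets
#'
#' Expression model (log-normal, per feature `i` and sample `s`):
#' baselines `b_i ~ LogNormal(log(baseline_mean), 0.5)`; planted miRNA
#' `j`: `m_js = b_j * FC^[s in treatment] * e_js`; its planted targets:
#' `t_is = b_i * (m*_js / gmean(m*_j))^(-strength) * e_is`, where `m*`
#' is the miRNA signal before noise and `e ~ LogNormal(0, noise_sd)`.
#' Decoy features are `b_i * e_is`. On the log scale every planted
#' relationship is exactly linear, so with `noise_sd = 0` and
#' `repression_strength > 0` planted miRNA-target pairs have Pearson
#' r = -1 and lncRNA-mRNA pairs r = +1 on log2 abundances.
#'
#' The predicted pair list contains the two planted MRE pairs of every
#' triplet (1-3 sites each) plus decoy pairs between miRNAs and
#' non-planted targets at `extra_mre_rate`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `expression` (an [expression_matrix()]
#'   with feature lengths), `target_pairs` (data.frame of predicted
#'   pairs) and `truth` (list: `planted_triplets` data.frame with
#'   `mirna_id`, `mrna_id`, `lncrna_id`; `planted_pair_list` the planted
#'   subset of `target_pairs`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "sim_config"))
    config <- do.call(simulation_config, config)
  with_preserved_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_s <- cfg$n_samples_per_group
  samples <- c(paste0("ctl_", seq_len(n_s)), paste0("trt_", seq_len(n_s)))
  group <- rep(c("control", "treatment"), each = n_s)
  trt <- group == "treatment"

  mirna_ids <- sprintf("miR_%03d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("gene_%04d", seq_len(cfg$n_mrna))
  lncrna_ids <- sprintf("lnc_%04d", seq_len(cfg$n_lncrna))
  ids <- c(mirna_ids, mrna_ids, lncrna_ids)
  cls <- rep(c("miRNA", "mRNA", "lncRNA"),
             c(cfg$n_mirna, cfg$n_mrna, cfg$n_lncrna))
  n_feat <- length(ids)

  k <- cfg$n_planted_triplets
  triplets <- data.frame(mirna_id = mirna_ids[seq_len(k)],
                         mrna_id = mrna_ids[seq_len(k)],
                         lncrna_id = lncrna_ids[seq_len(k)],
                         stringsAsFactors = FALSE)

  baseline <- stats::rlnorm(n_feat, meanlog = log(cfg$baseline_mean),
                            sdlog = 0.5)
  names(baseline) <- ids
  lengths <- stats::setNames(
    c(sample(20:25, cfg$n_mirna, replace = TRUE),
      sample(500:5000, cfg$n_mrna, replace = TRUE),
      sample(300:3000, cfg$n_lncrna, replace = TRUE)), ids)

  noise <- function(n) stats::rlnorm(n, meanlog = 0, sdlog = cfg$noise_sd)

  v <- matrix(0, n_feat, length(samples), dimnames = list(ids, samples))
  # decoys and miRNAs first: baseline (x group effect for planted miRNAs)
  for (i in seq_len(n_feat)) {
    sig <- rep(baseline[i], length(samples))
    if (ids[i] %in% triplets$mirna_id)
      sig[trt] <- sig[trt] * cfg$mirna_fold_change
    v[i, ] <- sig
  }
  # planted targets track the noiseless miRNA signal
  for (t in seq_len(k)) {
    mir_sig <- v[triplets$mirna_id[t], ]
    rel <- mir_sig / exp(mean(log(mir_sig)))   # relative to geometric mean
    for (tid in c(triplets$mrna_id[t], triplets$lncrna_id[t]))
      v[tid, ] <- baseline[tid] * rel^(-cfg$repression_strength)
  }
  if (cfg$noise_sd > 0)
    v <- v * matrix(noise(length(v)), nrow(v), ncol(v))

  expr <- expression_matrix(v, cls, group, feature_length = lengths)

  planted <- rbind(
    data.frame(mirna_id = triplets$mirna_id, target_id = triplets$mrna_id,
               target_class = "mRNA", stringsAsFactors = FALSE),
    data.frame(mirna_id = triplets$mirna_id,
               target_id = triplets$lncrna_id,
               target_class = "lncRNA", stringsAsFactors = FALSE))
  planted$n_sites <- sample(1:3, nrow(planted), replace = TRUE)
  planted$score <- round(stats::runif(nrow(planted), 140, 180), 2)

  decoy_targets <- data.frame(
    target_id = c(mrna_ids, lncrna_ids),
    target_class = rep(c("mRNA", "lncRNA"), c(cfg$n_mrna, cfg$n_lncrna)),
    stringsAsFactors = FALSE)
  planted_target <- decoy_targets$target_id %in%
    c(triplets$mrna_id, triplets$lncrna_id)
  decoy_targets <- decoy_targets[!planted_target, , drop = FALSE]
  extra <- expand.grid(mirna_id = mirna_ids,
                       target_id = decoy_targets$target_id,
                       stringsAsFactors = FALSE)
  extra$target_class <- decoy_targets$target_class[
    match(extra$target_id, decoy_targets$target_id)]
  extra <- extra[stats::runif(nrow(extra)) < cfg$extra_mre_rate, ,
                 drop = FALSE]
  if (nrow(extra)) {
    extra$n_sites <- sample(1:3, nrow(extra), replace = TRUE)
    extra$score <- round(stats::runif(nrow(extra), 140, 180), 2)
  } else {
    extra$n_sites <- numeric(0)
    extra$score <- numeric(0)
  }
  pairs <- validate_target_pairs(rbind(planted, extra))

  list(expression = expr,
       target_pairs = pairs,
       truth = list(planted_triplets = triplets,
                    planted_pair_list = planted))
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG
# state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Precision and recall of called ceRNA pairs against planted truth
#'
#' Compares called (lncRNA, mRNA) pairs with the planted triplets.
#' Precision is defined as 1 when nothing is called (no false positives
#' were produced); recall is the fraction of planted pairs recovered.
#'
#' @param called data.frame with columns `lncrna_id`, `mrna_id`
#'   (e.g. output of [call_shared_cernas()]).
#' @param truth the `truth` element of [generate_dataset()] output.
#' @param universe optional character vector of valid feature ids for
#'   id checking; defaults to the ids occurring in the truth's triplets
#'   plus any id (ids outside the generated matrices are rejected when a
#'   universe is given).
#' @return list with elements `precision` and `recall`, both in `[0, 1]`.
#' @export
truth_confusion <- function(called, truth, universe = NULL) {
  planted <- paste(truth$planted_triplets$lncrna_id,
                   truth$planted_triplets$mrna_id, sep = "\r")
  if (!is.null(universe)) {
    unknown <- setdiff(c(called$lncrna_id, called$mrna_id), universe)
    if (length(unknown))
      stop("called pairs reference unknown ids: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  called_keys <- unique(paste(called$lncrna_id, called$mrna_id,
                              sep = "\r"))
  hits <- sum(called_keys %in% planted)
  list(precision = if (length(called_keys)) hits / length(called_keys)
       else 1,
       recall = hits / length(planted))
}

#' Write a simulated dataset to a directory
#'
#' Writes `expression.tsv` + `groups.tsv` ([write_expression()]),
#' `target_pairs.tsv` ([write_target_pairs()]) and the ground truth as
#' `truth_triplets.tsv` (tab-delimited triplet table).
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression,
                   file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))
  write_target_pairs(dataset$target_pairs,
                     file.path(dir, "target_pairs.tsv"))
  write_tsv(dataset$truth$planted_triplets,
            file.path(dir, "truth_triplets.tsv"))
  invisible(dir)
}
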