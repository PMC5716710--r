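# Independent oracles and small in-code fixtures shared across tests.

# Brute-force overlap tail probability: enumerate every mp-subset of a
# universe of MT labelled miRNAs, take the lncRNA's set to be labels
# 1..mn, and count subsets overlapping it in at least mc elements.
# Deliberately naive; the implementation under test never sees this.
overlap_tail_oracle <- function(MT, mp, mn, mc) {
  subs <- utils::combn(MT, mp)
  ov <- colSums(matrix(subs <= mn, nrow = mp))
  mean(ov >= mc)
}

# A deterministic 4-feature x 6-sample toy matrix: one miRNA up 4-fold
# in treatment, one mRNA and one lncRNA tracking it inversely, one flat
# decoy mRNA. No noise, so planted correlations are exact on the log
# scale.
toy_matrix <- function() {
  mir <- c(10, 10, 10, 40, 40, 40)
  tgt <- 100 / (mir / exp(mean(log(mir))))
  v <- rbind(miR_1 = mir, gene_1 = tgt, lnc_1 = tgt * 2,
             gene_flat = rep(50, 6))
  colnames(v) <- c("c1", "c2", "c3", "t1", "t2", "t3")
  expression_matrix(v, c("miRNA", "mRNA", "lncRNA", "mRNA"),
                    rep(c("control", "treatment"), each = 3),
                    feature_length = c(22, 1000, 2000, 1500))
}

# Pair data.frames from character vectors "mir:target".
pair_df <- function(keys, target_class = "mRNA") {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(mirna_id = vapply(parts, `[`, "", 1),
             target_id = vapply(parts, `[`, "", 2),
             target_class = target_class,
             n_sites = 1,
             stringsAsFactors = FALSE)
}

# lncRNA-mRNA co-expression edges from "lnc:gene" keys.
calc_edges <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(source_id = vapply(parts, `[`, "", 1),
             target_id = vapply(parts, `[`, "", 2),
             source_class = rep("lncRNA", length(keys)),
             target_class = rep("mRNA", length(keys)),
             r = rep(0.9, length(keys)), pval = rep(0.01, length(keys)),
             n = rep(6, length(keys)), stringsAsFactors = FALSE)
}

empty_calc <- function() calc_edges(character(0))

published_mirna_table <- function() {
  utils::read.delim(system.file("extdata", "de_mirna_table.tsv",
                                package = "cernatriad"),
                    stringsAsFactors = FALSE)
}

published_lncrna_table <- function() {
  utils::read.delim(system.file("extdata", "de_lncrna_table.tsv",
                                package = "cernatriad"),
                    stringsAsFactors = FALSE)
}
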