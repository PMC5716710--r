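test_that("intersect_pairs is an exact set intersection", {
  a <- pair_df(c("a:x", "a:y", "b:x"))
  b <- pair_df(c("a:y", "b:x", "b:y"))
  got <- intersect_pairs(a, b)
  expect_equal(paste(got$mirna_id, got$target_id),
               c("a y", "b x"))
  expect_equal(nrow(intersect_pairs(a, pair_df("c:z"))), 0)
  expect_equal(intersect_pairs(a, a)[names(a)], a)

  # commutative and idempotent on the key set
  ab <- intersect_pairs(a, b)
  ba <- intersect_pairs(b, a)
  expect_setequal(paste(ab$mirna_id, ab$target_id),
                  paste(ba$mirna_id, ba$target_id))
  expect_equal(intersect_pairs(ab, b)[names(ab)], ab)

  expect_error(intersect_pairs(a, pair_df("a:x", "lncRNA")),
               "mixed target classes")
})

test_that("intersect_pairs carries correlation columns from the expression side", {
  pred <- pair_df(c("a:x", "a:y"))
  edges <- data.frame(source_id = c("a", "a"), target_id = c("y", "z"),
                      source_class = "miRNA", target_class = "mRNA",
                      r = c(-0.9, -0.8), pval = c(0.01, 0.02), n = 6)
  got <- intersect_pairs(pred, edges)
  expect_equal(got$target_id, "y")
  expect_equal(got$r, -0.9)
})

test_that("cerna_score is the shared fraction of the lncRNA miRNA set", {
  expect_equal(cerna_score(2, 4), 0.5)
  expect_equal(cerna_score(4, 4), 1)
  expect_equal(cerna_score(0, 3), 0)
  expect_error(cerna_score(1, 0), "m_n must be >= 1")
  expect_error(cerna_score(5, 4), "m_c must lie")
})

test_that("hypergeom_pvalue matches hand-enumerated closed forms", {
  # m_c = 0: the sum runs over the full support
  expect_equal(hypergeom_pvalue(10, 4, 5, 0), 1)
  expect_equal(hypergeom_pvalue(24, 10, 3, 0), 1)
  # universe of 3, both sets singletons: the draw hits 1/3 of the time
  expect_equal(hypergeom_pvalue(3, 1, 1, 1), 1 / 3, tolerance = 1e-12)
  # C(5,3)C(5,1) + C(5,4)C(5,0) = 55 of the C(10,4) = 210 subsets
  expect_equal(hypergeom_pvalue(10, 4, 5, 3), 55 / 210,
               tolerance = 1e-12)
  expect_error(hypergeom_pvalue(5, 6, 2, 1), "exceed M_T")
  expect_error(hypergeom_pvalue(5, 2, 2, 3), "exceed min")
  expect_error(hypergeom_pvalue(5.5, 2, 2, 1), "integers")
})

test_that("hypergeom_pvalue agrees with brute-force enumeration (universe <= 12)", {
  for (MT in 2:12) {
    for (mp in 1:MT) {
      subs <- utils::combn(MT, mp)
      for (mn in 1:MT) {
        ov <- colSums(matrix(subs <= mn, nrow = mp))
        for (mc in 0:min(mp, mn)) {
          expect_equal(hypergeom_pvalue(MT, mp, mn, mc),
                       mean(ov >= mc), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeom_pvalue is symmetric, monotone in m_c, and stable at scale", {
  for (MT in c(6, 11)) {
    for (mp in 1:MT) for (mn in 1:MT) {
      prev <- Inf
      for (mc in 0:min(mp, mn)) {
        p <- hypergeom_pvalue(MT, mp, mn, mc)
        expect_equal(p, hypergeom_pvalue(MT, mn, mp, mc),
                     tolerance = 1e-12)
        expect_lte(p, prev + 1e-15)
        prev <- p
      }
    }
  }
  # log-space evaluation survives arguments far beyond choose() overflow
  p_big <- hypergeom_pvalue(20000, 800, 900, 60)
  expect_true(p_big > 0 && p_big < 1)
  expect_equal(p_big,
               phyper(59, 900, 20000 - 900, 800, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("predict_cernas computes counts, score and p per candidate", {
  expect_equal(nrow(predict_cernas(pair_df(c("a:g1")),
                                   pair_df("b:l1", "lncRNA"))), 0)

  one <- predict_cernas(pair_df("a:g1"), pair_df("a:l1", "lncRNA"),
                        M_T = 3, p_threshold = 1)
  expect_equal(one$m_p, 1)
  expect_equal(one$m_n, 1)
  expect_equal(one$m_c, 1)
  expect_equal(one$cerna_score, 1)
  expect_equal(one$pval, 1 / 3, tolerance = 1e-12)
  expect_equal(one$shared_mirnas, "a")
  expect_equal(one$source, "predicted")
  # the same candidate fails a 0.05 p filter
  expect_equal(nrow(predict_cernas(pair_df("a:g1"),
                                   pair_df("a:l1", "lncRNA"), M_T = 3)),
               0)

  # two shared of m_n = 3, m_p = 2, universe 10
  mr <- pair_df(c("a:g1", "b:g1"))
  ln <- pair_df(c("a:l1", "b:l1", "c:l1"), "lncRNA")
  cand <- predict_cernas(mr, ln, M_T = 10, p_threshold = 1)
  expect_equal(cand$m_c, 2)
  expect_equal(cand$cerna_score, 2 / 3)
  expect_equal(cand$pval, hypergeom_pvalue(10, 2, 3, 2))

  expect_error(predict_cernas(mr, ln, M_T = 2), "smaller than")
  expect_error(predict_cernas(mr, ln, min_shared = 0), "min_shared")

  # optional BH adjustment across candidates never lowers a p-value
  mr2 <- pair_df(c("a:g1", "b:g1", "a:g2"))
  raw <- predict_cernas(mr2, ln, M_T = 10, p_threshold = 1)
  adj <- predict_cernas(mr2, ln, M_T = 10, p_threshold = 1,
                        bh_adjust = TRUE)
  key <- function(d) paste(d$lncrna_id, d$mrna_id)
  expect_true(all(adj$pval[match(key(raw), key(adj))] >= raw$pval))

  # site-weighted score uses predicted site counts on the lncRNA side
  ln_sites <- pair_df(c("a:l1", "b:l1"), "lncRNA")
  ln_sites$n_sites <- c(3, 1)
  sw <- predict_cernas(pair_df("a:g1"), ln_sites, M_T = 10,
                       p_threshold = 1, site_weighted = TRUE)
  expect_equal(sw$cerna_score, 3 / 4)
  mw <- predict_cernas(pair_df("a:g1"), ln_sites, M_T = 10,
                       p_threshold = 1)
  expect_equal(mw$cerna_score, 1 / 2)
})

test_that("a planted triplet with decoys off yields exactly its candidate", {
  cfg <- simulation_config(n_mirna = 5, n_mrna = 20, n_lncrna = 10,
                           n_planted_triplets = 1, extra_mre_rate = 0,
                           noise_sd = 0, seed = 11)
  ds <- generate_dataset(cfg)
  mr <- ds$target_pairs[ds$target_pairs$target_class == "mRNA", ]
  ln <- ds$target_pairs[ds$target_pairs$target_class == "lncRNA", ]
  cand <- predict_cernas(mr, ln, M_T = 5, p_threshold = 1)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$lncrna_id, ds$truth$planted_triplets$lncrna_id)
  expect_equal(cand$mrna_id, ds$truth$planted_triplets$mrna_id)
  expect_equal(cand$cerna_score, 1)
})

test_that("call_shared_cernas keeps co-expression-supported candidates", {
  pred <- predict_cernas(
    pair_df(c("a:g1", "a:g2", "a:g3")),
    pair_df("a:l1", "lncRNA"), M_T = 10, p_threshold = 1)
  expect_equal(nrow(pred), 3)

  expect_equal(nrow(call_shared_cernas(pred, empty_calc())), 0)

  all_edges <- calc_edges(c("l1:g1", "l1:g2", "l1:g3", "l1:g9"))
  expect_equal(call_shared_cernas(pred, all_edges)[names(pred)[1:6]],
               pred[1:6])

  two <- calc_edges(c("l1:g1", "l1:g3"))
  got <- call_shared_cernas(pred, two)
  expect_equal(sort(got$mrna_id), c("g1", "g3"))
  expect_true(all(got$source == "shared"))

  # reversed orientation (mRNA as source) is recognised via classes
  rev_edges <- data.frame(source_id = "g2", target_id = "l1",
                          source_class = "mRNA",
                          target_class = "lncRNA",
                          r = 0.9, pval = 0.01, n = 6)
  expect_equal(call_shared_cernas(pred, rev_edges)$mrna_id, "g2")
})
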