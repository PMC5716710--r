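test_that("fold_change matches the published table arithmetic", {
  # finite ratios: log2 column consistent with the fold-change column
  expect_equal(fold_change(2.14, 1)$log2fc, 1.10, tolerance = 0.005)
  expect_equal(fold_change(0.50, 1)$log2fc, -1.00, tolerance = 0.005)
  expect_equal(fold_change(76.19620987, 1)$log2fc, 6.251647332,
               tolerance = 1e-4)
  # zero-baseline features are reported as infinite, not pseudocounted
  up <- fold_change(5, 0)
  expect_equal(up$fc, Inf)
  expect_equal(up$log2fc, Inf)
  down <- fold_change(0, 5)
  expect_equal(down$fc, 0)
  expect_equal(down$log2fc, -Inf)
  expect_error(fold_change(0, 0), "both means are zero")
  expect_equal(fold_change(0, 0, pseudocount = 1)$fc, 1)
})

test_that("fold change is reciprocal and log2fc antisymmetric under group swap", {
  a <- c(2.3, 0.11, 77, 1)
  b <- c(1.9, 4.5, 0.2, 1)
  fwd <- fold_change(a, b)
  rev <- fold_change(b, a)
  expect_equal(fwd$fc * rev$fc, rep(1, 4))
  expect_equal(fwd$log2fc, -rev$log2fc)
})

test_that("direction classification applies the conjunction rule", {
  expect_equal(classify_direction(c(2.5, 2.5, 0.4, 0.4, 1.2, 2, 0.5),
                                  c(0.01, 0.2, 0.01, 0.2, 0.01, 0.049,
                                    0.049)),
               c("Up", "NotSignificant", "Down", "NotSignificant",
                 "NotSignificant", "Up", "Down"))
  # infinite and zero fold changes classify when significant
  expect_equal(classify_direction(c(Inf, 0), c(0.001, 0.001)),
               c("Up", "Down"))
  expect_error(classify_direction(2, 0.01, fc_threshold = 1),
               "fc_threshold must be > 1")
})

test_that("published miRNA table: log2 recomputation and tallies", {
  t1 <- published_mirna_table()
  expect_equal(nrow(t1), 24)
  # both printed columns are rounded to 2 dp; consistency bound accounts
  # for the fold-change rounding propagated through log2
  bound <- 0.005 / (t1$foldChange * log(2)) + 0.005
  expect_true(all(abs(log2(t1$foldChange) - t1$log2FoldChange) <= bound))

  # printed direction column: 9 up, 15 down
  expect_equal(sum(t1$up_down == "Up"), 9)
  expect_equal(sum(t1$up_down == "Down"), 15)

  # the strict 2-fold rule reproduces the Down tally but only 5 of the
  # 9 printed Up rows (the table lists Up fold changes down to 1.78);
  # a 1.5-fold cut recovers the printed tallies exactly
  strict <- classify_direction(t1$foldChange, t1$pval)
  expect_equal(sum(strict == "Down"), 15)
  expect_equal(sum(strict == "Up"), 5)
  relaxed <- classify_direction(t1$foldChange, t1$pval,
                                fc_threshold = 1.5)
  expect_equal(sum(relaxed == "Up"), 9)
  expect_equal(sum(relaxed == "Down"), 15)
})

test_that("published lncRNA table: log2 recomputation and tallies", {
  t2 <- published_lncrna_table()
  expect_equal(nrow(t2), 33)
  fin <- is.finite(t2$foldChange) & t2$foldChange > 0
  expect_equal(log2(t2$foldChange[fin]), t2$log2FoldChange[fin],
               tolerance = 1e-4)
  expect_equal(sum(!is.finite(t2$foldChange)), 5)  # zero-baseline rows

  called <- classify_direction(t2$foldChange, t2$pval)
  expect_equal(sum(called == "Up"), 28)
  expect_equal(sum(called == "Down"), 5)
  expect_equal(called, t2$up_down)
})

test_that("differential_table detects planted signal and obeys BH invariants", {
  set.seed(42)
  k <- 40
  v <- matrix(rlnorm(k * 6, log(100), 0.1), k, 6,
              dimnames = list(sprintf("g%02d", 1:k),
                              c("c1", "c2", "c3", "t1", "t2", "t3")))
  v[1, 4:6] <- v[1, 4:6] * 8     # planted up
  v[2, 4:6] <- v[2, 4:6] / 8     # planted down
  m <- expression_matrix(v, rep(c("mRNA", "lncRNA"), each = k / 2),
                         rep(c("control", "treatment"), each = 3))
  de <- differential_table(m)
  expect_equal(de$up_down[1:2], c("Up", "Down"))
  expect_lte(sum(de$up_down != "NotSignificant"), 4)

  # fc/log2fc consistency invariant on every record
  fin <- is.finite(de$foldChange) & de$foldChange > 0
  expect_equal(de$log2FoldChange[fin], log2(de$foldChange[fin]),
               tolerance = 1e-9)

  # BH per class: padj >= pval, <= 1, step-up monotone within class
  expect_true(all(de$padj >= de$pval))
  expect_true(all(de$padj <= 1))
  for (cl in unique(de$class)) {
    sub <- de[de$class == cl, ]
    sub <- sub[order(sub$pval), ]
    expect_true(all(diff(sub$padj) >= -1e-12))
    expect_equal(sub$padj, p.adjust(sub$pval, "BH"))
  }
})

test_that("identical groups yield no calls; degenerate designs warn", {
  v <- matrix(rep(c(5, 9, 100), 6), 3, 6,
              dimnames = list(c("a", "b", "c"),
                              c("c1", "c2", "c3", "t1", "t2", "t3")))
  m <- expression_matrix(v, rep("mRNA", 3),
                         rep(c("control", "treatment"), each = 3))
  de <- differential_table(m)
  expect_true(all(de$up_down == "NotSignificant"))
  expect_true(all(de$pval == 1))

  v1 <- matrix(c(10, 1, 80, 2), 2, 2,
               dimnames = list(c("a", "b"), c("c1", "t1")))
  m1 <- expression_matrix(v1, rep("mRNA", 2), c("control", "treatment"))
  expect_warning(de1 <- differential_table(m1), "fewer than 2 samples")
  expect_true(all(is.na(de1$pval)))
  expect_equal(de1$up_down, c("Up", "Up"))

  vz <- matrix(c(0, 1, 0, 2, 0, 1, 0, 3, 0, 2, 0, 2), 2, 6,
               dimnames = list(c("z", "a"),
                               c("c1", "c2", "c3", "t1", "t2", "t3")))
  mz <- expression_matrix(vz, rep("mRNA", 2),
                          rep(c("control", "treatment"), each = 3))
  expect_warning(dez <- differential_table(mz), "unexpressed in both")
  expect_true(is.na(dez$foldChange[1]))
  expect_equal(dez$up_down[1], "NotSignificant")
})
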