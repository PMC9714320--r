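test_that("correlation coefficients match closed forms and rank identities", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("i1", "i2", "i3")))
  cp <- correlateFeatures(cbind(x, neg = -x[, 1]), x, "pearson")
  expect_equal(cp$r["i1", "i1"], 1)
  expect_equal(cp$r["neg", "i1"], -1)

  ## Spearman is invariant under monotone transforms
  sp <- correlateFeatures(exp(x[, 1, drop = FALSE]), x[, 1, drop = FALSE],
                          "spearman")
  expect_equal(unname(sp$r[1, 1]), 1)

  ## Pearson against the covariance / (sd * sd) formula
  y <- matrix(rnorm(80), 20, 4)
  colnames(y) <- paste0("o", 1:4)
  cp <- correlateFeatures(x, y, "pearson")
  for (i in 1:3) for (j in 1:4) {
    num <- mean((x[, i] - mean(x[, i])) * (y[, j] - mean(y[, j])))
    den <- sqrt(mean((x[, i] - mean(x[, i]))^2)) *
           sqrt(mean((y[, j] - mean(y[, j]))^2))
    expect_equal(unname(cp$r[i, j]), num / den, tolerance = 1e-12)
  }

  ## Spearman equals Pearson on average ranks
  xt <- x; xt[1, 1] <- xt[2, 1]        # introduce a tie
  sp <- correlateFeatures(xt, y, "spearman")
  pr <- correlateFeatures(apply(xt, 2, rank), apply(y, 2, rank), "pearson")
  expect_equal(sp$r, pr$r, tolerance = 1e-12, ignore_attr = TRUE)

  ## p-values agree with the standard two-sided tests
  ctp <- cor.test(x[, 1], y[, 2])$p.value
  expect_equal(unname(cp$p[1, 2]), ctp, tolerance = 1e-12)
  cts <- cor.test(xt[, 2], y[, 3], method = "spearman", exact = FALSE)$p.value
  expect_equal(unname(sp$p[2, 3]), cts, tolerance = 1e-10)

  ## zero-variance features are recorded as r = 0, p = 1 with a warning
  expect_warning(z <- correlateFeatures(cbind(x, flat = 7), y, "pearson"),
                 "zero-variance")
  expect_equal(unname(z$r["flat", ]), rep(0, 4))
  expect_equal(unname(z$p["flat", ]), rep(1, 4))

  expect_error(correlateFeatures(x[1:2, ], y[1:2, ]), "at least 3")
})

test_that("p-value adjustment follows each method and stays monotone", {
  expect_equal(adjustPvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  for (m in c("holm", "hochberg", "BH", "BY", "bonferroni", "hommel"))
    expect_equal(adjustPvalues(0.03, m), 0.03)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_identical(adjustPvalues(c(0.2, 0.01), "fdr"),
                   adjustPvalues(c(0.2, 0.01), "BH"))
  expect_error(adjustPvalues(0.5, "banana"), "unknown")
  expect_error(adjustPvalues(1.2, "BH"), "\\[0,1\\]")

  set.seed(42)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    for (m in c("holm", "hochberg", "BH", "BY", "bonferroni")) {
      a <- adjustPvalues(p, m)
      expect_true(all(a >= 0 & a <= 1))
      expect_true(all(diff(a[order(p)]) >= -1e-15))   # monotone in p
      if (m %in% c("bonferroni", "holm")) expect_true(all(a >= p - 1e-15))
    }
  }
})

test_that("pair filtering applies strict thresholds and the disable switch", {
  r <- matrix(c(0.6, 0.9, 0.2, -0.7), 2, 2,
              dimnames = list(c("i1", "i2"), c("o1", "o2")))
  p <- matrix(c(0.001, 0.2, 0.5, 0.01), 2, 2, dimnames = dimnames(r))
  cr <- new("CorrelationResult", method = "pearson", r = r, p = p,
            padj = p, correctionMethod = "BH", coeffThreshold = NA_real_,
            pThreshold = NA_real_, survivingImaging = NULL,
            survivingOmics = NULL, pairs = NULL)
  f <- filterByCorrelation(cr, 0.5, 0.05)
  pairs <- survivingPairs(f)
  ## i1-o1 (|r|=0.6, p 0.001) and i2-o2 (|r|=0.7, p 0.01) survive;
  ## i2-o1 has r=0.9 but adjusted p 0.2 -> dropped
  expect_true(pairs$survives[pairs$feature_imaging == "i1" &
                             pairs$feature_omics == "o1"])
  expect_false(pairs$survives[pairs$feature_imaging == "i2" &
                              pairs$feature_omics == "o1"])
  expect_setequal(f@survivingImaging, c("i1", "i2"))

  ## strictness at the boundary: |r| must exceed the threshold
  g <- filterByCorrelation(cr, 0.6, 0.05)
  expect_false("i1" %in% g@survivingImaging)

  off <- filterByCorrelation(cr, -1.0)
  expect_equal(off@survivingImaging, c("i1", "i2"))
  expect_equal(off@survivingOmics, c("o1", "o2"))
  expect_true(all(survivingPairs(off)$survives))

  ## monotone shrinkage: a higher threshold keeps a subset
  set.seed(9)
  cr2 <- correlationAnalysis(randomTable(30, 8, seed = 1),
                             randomTable(30, 6, "omics", seed = 2),
                             "pearson")
  lo <- filterByCorrelation(cr2, 0.1, 0.5)
  hi <- filterByCorrelation(cr2, 0.4, 0.5)
  expect_true(all(hi@survivingImaging %in% lo@survivingImaging))
  expect_true(all(hi@survivingOmics %in% lo@survivingOmics))
})

test_that("heat-map leaf ordering reproduces brute-force average linkage", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 2.9, 4.2), c = c(2, 1, 4, 1))
  ord <- clusterOrder(m)
  expect_setequal(ord$rowOrder, 1:3)
  expect_setequal(ord$colOrder, 1:4)
  ## rows a and b are near-identical profiles -> merged first, adjacent
  pos <- match(1:2, ord$rowOrder)
  expect_equal(abs(diff(pos)), 1L)

  ## brute-force agglomeration oracle on the 3x3 profile distances
  d <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3)
    d[j, i] <- d[i, j] <- 1 - abs(cor(m[i, ], m[j, ]))
  firstPair <- as.integer(which(d == min(d[upper.tri(d)]),
                                arr.ind = TRUE)[1, ])
  expect_setequal(firstPair, 1:2)
  h <- ord$rowTree
  expect_setequal(-h$merge[1, ], firstPair)   # first merge = closest pair
  expect_equal(h$height[1], min(d[upper.tri(d)]), tolerance = 1e-12)
  ## average-linkage height of the final merge
  expect_equal(h$height[2], mean(c(d[1, 3], d[2, 3])), tolerance = 1e-12)

  single <- clusterOrder(m[1, , drop = FALSE])
  expect_equal(single$rowOrder, 1L)
  expect_error(clusterOrder(matrix(c(1, NA), 1, 2)), "finite")
})
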