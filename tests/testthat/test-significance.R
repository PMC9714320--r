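test_that("the test-phase gate applies strict AUC and R2 thresholds", {
  met <- data.frame(label = c("WT1-like", "border", "weakR2", "allNA"),
                    AUC = c(1.0, 0.9, 0.95, NA),
                    R2_direct = c(0.48, 0.5, 0.1, NA))
  expect_equal(gateLabels(met), "WT1-like")
})

test_that("permutation p-values count exceedances on the 1/n grid", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  Y <- matrix(X[, 1] * 2 + rnorm(n, sd = 0.1), ncol = 1,
              dimnames = list(NULL, "g1"))
  tr <- 1:30; te <- 31:40
  pr <- permutationTest(modelSpec("linear"), X[tr, ], Y[tr, , drop = FALSE],
                        X[te, ], Y[te, 1], "g1", nPerm = 40, seed = 5)
  ## strong signal beats every permutation
  expect_equal(pr@pR2, 0)
  expect_length(pr@r2Perm, 40L)
  expect_true(all(pr@r2Perm < pr@r2Test))
  ## p-values are multiples of 1/n_perm
  expect_equal(pr@pAuc * 40, round(pr@pAuc * 40))

  ## reproducibility of the permuted statistic sequences
  pr2 <- permutationTest(modelSpec("linear"), X[tr, ], Y[tr, , drop = FALSE],
                         X[te, ], Y[te, 1], "g1", nPerm = 40, seed = 5)
  expect_identical(pr@r2Perm, pr2@r2Perm)

  ## smoothed convention shifts to (count+1)/(n+1)
  ps <- permutationTest(modelSpec("linear"), X[tr, ], Y[tr, , drop = FALSE],
                        X[te, ], Y[te, 1], "g1", nPerm = 40, seed = 5,
                        smoothed = TRUE)
  expect_equal(ps@pR2, 1 / 41)

  ## a permutation-invariant model (zero-variance predictor) gives p = 1
  Xc <- matrix(0, n, 1, dimnames = list(NULL, "f1"))
  pc <- suppressWarnings(
    permutationTest(modelSpec("linear"), Xc[tr, , drop = FALSE],
                    Y[tr, , drop = FALSE], Xc[te, , drop = FALSE],
                    Y[te, 1], "g1", nPerm = 20, seed = 1))
  expect_equal(pc@pR2, 1)

  expect_error(permutationTest(modelSpec("linear"), X[tr, ],
                               Y[tr, , drop = FALSE], X[te, ], Y[te, 1],
                               "g1", nPerm = 0), "nPerm")
  expect_error(permutationTest(modelSpec("linear"), X[tr, ],
                               Y[tr, , drop = FALSE], X[te, ], Y[te, 1],
                               "nope", nPerm = 5), "not found")
})

test_that("null labels give roughly uniform permutation p-values", {
  set.seed(77)
  ps <- replicate(60, {
    nd <- nullDataset(32, 3, 1, seed = sample.int(1e6, 1))
    X <- featureValues(nd$imaging); Y <- featureValues(nd$omics)
    tr <- 1:24; te <- 25:32
    permutationTest(modelSpec("linear"), X[tr, ], Y[tr, , drop = FALSE],
                    X[te, ], Y[te, 1], colnames(Y)[1],
                    nPerm = 30, seed = sample.int(1e6, 1))@pR2
  })
  ## mean of U(0,1) draws, 3 sigma band: 0.5 +/- 3*sqrt(1/12/60)
  expect_lt(abs(mean(ps) - 0.5), 3 * sqrt(1 / 12 / 60))
})

test_that("validation permuts files and summaries stay consistent", {
  set.seed(30)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  Y <- matrix(X[, 2] + rnorm(20, sd = 0.2), ncol = 1,
              dimnames = list(NULL, "gA"))
  pr <- permutationTest(modelSpec("linear"), X[1:15, ], Y[1:15, , drop = FALSE],
                        X[16:20, ], Y[16:20, 1], "gA", nPerm = 12, seed = 2)
  dir <- tempfile(); dir.create(dir)
  f <- writeValidationPermuts(pr, dir)
  expect_true(file.exists(file.path(dir, "validation_permuts_gA.txt")))
  tab <- read.delim(file.path(dir, "validation_permuts_gA.txt"))
  expect_equal(nrow(tab), 12L)
  expect_named(tab, c("permutation", "AUC_perm", "R2_perm"))

  sm <- permutationSummary(list(gA = pr))
  expect_equal(sm$label, "gA")
  expect_equal(sm$p_R2, pr@pR2)
  expect_equal(significantLabels(data.frame(label = c("a", "b"),
                                            p_R2 = c(0.01, 0.3))), "a")
  expect_equal(nrow(permutationSummary(list())), 0L)
})
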