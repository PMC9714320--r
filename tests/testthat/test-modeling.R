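linData <- function(n = 30, p = 4, q = 3, noise = 0, seed = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  B <- matrix(rnorm(p * q), p, q)
  Y <- X %*% B + matrix(rnorm(n * q, sd = noise), n, q)
  colnames(Y) <- paste0("y", 1:q)
  list(X = X, Y = Y, B = B)
}

test_that("ordinary least squares fits noiseless data exactly", {
  d <- linData()
  m <- trainModel(modelSpec("linear"), d$X, d$Y)
  pred <- predict(m, d$X, preNormalized = TRUE)
  expect_lt(max(abs(pred - d$Y)), 1e-8)
  expect_equal(dim(m@coefMatrix), c(3L, 4L))

  ## single-feature coefficients agree with the normal equations
  x4 <- matrix(c(0, 1, 2, 4), 4, 1, dimnames = list(NULL, "f1"))
  y4 <- matrix(c(1, 3, 4, 9), 4, 1, dimnames = list(NULL, "y1"))
  slope <- sum((x4 - mean(x4)) * (y4 - mean(y4))) / sum((x4 - mean(x4))^2)
  icept <- mean(y4) - slope * mean(x4)
  m1 <- trainModel(modelSpec("linear", cvFolds = 2), x4, y4)
  expect_equal(unname(m1@coefMatrix[1, 1]), slope, tolerance = 1e-10)
  expect_equal(unname(m1@intercepts[1]), icept, tolerance = 1e-10)
  ## exported weight table carries the same slope
  w <- exportFeatureWeights(m1)
  expect_equal(w$weight, slope, tolerance = 1e-10)
})

test_that("regularized families shrink, agree at the L1 limit, and couple tasks", {
  d <- linData(noise = 0.1)
  ## infinite-penalty limit: all coefficients zero, prediction = label mean
  big <- trainModel(modelSpec("lasso", params = list(alpha = 1e6)), d$X, d$Y)
  expect_equal(max(abs(big@coefMatrix)), 0)
  pred <- predict(big, d$X, preNormalized = TRUE)
  expect_equal(unname(pred[1, ]), unname(colMeans(d$Y)), tolerance = 1e-8)

  ## elastic net at l1_ratio = 1 equals the lasso
  la <- trainModel(modelSpec("lasso", params = list(alpha = 0.1)), d$X, d$Y)
  en <- trainModel(modelSpec("elastic_net",
                             params = list(alpha = 0.1, l1_ratio = 1)),
                   d$X, d$Y)
  expect_equal(la@coefMatrix, en@coefMatrix, tolerance = 1e-6)

  ## multi-task group sparsity: a feature dropped for one label is dropped
  ## for all labels (here: a planted pure-noise feature)
  set.seed(33)
  Xn <- cbind(d$X, f5 = rnorm(nrow(d$X)))
  mt <- trainModel(modelSpec("multi_task_lasso", params = list(alpha = 0.5)),
                   Xn, d$Y)
  zero <- colSums(abs(mt@coefMatrix)) == 0
  expect_true(zero["f5"])    # noise feature zeroed jointly across all labels
  expect_true(all(mt@coefMatrix[, "f5"] == 0))
  expect_error(trainModel(modelSpec("multi_task_lasso"), d$X,
                          d$Y[, 1, drop = FALSE]),
               "at least 2 label")
})

test_that("decision trees interpolate distinct rows and report importances", {
  d <- linData(n = 20, noise = 0)
  m <- trainModel(modelSpec("decision_tree"), d$X, d$Y)
  pred <- predict(m, d$X, preNormalized = TRUE)
  expect_lt(max(abs(pred - d$Y)), 1e-9)
  imp <- m@coefMatrix
  expect_true(all(imp >= 0))
  expect_equal(unname(rowSums(imp)), rep(1, 3), tolerance = 1e-12)

  ## a feature irrelevant to the label never splits -> importance 0
  set.seed(5)
  X <- cbind(f1 = rnorm(60), f2 = rnorm(60))
  Y <- matrix(sign(X[, 1]), ncol = 1, dimnames = list(NULL, "y1"))
  t1 <- trainModel(modelSpec("decision_tree",
                             params = list(max_depth = 2)), X, Y)
  expect_equal(unname(t1@coefMatrix[1, "f2"]), 0)
  expect_equal(unname(t1@coefMatrix[1, "f1"]), 1)
})

test_that("cross-validation partitions rows and scores by negative MSE", {
  d <- linData(n = 10, noise = 0.5)
  sp <- modelSpec("linear", cvFolds = 2)
  sc <- crossValidate(sp, d$X, d$Y)
  expect_length(sc, 2L)
  expect_true(all(sc <= 0))
  expect_error(crossValidate(modelSpec("linear", cvFolds = 11), d$X, d$Y),
               "exceeds")
  ## determinism: identical seed and data give identical models
  d2 <- linData(n = 40, noise = 0.3)
  a <- trainModel(modelSpec("decision_tree", seed = 3), d2$X, d2$Y)
  b <- trainModel(modelSpec("decision_tree", seed = 3), d2$X, d2$Y)
  expect_identical(a@coefMatrix, b@coefMatrix)
  expect_identical(a@cvScores, b@cvScores)
})

test_that("grid search enumerates the candidate product and picks the winner", {
  d <- linData(n = 40, noise = 0.05)
  single <- trainModel(modelSpec("lasso", params = list(alpha = 0.2),
                                 grid = list(alpha = 0.2),
                                 gridSearch = TRUE), d$X, d$Y)
  plain <- trainModel(modelSpec("lasso", params = list(alpha = 0.2)),
                      d$X, d$Y)
  expect_equal(single@coefMatrix, plain@coefMatrix, tolerance = 1e-10)

  g <- trainModel(modelSpec("elastic_net",
                            grid = list(alpha = c(1e-6, 1e6),
                                        l1_ratio = c(0.2, 0.9)),
                            gridSearch = TRUE), d$X, d$Y)
  expect_equal(nrow(g@gridLog), 4L)            # 2 x 2 candidates evaluated
  expect_equal(g@chosenParams$alpha, 1e-6)     # tiny penalty wins on linear data
  expect_error(trainModel(modelSpec("lasso", grid = list(alpha = numeric()),
                                    gridSearch = TRUE), d$X, d$Y),
               "empty candidate")
})

test_that("models survive a save/load round trip bit for bit", {
  d <- linData(n = 25, noise = 0.2)
  m <- trainModel(modelSpec("decision_tree", seed = 8), d$X, d$Y)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(predict(back, d$X, preNormalized = TRUE),
                   predict(m, d$X, preNormalized = TRUE))
  expect_identical(back@cvScores, m@cvScores)
  expect_error(loadModel(tempfile()), "not found")
  junk <- tempfile(); saveRDS(list(a = 1), junk)
  expect_error(loadModel(junk), "not a RadioLink model")

  expect_error(predict(m, d$X[, 1:2], preNormalized = TRUE),
               "missing feature column.*f3")
})
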