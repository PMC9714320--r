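test_that("CSV loading validates shape, duplicates and numeric cells", {
  path <- writeTempCSV(data.frame(Sample = c("S1", "S2", "S3"),
                                  A = c(1, 2, 3), B = c(4.5, 5.5, 6.5)))
  ft <- loadFeatureTable(path, "imaging")
  expect_equal(dim(ft), c(3L, 2L))
  expect_equal(sampleIDs(ft), c("S1", "S2", "S3"))
  expect_equal(featureNames(ft), c("A", "B"))

  dup <- writeTempCSV(data.frame(Sample = c("S1", "S1"), A = 1:2))
  expect_error(loadFeatureTable(dup, "imaging"), "duplicate sample ID 'S1'")

  bad <- writeTempCSV(data.frame(Sample = c("S1", "S2"), A = c("1", "oops")))
  expect_error(loadFeatureTable(bad, "imaging"), "row 2, column 'A'")

  empty <- writeTempCSV(data.frame(Sample = character(), A = numeric()))
  expect_error(loadFeatureTable(empty, "imaging"), "empty")
  expect_error(loadFeatureTable(tempfile(), "imaging"), "not found")
})

test_that("feature tables survive a write/load round trip", {
  ft <- randomTable(5, 3, "omics", seed = 11)
  path <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- loadFeatureTable(path, "omics")
  expect_equal(featureValues(back), featureValues(ft), tolerance = 1e-12)
})

test_that("sample matching intersects, preserves order and is idempotent", {
  a <- makeTable(matrix(1:8, 4, 2), ids = c("A", "B", "C", "D"))
  b <- makeTable(matrix(1:6, 3, 2), ids = c("C", "B", "E"), role = "omics")
  m <- matchSamples(a, b)
  expect_equal(sampleIDs(m$a), c("B", "C"))
  expect_identical(sampleIDs(m$a), sampleIDs(m$b))

  ## same ID set, shuffled rows: order matched, nothing lost
  b2 <- featureTable(featureValues(a)[c(3, 1, 4, 2), ], role = "omics")
  m2 <- matchSamples(a, b2)
  expect_equal(nrow(featureValues(m2$a)), 4L)
  expect_identical(sampleIDs(m2$a), sampleIDs(m2$b))

  m3 <- matchSamples(m$a, m$b)
  expect_identical(featureValues(m3$a), featureValues(m$a))

  only1 <- makeTable(matrix(1, 1, 1), ids = "A")
  only2 <- makeTable(matrix(1, 1, 1), ids = "B", role = "omics")
  expect_error(matchSamples(only1, only2), "zero common samples")
})

test_that("omics screening keeps exactly the qualifying features", {
  set.seed(3)
  m <- matrix(runif(50, 0, 4), 5, 10)      # nothing reaches 5
  m[, c(2, 4, 6, 8, 10)] <- matrix(runif(25, 5, 20), 5, 5)
  ft <- makeTable(m, "omics")
  out <- screenOmics(ft, minValue = 5, minSamples = 3)
  expect_setequal(featureNames(out), sprintf("F%d", c(2, 4, 6, 8, 10)))
  expect_equal(sampleIDs(out), sampleIDs(ft))

  allZero <- makeTable(cbind(A = m[, 2], Z = 0), "omics")
  expect_equal(featureNames(screenOmics(allZero, 5, 3)), "A")
  expect_error(screenOmics(ft, 5, minSamples = 6), "exceeds")

  ## invariant: result independent of sample row order
  perm <- featureValues(ft)[c(4, 2, 5, 1, 3), ]
  out2 <- screenOmics(featureTable(perm, "omics"), 5, 3)
  expect_setequal(featureNames(out2), featureNames(out))
})

test_that("train/test split partitions deterministically", {
  x <- randomTable(10, 3, seed = 5)
  y <- makeTable(featureValues(randomTable(10, 2, seed = 6)), "omics")
  sp <- splitTrainTest(x, y, trainSize = 0.8, testSize = 0.2, seed = 99)
  expect_length(sp$testIDs, 2L)
  expect_length(sp$trainIDs, 8L)
  expect_length(intersect(sp$trainIDs, sp$testIDs), 0L)
  expect_setequal(c(sp$trainIDs, sp$testIDs), sampleIDs(x))
  expect_identical(sp$trainIDs,
                   splitTrainTest(x, y, 0.8, 0.2, seed = 99)$trainIDs)
  ## same split applied to both tables
  expect_identical(sampleIDs(sp$train$x), sampleIDs(sp$train$y))

  x100 <- randomTable(100, 2, seed = 7)
  y100 <- makeTable(featureValues(randomTable(100, 2, seed = 8)), "omics")
  expect_length(splitTrainTest(x100, y100, 0.9, 0.1, 1)$testIDs, 10L)
  expect_error(splitTrainTest(x, y, 0.8, 1.2, 1), "fractions")
  expect_error(splitTrainTest(x, y, 0.9, 0.2, 1), "exceed")
})

test_that("the three scalers normalize and invert as specified", {
  ft <- makeTable(cbind(a = c(2, 4, 6), b = c(-2, 1, 4)))
  mm <- applyScaler(ft, fitScaler(ft, "min_max"))
  expect_equal(featureValues(mm)[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  ma <- applyScaler(ft, fitScaler(ft, "max_abs"))
  expect_equal(featureValues(ma)[, "b"], c(-0.5, 0.25, 1), ignore_attr = TRUE)

  big <- randomTable(40, 6, seed = 20)
  ss <- fitScaler(big, "stand_scaler")
  z <- featureValues(applyScaler(big, ss))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  popsd <- apply(z, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(popsd - 1)), 1e-9)

  for (meth in c("stand_scaler", "min_max", "max_abs")) {
    p <- fitScaler(big, meth)
    back <- inverseScaler(applyScaler(big, p), p)
    expect_lt(max(abs(featureValues(back) - featureValues(big))), 1e-9)
  }

  const <- makeTable(cbind(c = c(3, 3, 3), d = 1:3))
  expect_warning(out <- applyScaler(const, fitScaler(const, "stand_scaler")),
                 "constant")
  expect_equal(featureValues(out)[, "c"], rep(0, 3), ignore_attr = TRUE)

  other <- makeTable(matrix(1:6, 3, 2), feats = c("x", "y"))
  expect_error(applyScaler(other, fitScaler(ft, "min_max")),
               "feature names differ")
})
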