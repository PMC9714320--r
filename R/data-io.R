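#' Construct a FeatureTable from a numeric matrix
#'
#' @param values numeric matrix, samples in rows (row names = sample IDs),
#'   features in columns (column names = feature names).
#' @param role \code{"imaging"} or \code{"omics"}.
#' @return a validated \code{FeatureTable}
#' @export
featureTable <- function(values, role = c("imaging", "omics")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("FeatureTable", values = values, role = role)
}

#' Load a feature table from CSV
#'
#' Expects samples in rows: the first column holds sample identifiers and
#' the header row holds feature names. Every remaining cell must parse as a
#' finite number; duplicates and missing values are rejected rather than
#' silently repaired.
#'
#' @param path CSV file path.
#' @param role \code{"imaging"} or \code{"omics"}.
#' @return a \code{FeatureTable}, with row and column order preserved from
#'   the file.
#' @export
loadFeatureTable <- function(path, role = c("imaging", "omics")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop(sprintf("empty table in %s", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample ID '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  feat <- colnames(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(feat),
              dimnames = list(ids, feat))
  for (j in seq_along(feat)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column '%s' in %s",
                   bad[1L], feat[j], path))
    m[, j] <- num
  }
  featureTable(m, role)
}

#' Write a FeatureTable back to CSV in the same dialect it is read in
#' @param x a \code{FeatureTable}
#' @param path output path
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "FeatureTable"))
  df <- data.frame(Sample = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match two feature tables on their common samples
#'
#' Restricts both tables to the intersection of their sample IDs (exact,
#' case-sensitive string match) and puts the rows in an identical order.
#'
#' @param a,b \code{FeatureTable}s
#' @return list with elements \code{a} and \code{b}, sample-matched
#' @export
matchSamples <- function(a, b) {
  stopifnot(is(a, "FeatureTable"), is(b, "FeatureTable"))
  common <- intersect(sampleIDs(a), sampleIDs(b))
  if (length(common) == 0L) stop("zero common samples between the two tables")
  list(a = featureTable(a@values[common, , drop = FALSE], a@role),
       b = featureTable(b@values[common, , drop = FALSE], b@role))
}

#' Screen omics features by a minimum-expression rule
#'
#' Retains features whose value is at least \code{minValue} in at least
#' \code{minSamples} samples (e.g. FPKM >= 5 in >= 30 patients, the
#' screening rule used for expression labels).
#'
#' @param x an omics \code{FeatureTable}
#' @param minValue expression floor
#' @param minSamples minimum number of samples at or above the floor
#' @return the screened \code{FeatureTable} (samples unchanged)
#' @export
screenOmics <- function(x, minValue = 5, minSamples = 30) {
  stopifnot(is(x, "FeatureTable"))
  if (x@role != "omics") stop("screenOmics applies to omics tables only")
  if (minSamples > nrow(x@values))
    stop(sprintf("minSamples (%d) exceeds the %d available samples",
                 minSamples, nrow(x@values)))
  keep <- colSums(x@values >= minValue) >= minSamples
  if (!any(keep)) stop("no omics features pass the screen")
  featureTable(x@values[, keep, drop = FALSE], "omics")
}

#' Split two sample-matched tables into shared train and test partitions
#'
#' Samples are drawn uniformly at random without replacement (no
#' stratification); the identical partition is applied to both tables so
#' data and labels stay aligned. The test set size is
#' \code{round(testSize * n)}.
#'
#' @param x,y sample-matched \code{FeatureTable}s
#' @param trainSize,testSize fractions in (0,1), summing to at most 1
#' @param seed integer seed; the partition is deterministic given the seed
#' @return list with \code{train} and \code{test}, each a list of the two
#'   restricted tables, plus \code{trainIDs}/\code{testIDs}
#' @export
splitTrainTest <- function(x, y, trainSize = 0.9, testSize = 0.1, seed = 1L) {
  stopifnot(is(x, "FeatureTable"), is(y, "FeatureTable"))
  if (!identical(sampleIDs(x), sampleIDs(y)))
    stop("tables must be sample-matched before splitting")
  if (trainSize <= 0 || trainSize >= 1 || testSize <= 0 || testSize >= 1)
    stop("train and test fractions must lie in (0,1)")
  if (trainSize + testSize > 1 + 1e-12)
    stop("trainSize + testSize must not exceed 1")
  n <- nrow(x@values)
  nTest <- round(testSize * n)
  nTrain <- if (abs(trainSize + testSize - 1) < 1e-12) n - nTest
            else round(trainSize * n)
  if (nTest < 1L || nTrain < 1L)
    stop("split leaves an empty train or test set")
  idx <- withSeed(seed, sample.int(n))
  testIdx <- sort(idx[seq_len(nTest)])
  trainIdx <- sort(idx[nTest + seq_len(nTrain)])
  ids <- sampleIDs(x)
  sub <- function(t, i) featureTable(t@values[i, , drop = FALSE], t@role)
  list(train = list(x = sub(x, trainIdx), y = sub(y, trainIdx)),
       test = list(x = sub(x, testIdx), y = sub(y, testIdx)),
       trainIDs = ids[trainIdx], testIDs = ids[testIdx])
}

## Evaluate an expression under a temporary, restored RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## population (ddof = 0) standard deviation -- the convention used
## throughout so that the R2 = 1 - v^2 identity is exact
popSD <- function(x) sqrt(mean((x - mean(x))^2))

#' Fit normalization parameters on a feature table
#'
#' @param x a \code{FeatureTable} or numeric matrix
#' @param method \code{"stand_scaler"} (mean 0, unit population SD),
#'   \code{"min_max"} (map to [0,1]) or \code{"max_abs"} (divide by max |x|)
#' @return a \code{ScalerParams}
#' @export
fitScaler <- function(x, method = c("stand_scaler", "min_max", "max_abs")) {
  method <- match.arg(method)
  m <- if (is(x, "FeatureTable")) x@values else as.matrix(x)
  center <- switch(method,
    stand_scaler = colMeans(m),
    min_max = apply(m, 2L, min),
    max_abs = rep(0, ncol(m)))
  scale <- switch(method,
    stand_scaler = apply(m, 2L, popSD),
    min_max = apply(m, 2L, max) - apply(m, 2L, min),
    max_abs = apply(m, 2L, function(v) max(abs(v))))
  names(center) <- names(scale) <- colnames(m)
  new("ScalerParams", method = method, center = center, scale = scale,
      featureNames = colnames(m))
}

#' Apply fitted normalization parameters
#'
#' Constant features (zero scale statistic) map to 0 with a warning.
#'
#' @param x a \code{FeatureTable} or matrix with the same feature names the
#'   scaler was fitted on
#' @param params a \code{ScalerParams}
#' @return object of the same kind as \code{x}, normalized
#' @export
applyScaler <- function(x, params) {
  stopifnot(is(params, "ScalerParams"))
  isFT <- is(x, "FeatureTable")
  m <- if (isFT) x@values else as.matrix(x)
  if (!identical(colnames(m), params@featureNames))
    stop("feature names differ from those the scaler was fitted on")
  sc <- params@scale
  const <- sc == 0
  if (any(const)) {
    warning(sprintf("constant feature(s) mapped to 0: %s",
                    paste(params@featureNames[const], collapse = ", ")))
    sc[const] <- 1  # (x - center)/1 = 0 for a constant column
  }
  out <- sweep(sweep(m, 2L, params@center, "-"), 2L, sc, "/")
  if (isFT) featureTable(out, x@role) else out
}

#' Invert a normalization
#' @param x normalized \code{FeatureTable} or matrix
#' @param params the \code{ScalerParams} used for the forward transform
#' @return de-normalized object (constant features return their center)
#' @export
inverseScaler <- function(x, params) {
  stopifnot(is(params, "ScalerParams"))
  isFT <- is(x, "FeatureTable")
  m <- if (isFT) x@values else as.matrix(x)
  if (!identical(colnames(m), params@featureNames))
    stop("feature names differ from those the scaler was fitted on")
  sc <- params@scale
  sc[sc == 0] <- 1
  out <- sweep(sweep(m, 2L, sc, "*"), 2L, params@center, "+")
  if (isFT) featureTable(out, x@role) else out
}
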