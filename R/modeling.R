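#' Frozen default hyperparameters per model family
#'
#' Defaults mirror the reference implementations the families are named
#' after: regularized families use penalty strength \code{alpha = 1} with
#' \code{l1_ratio = 0.5} for the elastic nets, and trees grow to purity
#' (no cost-complexity pruning, minimum split size 2, minimum leaf size 1).
#' Unspecified parameters in a \code{ModelSpec} fall back to this table.
#'
#' @param modelType one of the six supported families
#' @return named list of default hyperparameters
#' @export
modelDefaults <- function(modelType) {
  tab <- list(
    linear = list(),
    lasso = list(alpha = 1.0, tol = 1e-7, max_iter = 1e5),
    elastic_net = list(alpha = 1.0, l1_ratio = 0.5, tol = 1e-7, max_iter = 1e5),
    multi_task_lasso = list(alpha = 1.0, tol = 1e-7, max_iter = 1e5),
    multi_task_elastic_net = list(alpha = 1.0, l1_ratio = 0.5, tol = 1e-7,
                                  max_iter = 1e5),
    decision_tree = list(max_depth = 30, min_samples_split = 2,
                         min_samples_leaf = 1, cp = 0))
  if (!modelType %in% names(tab)) stop(sprintf("unknown model type '%s'", modelType))
  tab[[modelType]]
}

#' Construct a ModelSpec
#'
#' @param modelType model family; see \code{\link{modelDefaults}}
#' @param params named list of hyperparameters (missing ones take defaults)
#' @param grid named list of candidate vectors for grid search
#' @param gridSearch logical; exhaustively search \code{grid} by CV
#' @param cvFolds number of cross-validation folds (default 2)
#' @param seed integer seed
#' @return a \code{ModelSpec}
#' @export
modelSpec <- function(modelType = "decision_tree", params = list(),
                      grid = list(), gridSearch = FALSE, cvFolds = 2,
                      seed = 1L) {
  new("ModelSpec", modelType = modelType, params = params, grid = grid,
      gridSearch = gridSearch, cvFolds = cvFolds, seed = seed)
}

.resolveParams <- function(spec, override = NULL) {
  p <- utils::modifyList(modelDefaults(spec@modelType), spec@params)
  if (!is.null(override)) p <- utils::modifyList(p, override)
  p
}

.isMultiTask <- function(type) type %in% c("multi_task_lasso",
                                           "multi_task_elastic_net")

## Core fit: returns a light-weight list holding coefficients (linear
## families) or rpart objects (trees), independent of scalers and CV.
.fitCore <- function(spec, params, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) == 0L) stop("cannot train a model with zero features")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("NaNs in training data")
  type <- spec@modelType
  if (.isMultiTask(type) && ncol(Y) < 2L)
    stop("multi-task models require at least 2 label columns")
  fn <- colnames(X); ln <- colnames(Y)
  if (is.null(fn)) fn <- paste0("x", seq_len(ncol(X)))
  if (is.null(ln)) ln <- paste0("y", seq_len(ncol(Y)))
  core <- list(type = type, featureNames = fn, labelNames = ln, trees = NULL)
  if (type == "linear") {
    fit <- stats::lm.fit(cbind(1, X), Y)
    cf <- as.matrix(fit$coefficients)
    cf[is.na(cf)] <- 0          # rank-deficient columns contribute nothing
    core$intercepts <- cf[1L, ]
    core$coef <- t(cf[-1L, , drop = FALSE])
  } else if (type %in% c("lasso", "elastic_net")) {
    l1 <- if (type == "lasso") 1 else params$l1_ratio
    cmat <- matrix(0, ncol(Y), ncol(X))
    ic <- numeric(ncol(Y))
    Xg <- X; pad <- ncol(X) == 1L
    if (pad) Xg <- cbind(X, `..pad..` = 0)
    for (j in seq_len(ncol(Y))) {
      fit <- glmnet::glmnet(Xg, Y[, j], family = "gaussian", alpha = l1,
                            lambda = params$alpha, standardize = FALSE,
                            thresh = params$tol, maxit = params$max_iter)
      b <- as.matrix(stats::coef(fit, s = params$alpha))
      ic[j] <- b[1L]
      cmat[j, ] <- b[1L + seq_len(ncol(X))]
    }
    core$coef <- cmat; core$intercepts <- ic
  } else if (.isMultiTask(type)) {
    l1 <- if (type == "multi_task_lasso") 1 else params$l1_ratio
    fit <- glmnet::glmnet(X, Y, family = "mgaussian", alpha = l1,
                          lambda = params$alpha, standardize = FALSE,
                          standardize.response = FALSE,
                          thresh = params$tol, maxit = params$max_iter)
    bl <- stats::coef(fit, s = params$alpha)
    cmat <- matrix(0, ncol(Y), ncol(X))
    ic <- numeric(ncol(Y))
    for (j in seq_len(ncol(Y))) {
      b <- as.matrix(bl[[j]])
      ic[j] <- b[1L]
      cmat[j, ] <- b[-1L]
    }
    core$coef <- cmat; core$intercepts <- ic
  } else { # decision_tree
    safe <- paste0("f", seq_len(ncol(X)))
    df <- as.data.frame(X); colnames(df) <- safe
    ctrl <- rpart::rpart.control(
      cp = params$cp, minsplit = params$min_samples_split,
      minbucket = params$min_samples_leaf,
      maxdepth = min(params$max_depth, 30), xval = 0,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
    trees <- vector("list", ncol(Y))
    imp <- matrix(0, ncol(Y), ncol(X))
    for (j in seq_len(ncol(Y))) {
      df$.y <- Y[, j]
      trees[[j]] <- withSeed(spec@seed, rpart::rpart(.y ~ ., data = df,
                                                     method = "anova",
                                                     control = ctrl))
      imp[j, ] <- .treeImportance(trees[[j]], safe)
    }
    core$trees <- trees
    core$coef <- imp                   # normalized importances per label
    core$intercepts <- rep(0, ncol(Y))
    core$safeNames <- safe
  }
  dimnames(core$coef) <- list(ln, fn)
  names(core$intercepts) <- ln
  core
}

## Importance from primary splits only (competitors and surrogates are
## disabled at fit time), normalized to sum 1; all-zero if the tree never
## splits.
.treeImportance <- function(tree, featNames) {
  imp <- stats::setNames(numeric(length(featNames)), featNames)
  fr <- tree$frame
  sp <- tree$splits
  if (!is.null(sp) && nrow(sp) > 0) {
    vars <- fr$var[fr$var != "<leaf>"]
    for (i in seq_along(vars))
      imp[as.character(vars[i])] <- imp[as.character(vars[i])] + sp[i, "improve"]
  }
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  unname(imp)
}

.predictCore <- function(core, Xnew) {
  Xnew <- as.matrix(Xnew)
  miss <- setdiff(core$featureNames, colnames(Xnew))
  if (length(miss))
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  Xnew <- Xnew[, core$featureNames, drop = FALSE]
  if (core$type == "decision_tree") {
    df <- as.data.frame(Xnew); colnames(df) <- core$safeNames
    out <- vapply(core$trees, function(t) unname(stats::predict(t, df)),
                  numeric(nrow(Xnew)))
    out <- matrix(out, nrow = nrow(Xnew))
  } else {
    out <- Xnew %*% t(core$coef) +
      matrix(core$intercepts, nrow(Xnew), length(core$intercepts), byrow = TRUE)
  }
  dimnames(out) <- list(rownames(Xnew), core$labelNames)
  out
}

#' K-fold cross-validation scores (negative MSE per fold)
#'
#' Folds are contiguous blocks by default (set \code{shuffle = TRUE} for a
#' seeded random assignment); every row falls in exactly one fold. The fold
#' score is the negative mean squared error over all labels of the held-out
#' block.
#'
#' @param spec a \code{ModelSpec}
#' @param X,Y row-aligned numeric matrices (already normalized)
#' @param shuffle randomize fold membership (seeded by \code{spec@seed})
#' @param paramsOverride internal: hyperparameter override for grid search
#' @return numeric vector of per-fold negative MSE (all <= 0)
#' @export
crossValidate <- function(spec, X, Y, shuffle = FALSE, paramsOverride = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  K <- spec@cvFolds
  n <- nrow(X)
  if (K < 2) stop("cvFolds must be >= 2")
  if (K > n) stop(sprintf("cvFolds (%d) exceeds the %d training rows", K, n))
  idx <- seq_len(n)
  if (shuffle) idx <- withSeed(spec@seed, sample.int(n))
  foldId <- cut(seq_len(n), breaks = K, labels = FALSE)[order(idx)]
  params <- .resolveParams(spec, paramsOverride)
  vapply(seq_len(K), function(k) {
    tr <- foldId != k
    core <- .fitCore(spec, params, X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    pred <- .predictCore(core, X[!tr, , drop = FALSE])
    -mean((Y[!tr, , drop = FALSE] - pred)^2)
  }, numeric(1L))
}

#' Train a model (with optional exhaustive grid search)
#'
#' Fits the requested family on the normalized training matrices, runs
#' K-fold cross-validation, and -- when \code{spec@gridSearch} is TRUE and
#' a grid is given -- exhaustively evaluates the candidate product by mean
#' CV negative MSE, refitting the winner (ties broken by grid order) on the
#' full training set.
#'
#' @param spec a \code{ModelSpec}
#' @param X,Y row-aligned numeric matrices in model (normalized) space
#' @param scalerX,scalerY optional fitted \code{ScalerParams} recorded for
#'   later prediction on raw inputs
#' @param scalerFit \code{"independent"} (default: refit the scaler on new
#'   data at prediction time, matching train/test normalization
#'   independence) or \code{"train_only"} (re-apply training statistics)
#' @param cv run cross-validation (skipped inside permutation refits)
#' @return a \code{TrainedModel}
#' @export
trainModel <- function(spec, X, Y, scalerX = NULL, scalerY = NULL,
                       scalerFit = "independent", cv = TRUE) {
  stopifnot(is(spec, "ModelSpec"))
  gridLog <- NULL
  chosen <- .resolveParams(spec)
  if (spec@gridSearch && length(spec@grid)) {
    for (nm in names(spec@grid))
      if (length(spec@grid[[nm]]) == 0L)
        stop(sprintf("empty candidate list for grid parameter '%s'", nm))
    combos <- expand.grid(spec@grid, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    scores <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      ov <- as.list(combos[i, , drop = FALSE])
      scores[i] <- mean(crossValidate(spec, X, Y, paramsOverride = ov))
    }
    best <- which.max(scores)           # ties -> first in grid order
    chosen <- .resolveParams(spec, as.list(combos[best, , drop = FALSE]))
    gridLog <- cbind(combos, meanNegMSE = scores)
  } else if (spec@gridSearch) {
    stop("gridSearch = TRUE requires a non-empty grid")
  }
  cvScores <- if (cv) crossValidate(spec, X, Y,
                                    paramsOverride = chosen) else numeric()
  core <- .fitCore(spec, chosen, X, Y)
  new("TrainedModel", spec = spec, fits = core[c("trees", "safeNames")],
      coefMatrix = core$coef, intercepts = core$intercepts,
      featureNames = core$featureNames, labelNames = core$labelNames,
      scalerX = scalerX, scalerY = scalerY, scalerFit = scalerFit,
      cvScores = cvScores, chosenParams = chosen,
      gridLog = gridLog)
}

.coreOf <- function(model) {
  list(type = model@spec@modelType, featureNames = model@featureNames,
       labelNames = model@labelNames, coef = model@coefMatrix,
       intercepts = model@intercepts, trees = model@fits$trees,
       safeNames = model@fits$safeNames)
}

#' Predict labels for new data
#'
#' \code{newdata} is given in original units unless
#' \code{preNormalized = TRUE}; depending on the model's scaler-fit policy
#' the stored normalization method is either refitted on the new data
#' (\code{"independent"}, the default pipeline behavior) or the stored
#' training statistics are re-applied (\code{"train_only"}). Predictions
#' are returned in normalized label space.
#'
#' @param object a \code{TrainedModel}
#' @param newdata matrix or \code{FeatureTable} containing the model's
#'   feature columns
#' @param preNormalized set TRUE when \code{newdata} is already in model space
#' @return matrix n_new x n_labels of continuous predictions
#' @export
setMethod("predict", "TrainedModel", function(object, newdata,
                                              preNormalized = FALSE) {
  m <- if (is(newdata, "FeatureTable")) newdata@values else as.matrix(newdata)
  if (!preNormalized && !is.null(object@scalerX)) {
    miss <- setdiff(object@featureNames, colnames(m))
    if (length(miss))
      stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
    m <- m[, object@scalerX@featureNames, drop = FALSE]
    m <- if (identical(object@scalerFit, "train_only"))
      applyScaler(m, object@scalerX)
    else
      applyScaler(m, fitScaler(m, object@scalerX@method))
  }
  .predictCore(.coreOf(object), m)
})

#' Persist a trained model to disk
#'
#' The artifact is an RDS container with a versioned metadata header that
#' is checked at load; a reloaded model reproduces identical predictions.
#'
#' @param model a \code{TrainedModel}
#' @param path destination file
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  saveRDS(list(format = "RadioLink-model", version = 1L,
               modelType = model@spec@modelType, model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel}: the restored \code{TrainedModel}
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("corrupt model file: %s", path)))
  if (!is.list(obj) || !identical(obj$format, "RadioLink-model"))
    stop("not a RadioLink model file")
  if (!identical(obj$version, 1L))
    stop(sprintf("unsupported model file version: %s", obj$version))
  obj$model
}
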