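#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' FeatureTable: a samples-by-features numeric matrix with a role
#'
#' The central input container: rows are tumor samples, columns are either
#' imaging (radiomic) features or omics features (e.g. normalized gene
#' expression). Sample identifiers are the row names and feature names the
#' column names; both must be unique and all entries finite.
#'
#' @slot values numeric matrix (n_samples x n_features) with sample IDs as
#'   row names and feature names as column names.
#' @slot role one of \code{"imaging"} or \code{"omics"}.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", role = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
    if (nrow(v) == 0L || ncol(v) == 0L) msg <- c(msg, "table is empty")
    if (is.null(rownames(v))) msg <- c(msg, "sample IDs (row names) required")
    if (is.null(colnames(v))) msg <- c(msg, "feature names (column names) required")
    if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicate sample ID: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicate feature name: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
    if (is.numeric(v) && length(v) && !all(is.finite(v)))
      msg <- c(msg, "all entries must be finite (no NA/NaN/Inf)")
    if (length(object@role) != 1L || !object@role %in% c("imaging", "omics"))
      msg <- c(msg, "role must be 'imaging' or 'omics'")
    if (length(msg)) msg else TRUE
  })

#' ScalerParams: fitted per-feature normalization statistics
#'
#' Stores the statistics of one of three scalers so the identical affine
#' transform can be re-applied or inverted. \code{stand_scaler} centers by
#' the mean and divides by the population standard deviation; \code{min_max}
#' maps each feature to [0,1]; \code{max_abs} divides by the maximum
#' absolute value.
#'
#' @slot method one of \code{"stand_scaler"}, \code{"min_max"}, \code{"max_abs"}.
#' @slot center per-feature offset subtracted before scaling.
#' @slot scale per-feature divisor (nonnegative; 0 marks a constant feature).
#' @slot featureNames feature names the parameters were fitted on.
#' @exportClass ScalerParams
setClass("ScalerParams",
  representation(method = "character", center = "numeric", scale = "numeric",
                 featureNames = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("stand_scaler", "min_max", "max_abs"))
      msg <- c(msg, "unknown scaler method")
    n <- length(object@featureNames)
    if (length(object@center) != n || length(object@scale) != n)
      msg <- c(msg, "one (center, scale) pair per feature required")
    if (any(object@scale < 0)) msg <- c(msg, "scale statistics must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' CorrelationResult: imaging-vs-omics correlation matrices and survivors
#'
#' Holds the pairwise coefficient matrix (imaging features in rows, omics
#' features in columns), raw and multiplicity-adjusted two-sided p-values,
#' and -- after filtering -- the surviving feature subsets.
#'
#' @slot method \code{"pearson"} or \code{"spearman"}.
#' @slot r coefficient matrix.
#' @slot p raw two-sided p-value matrix.
#' @slot padj adjusted p-value matrix.
#' @slot correctionMethod the p-value adjustment used.
#' @slot coeffThreshold coefficient threshold applied (NA before filtering).
#' @slot pThreshold adjusted-p threshold applied (NA before filtering).
#' @slot survivingImaging,survivingOmics surviving feature names.
#' @slot pairs long-format data.frame of all pairs with a \code{survives} flag.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(method = "character", r = "matrix", p = "matrix",
                 padj = "matrix", correctionMethod = "character",
                 coeffThreshold = "numeric", pThreshold = "numeric",
                 survivingImaging = "characterOrNULL",
                 survivingOmics = "characterOrNULL",
                 pairs = "listOrNULL"),
  validity = function(object) {
    msg <- character()
    if (any(abs(object@r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
    if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p-values must lie in [0,1]")
    if (length(object@padj) &&
        any(object@padj < -1e-12 | object@padj > 1 + 1e-12))
      msg <- c(msg, "adjusted p-values must lie in [0,1]")
    if (!is.null(object@survivingImaging) &&
        !all(object@survivingImaging %in% rownames(object@r)))
      msg <- c(msg, "surviving imaging features must be a subset of the input")
    if (!is.null(object@survivingOmics) &&
        !all(object@survivingOmics %in% colnames(object@r)))
      msg <- c(msg, "surviving omics features must be a subset of the input")
    if (length(msg)) msg else TRUE
  })

#' ModelSpec: model family, hyperparameters and cross-validation settings
#'
#' @slot modelType one of \code{"linear"}, \code{"lasso"}, \code{"elastic_net"},
#'   \code{"multi_task_lasso"}, \code{"multi_task_elastic_net"},
#'   \code{"decision_tree"}.
#' @slot params named list of hyperparameters; empty entries fall back to the
#'   frozen defaults table (see \code{\link{modelDefaults}}).
#' @slot grid named list of candidate vectors for grid search (may be empty).
#' @slot gridSearch logical, whether to run an exhaustive grid search.
#' @slot cvFolds number of cross-validation folds (>= 2).
#' @slot seed integer seed governing any randomized step.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(modelType = "character", params = "list", grid = "list",
                 gridSearch = "logical", cvFolds = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@modelType %in% c("linear", "lasso", "elastic_net",
                                 "multi_task_lasso", "multi_task_elastic_net",
                                 "decision_tree"))
      msg <- c(msg, sprintf("unknown model type '%s'", object@modelType))
    if (object@cvFolds < 2) msg <- c(msg, "cvFolds must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' TrainedModel: a fitted multi-label regression model
#'
#' Wraps the per-label fitted objects together with everything needed to
#' reproduce predictions: the feature and label names, the fitted scaler
#' parameters for X and Y, the coefficient (or importance) matrix, the
#' cross-validation scores and the hyperparameters finally used.
#'
#' @slot spec the \code{ModelSpec} used.
#' @slot fits per-label fitted objects (or one joint object for multi-task).
#' @slot coefMatrix n_labels x n_features coefficient matrix (linear
#'   families) or normalized importance matrix (trees).
#' @slot intercepts per-label intercepts (0 for trees).
#' @slot featureNames,labelNames names of predictors and predicted labels.
#' @slot scalerX,scalerY fitted \code{ScalerParams} (may be NULL when the
#'   caller normalizes externally).
#' @slot scalerFit \code{"independent"} (refit on each dataset) or
#'   \code{"train_only"} (re-apply the training statistics).
#' @slot cvScores per-fold negative-MSE scores.
#' @slot chosenParams hyperparameters after defaults/grid resolution.
#' @slot gridLog data.frame of grid-search evaluations (empty if no search).
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(spec = "ModelSpec", fits = "list", coefMatrix = "matrix",
                 intercepts = "numeric", featureNames = "character",
                 labelNames = "character", scalerX = "ANY", scalerY = "ANY",
                 scalerFit = "character", cvScores = "numeric",
                 chosenParams = "list", gridLog = "ANY"))

#' PermutationResult: permutation-test outcome for one gated label
#'
#' @slot label the label (gene) tested.
#' @slot nPerm number of permutations.
#' @slot aucTest,r2Test observed test-phase statistics.
#' @slot aucPerm,r2Perm permuted statistic samples (length nPerm).
#' @slot pAuc,pR2 count-based p-values.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(label = "character", nPerm = "numeric",
                 aucTest = "numeric", r2Test = "numeric",
                 aucPerm = "numeric", r2Perm = "numeric",
                 pAuc = "numeric", pR2 = "numeric"),
  validity = function(object) {
    msg <- character()
    for (p in c(object@pAuc, object@pR2))
      if (!is.na(p) && (p < 0 || p > 1)) msg <- c(msg, "p-values must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' RadioLinkConfig: the full experiment configuration
#'
#' One object holding every pipeline parameter; defaults follow the
#' platform's standard configuration (Spearman correlation at threshold 0.5,
#' BH correction, imaging features as data and omics as labels, 0.9/0.1
#' train/test split, standard scaling, decision-tree model, cv = 2).
#'
#' @slot settings named list of all configuration values; see
#'   \code{\link{radioLinkConfig}} for the keys.
#' @exportClass RadioLinkConfig
setClass("RadioLinkConfig", representation(settings = "list"),
  validity = function(object) {
    s <- object@settings
    msg <- character()
    if (identical(s$dataRole, s$labelRole))
      msg <- c(msg, "dataRole and labelRole must differ")
    for (fr in c("trainSize", "testSize"))
      if (s[[fr]] <= 0 || s[[fr]] >= 1)
        msg <- c(msg, sprintf("%s must lie in (0,1)", fr))
    if (s$trainSize + s$testSize > 1 + 1e-12)
      msg <- c(msg, "trainSize + testSize must not exceed 1")
    if (!s$mode %in% c("train", "validate", "predict"))
      msg <- c(msg, "mode must be train, validate or predict")
    if (!s$normalization %in% c("stand_scaler", "min_max", "max_abs"))
      msg <- c(msg, "unknown normalization method")
    if (!s$correlationMethod %in% c("pearson", "spearman"))
      msg <- c(msg, "correlationMethod must be pearson or spearman")
    if (s$nPermutations < 1) msg <- c(msg, "nPermutations must be >= 1")
    if (length(msg)) msg else TRUE
  })
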