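#' Build a full experiment configuration
#'
#' Defaults reproduce the platform's standard settings: Spearman
#' correlation at |r| threshold 0.5 (set -1 to disable filtering), BH
#' adjustment with the 0.05 cutoff, imaging features as data (X) and omics
#' features as labels (Y), a 0.9/0.1 train/test split, standard scaling
#' fitted independently on train and test, decision-tree modeling without
#' grid search, 2-fold cross-validation, and 100 permutations for gated
#' labels.
#'
#' @param correlationMethod "spearman" (default) or "pearson"
#' @param correlationThreshold minimum |r| for a pair to survive; -1
#'   disables correlation-based filtering
#' @param pCorrection p-value adjustment method (holm, hochberg, hommel,
#'   bonferroni, BH, BY, fdr)
#' @param pThreshold adjusted-p cutoff (default 0.05)
#' @param dataRole,labelRole "imaging" or "gene"; which table provides the
#'   independent set X and which the dependent labels Y (must differ)
#' @param trainSize,testSize split fractions in (0,1)
#' @param normalization "stand_scaler", "min_max" or "max_abs"
#' @param scalerFit "independent" (fit separately on train and test) or
#'   "train_only" (fit on train, apply to test)
#' @param mode "train", "validate" or "predict"
#' @param modelType one of the six model families
#' @param gridSearch logical
#' @param cv number of cross-validation folds
#' @param modelParams,gridParams named lists of hyperparameters /
#'   grid candidates
#' @param seed integer master seed for split and permutations
#' @param nPermutations permutations per gated label
#' @param smoothedP use the (count+1)/(n+1) permutation p-value
#' @param dtGrid decision-threshold grid
#' @param aucGate,r2Gate test-phase gates for permutation testing
#' @param selectThreshold "mean" or a numeric importance cutoff for
#'   model-based feature selection (second round)
#' @param screenMinValue,screenMinSamples optional omics screening rule
#'   (e.g. 5 and 30: keep features with value >= 5 in >= 30 samples);
#'   NULL skips screening
#' @return a validated \code{RadioLinkConfig}
#' @export
radioLinkConfig <- function(correlationMethod = "spearman",
                            correlationThreshold = 0.5,
                            pCorrection = "BH", pThreshold = 0.05,
                            dataRole = "imaging", labelRole = "gene",
                            trainSize = 0.9, testSize = 0.1,
                            normalization = "stand_scaler",
                            scalerFit = "independent",
                            mode = "train", modelType = "decision_tree",
                            gridSearch = FALSE, cv = 2,
                            modelParams = list(), gridParams = list(),
                            seed = 1L, nPermutations = 100L,
                            smoothedP = FALSE,
                            dtGrid = seq(0.1, 1, by = 0.1),
                            aucGate = 0.9, r2Gate = 0.25,
                            selectThreshold = "mean",
                            screenMinValue = NULL, screenMinSamples = NULL) {
  s <- list(correlationMethod = correlationMethod,
            correlationThreshold = correlationThreshold,
            pCorrection = pCorrection, pThreshold = pThreshold,
            dataRole = dataRole, labelRole = labelRole,
            trainSize = trainSize, testSize = testSize,
            normalization = normalization, scalerFit = scalerFit,
            mode = mode, modelType = modelType, gridSearch = gridSearch,
            cv = cv, modelParams = modelParams, gridParams = gridParams,
            seed = seed, nPermutations = nPermutations,
            smoothedP = smoothedP, dtGrid = dtGrid, aucGate = aucGate,
            r2Gate = r2Gate, selectThreshold = selectThreshold,
            screenMinValue = screenMinValue,
            screenMinSamples = screenMinSamples)
  new("RadioLinkConfig", settings = s)
}

#' @rdname radioLinkConfig
#' @param x a \code{RadioLinkConfig}
#' @param name a settings key
#' @export
setMethod("$", "RadioLinkConfig", function(x, name) x@settings[[name]])

.asFeatureTable <- function(x, role) {
  if (is(x, "FeatureTable")) x else loadFeatureTable(x, role)
}

#' Model-based feature selection (second analysis round)
#'
#' Ranks features by the model's own importance scores -- normalized split
#' importances for trees, the L2 norm of coefficients across labels for
#' linear families -- and keeps those scoring at or above the threshold
#' (default: the mean score). If nothing survives, the single top-scoring
#' feature is kept with a warning.
#'
#' @param model a \code{TrainedModel} fitted on the full feature set
#' @param threshold "mean" or a numeric cutoff
#' @return character vector of selected feature names
#' @export
selectFeaturesFromModel <- function(model, threshold = "mean") {
  stopifnot(is(model, "TrainedModel"))
  w <- model@coefMatrix
  scores <- if (model@spec@modelType == "decision_tree")
    colMeans(w) else sqrt(colSums(w^2))
  cut <- if (identical(threshold, "mean")) mean(scores) else as.numeric(threshold)
  keep <- names(scores)[scores >= cut]
  if (length(keep) == 0L) {
    warning("no feature reached the selection threshold; keeping the top one")
    keep <- names(scores)[which.max(scores)]
  }
  keep
}

## Train + evaluate + gate + permute on a fixed feature/label subset.
## Everything here operates on one shared train/test split.
.runScenario <- function(config, split, features, labels, dir,
                         scenario, logf, plots = TRUE) {
  s <- config@settings
  subm <- function(ft, cols) ft@values[, cols, drop = FALSE]
  XtrR <- subm(split$train$x, features); XteR <- subm(split$test$x, features)
  YtrR <- subm(split$train$y, labels);   YteR <- subm(split$test$y, labels)
  scX <- fitScaler(XtrR, s$normalization)
  scY <- fitScaler(YtrR, s$normalization)
  norm <- function(m, scTrain) {
    if (identical(s$scalerFit, "train_only")) applyScaler(m, scTrain)
    else applyScaler(m, fitScaler(m, s$normalization))
  }
  Xtr <- applyScaler(XtrR, scX); Ytr <- applyScaler(YtrR, scY)
  Xte <- norm(XteR, scX); Yte <- norm(YteR, scY)

  spec <- modelSpec(s$modelType, params = s$modelParams,
                    grid = s$gridParams, gridSearch = s$gridSearch,
                    cvFolds = s$cv, seed = s$seed)
  model <- trainModel(spec, Xtr, Ytr, scalerX = scX, scalerY = scY,
                      scalerFit = s$scalerFit)
  pred <- predict(model, Xte, preNormalized = TRUE)
  ev <- evaluateLabels(Yte, pred, s$dtGrid)
  gated <- gateLabels(ev$metrics, s$aucGate, s$r2Gate)
  logf(sprintf("[%s] trained %s on %d features x %d labels; %d label(s) gated",
               scenario, s$modelType, length(features), length(labels),
               length(gated)))
  perms <- list()
  for (lb in gated) {
    permSeed <- (s$seed * 1009L + match(lb, labels) * 7919L) %% .Machine$integer.max
    perms[[lb]] <- permutationTest(spec, Xtr, Ytr, Xte, Yte[, lb], lb,
                                   nPerm = s$nPermutations, seed = permSeed,
                                   dtGrid = s$dtGrid, smoothed = s$smoothedP)
    writeValidationPermuts(perms[[lb]], dir)
  }
  psum <- permutationSummary(perms)

  ## machine-readable artifacts
  utils::write.csv(ev$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  curves <- do.call(rbind, lapply(names(ev$curves), function(lb)
    cbind(label = lb, ev$curves[[lb]])))
  utils::write.csv(curves, file.path(dir, "auc_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(exportFeatureWeights(model),
                   file.path(dir, "feature_weights.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(fold = seq_along(model@cvScores),
                              neg_MSE = model@cvScores),
                   file.path(dir, "cv_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(psum, file.path(dir, "significance.csv"),
                   row.names = FALSE, quote = FALSE)
  saveModel(model, file.path(dir, "model.rds"))
  plotFiles <- if (plots)
    .scenarioPlots(ev, Yte, pred, dir) else character()

  list(scenario = scenario, dir = dir, features = features, labels = labels,
       model = model, evaluation = ev, gated = gated, permutations = perms,
       significance = psum, yObsTest = Yte, yPredTest = pred,
       plotFiles = plotFiles)
}

#' Run a full two-scenario training experiment
#'
#' Scenario A correlates the (non-normalized) matched tables, filters the
#' feature pairs by |r| and adjusted p, then splits, normalizes, trains,
#' evaluates per label, gates and permutes. Scenario B bypasses the
#' correlation module entirely: a model trained on all features selects its
#' own features (model-based selection), a second model is retrained on the
#' selected subset, and its outputs land in a subdirectory prefixed
#' \code{FeaturesSelFromModel}. Both scenarios share one train/test split
#' so their metrics are comparable, and the whole run is deterministic
#' given the config seed.
#'
#' @param config a \code{RadioLinkConfig}
#' @param imaging,omics CSV paths or \code{FeatureTable}s
#' @param outputDir job directory (created; default: timestamped name under
#'   the working directory)
#' @param plots render PNG figures and reference them in the report
#' @return (invisibly) a list with the correlation result, both scenario
#'   result sets and the artifact paths
#' @export
runTrain <- function(config, imaging, omics, outputDir = NULL, plots = TRUE) {
  stopifnot(is(config, "RadioLinkConfig"))
  s <- config@settings
  img <- .asFeatureTable(imaging, "imaging")
  omi <- .asFeatureTable(omics, "omics")
  if (!is.null(s$screenMinValue))
    omi <- screenOmics(omi, s$screenMinValue, s$screenMinSamples)
  m <- matchSamples(img, omi)
  if (is.null(outputDir))
    outputDir <- paste0("radiolink_job_", format(Sys.time(), "%Y%m%d_%H%M%S"))
  fsDir <- file.path(outputDir, "FeaturesSelFromModel")
  dir.create(fsDir, recursive = TRUE, showWarnings = FALSE)

  ## config snapshot is the first artifact (reproducible provenance)
  snap <- s; snap$dtGrid <- as.numeric(snap$dtGrid)
  jsonlite::write_json(snap, file.path(outputDir, "config_snapshot.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  logPath <- file.path(outputDir, "run_log.txt")
  logf <- function(msg) cat(msg, "\n", file = logPath, append = TRUE, sep = "")
  logf(sprintf("run started; %d matched samples", nrow(m$a@values)))

  ## data/label role assignment (Table-style role swap)
  X <- if (identical(s$dataRole, "imaging")) m$a else m$b
  Y <- if (identical(s$dataRole, "imaging")) m$b else m$a

  split <- splitTrainTest(X, Y, s$trainSize, s$testSize, s$seed)

  ## --- Scenario A: correlation-filtered features -------------------------
  cr <- correlationAnalysis(X, Y, s$correlationMethod, s$pCorrection)
  cr <- filterByCorrelation(cr, s$correlationThreshold, s$pThreshold)
  writeCorrelationResult(cr, file.path(outputDir, "correlation.csv"))
  heatmapFile <- if (plots) .plotCorrelationHeatmap(cr, outputDir) else NULL
  scenA <- NULL
  if (length(cr@survivingImaging) == 0L || length(cr@survivingOmics) == 0L) {
    warning("no feature pair survived correlation filtering; scenario A is empty")
    logf("[corr-filtered] no surviving features; scenario skipped")
  } else {
    scenA <- .runScenario(config, split, cr@survivingImaging,
                          cr@survivingOmics, outputDir, "corr-filtered",
                          logf, plots)
  }

  ## --- Scenario B: model-based feature selection (correlation bypassed) --
  allFeat <- featureNames(X); allLab <- featureNames(Y)
  XtrR <- split$train$x@values
  YtrR <- split$train$y@values
  scX <- fitScaler(XtrR, s$normalization); scY <- fitScaler(YtrR, s$normalization)
  spec0 <- modelSpec(s$modelType, params = s$modelParams, cvFolds = s$cv,
                     seed = s$seed)
  full <- trainModel(spec0, applyScaler(XtrR, scX), applyScaler(YtrR, scY),
                     cv = FALSE)
  selected <- selectFeaturesFromModel(full, s$selectThreshold)
  writeLines(selected, file.path(fsDir, "selected_features.txt"))
  logf(sprintf("[FeaturesSelFromModel] %d of %d features selected",
               length(selected), length(allFeat)))
  scenB <- .runScenario(config, split, selected, allLab, fsDir,
                        "FeaturesSelFromModel", logf, plots)
  scenB$selectionModel <- full

  res <- list(config = config, outputDir = outputDir,
              nMatchedSamples = nrow(m$a@values),
              trainIDs = split$trainIDs, testIDs = split$testIDs,
              correlation = cr, heatmapFile = heatmapFile,
              scenarioA = scenA, scenarioB = scenB)
  renderReport(res, file.path(outputDir, "report.html"))
  logf("run finished")
  invisible(res)
}

#' Validate a stored model on one or more held-out dataset pairs
#'
#' The stored model is applied unchanged: features are normalized per the
#' model's scaler-fit policy, predictions are evaluated per label and the
#' AUC sweep is recomputed for every dataset.
#'
#' @param config a \code{RadioLinkConfig}
#' @param modelFile path to a saved model (\code{\link{saveModel}})
#' @param testSets list of \code{list(imaging = , omics = )} pairs
#'   (paths or \code{FeatureTable}s)
#' @param outputDir optional directory for per-dataset metric CSVs
#' @return list of per-dataset evaluation lists
#' @export
runValidate <- function(config, modelFile, testSets, outputDir = NULL) {
  stopifnot(is(config, "RadioLinkConfig"))
  s <- config@settings
  model <- loadModel(modelFile)
  if (!is.null(outputDir))
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- vector("list", length(testSets))
  for (i in seq_along(testSets)) {
    ts <- testSets[[i]]
    img <- .asFeatureTable(ts$imaging, "imaging")
    omi <- .asFeatureTable(ts$omics, "omics")
    m <- matchSamples(img, omi)
    X <- if (identical(s$dataRole, "imaging")) m$a else m$b
    Y <- if (identical(s$dataRole, "imaging")) m$b else m$a
    miss <- setdiff(model@labelNames, featureNames(Y))
    if (length(miss))
      stop(sprintf("label(s) missing from validation set %d: %s", i,
                   paste(miss, collapse = ", ")))
    pred <- predict(model, X@values)
    YR <- Y@values[, model@labelNames, drop = FALSE]
    Yn <- if (identical(model@scalerFit, "train_only"))
      applyScaler(YR[, model@scalerY@featureNames, drop = FALSE], model@scalerY)
    else
      applyScaler(YR, fitScaler(YR, model@scalerY@method))
    ev <- evaluateLabels(Yn, pred, s$dtGrid)
    if (!is.null(outputDir))
      utils::write.csv(ev$metrics,
                       file.path(outputDir, sprintf("metrics_set%d.csv", i)),
                       row.names = FALSE, quote = FALSE)
    out[[i]] <- ev
  }
  out
}

#' Predict labels for a new data table with a stored model
#'
#' @param config a \code{RadioLinkConfig}
#' @param modelFile path to a saved model
#' @param data CSV path or \code{FeatureTable} of data features
#' @param outputFile optional CSV destination for the predictions
#' @return matrix of continuous predictions (normalized label space),
#'   samples x labels
#' @export
runPredict <- function(config, modelFile, data, outputFile = NULL) {
  stopifnot(is(config, "RadioLinkConfig"))
  s <- config@settings
  role <- if (identical(s$dataRole, "imaging")) "imaging" else "omics"
  X <- .asFeatureTable(data, role)
  model <- loadModel(modelFile)
  pred <- predict(model, X@values)
  if (!is.null(outputFile)) {
    df <- data.frame(Sample = rownames(pred), pred, check.names = FALSE)
    utils::write.csv(df, outputFile, row.names = FALSE, quote = FALSE)
  }
  pred
}
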