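#' Per-label regression metrics: MSE, RMSE, STDEV, v and R-squared
#'
#' The v statistic is the ratio of the prediction RMSE to the population
#' standard deviation of the observed values; squaring it gives SSL/SST, so
#' R^2 = 1 - v^2. Both routes to R^2 are computed: \code{R2_direct} from
#' the sums of squares and \code{R2_identity} from v; with the population
#' (ddof = 0) convention they agree to machine precision, including v > 1
#' (negative R^2). A constant observed vector leaves v and R^2 undefined
#' (NA) with a warning.
#'
#' @param yObs,yPred numeric vectors of equal length >= 2
#' @return one-row data.frame with MSE, RMSE, STDEV, v, R2_direct,
#'   R2_identity, SSL, SST
#' @export
scoreLabel <- function(yObs, yPred) {
  if (length(yObs) != length(yPred)) stop("length mismatch")
  if (length(yObs) < 2L) stop("at least 2 observations required")
  mse <- mean((yObs - yPred)^2)
  rmse <- sqrt(mse)
  stdev <- popSD(yObs)
  ssl <- sum((yObs - yPred)^2)
  sst <- sum((yObs - mean(yObs))^2)
  if (stdev == 0) {
    warning("constant observed values: v and R2 are undefined")
    v <- NA_real_; r2d <- NA_real_; r2i <- NA_real_
  } else {
    v <- rmse / stdev
    r2d <- 1 - ssl / sst
    r2i <- 1 - v^2
  }
  data.frame(MSE = mse, RMSE = rmse, STDEV = stdev, v = v,
             R2_direct = r2d, R2_identity = r2i, SSL = ssl, SST = sst)
}

#' Binarize observed label values at a decision threshold
#'
#' Values strictly below \code{dt} become 0 ("low"); values at or above it
#' become 1 ("high"). Predictions are never binarized -- they stay
#' continuous classifier scores.
#'
#' @param y numeric vector (rescaled to [0,1] for the sweep)
#' @param dt decision threshold
#' @return integer 0/1 vector
#' @export
binarize <- function(y, dt) as.integer(y >= dt)

#' Rank-based AUC of continuous scores against binary labels
#'
#' Equals the probability that a random positive outranks a random
#' negative, with ties credited 0.5 (Mann-Whitney statistic). Undefined
#' (NA) when the labels are all one class.
#'
#' @param labels 0/1 vector
#' @param scores continuous scores, same length
#' @return AUC in [0,1], or NA when undefined
#' @export
aucRank <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks: ties get 0.5 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Min-max map of yObs to [0,1]; yPred is sent through the same affine map
## so the score ranking (hence every AUC) is unchanged.
.sweepRescale <- function(yObs, yPred) {
  lo <- min(yObs); span <- max(yObs) - lo
  if (span == 0) return(NULL)
  list(obs = (yObs - lo) / span, pred = (yPred - lo) / span)
}

#' AUC versus decision threshold sweep for one label
#'
#' The observed values are min-max rescaled to [0,1] (independently of the
#' model-space scaler, so the dt grid is always meaningful), binarized at
#' each grid threshold, and scored against the continuous predictions.
#' Thresholds where the binarized labels are all one class yield NA.
#'
#' @param yObs,yPred numeric vectors
#' @param dtGrid strictly increasing thresholds in [0,1]
#'   (default 0.1, 0.2, ..., 1.0)
#' @return data.frame with columns \code{dt} and \code{AUC}
#' @export
aucSweep <- function(yObs, yPred, dtGrid = seq(0.1, 1, by = 0.1)) {
  if (any(diff(dtGrid) <= 0) || any(dtGrid < 0 | dtGrid > 1))
    stop("dtGrid must be strictly increasing within [0,1]")
  rs <- .sweepRescale(yObs, yPred)
  auc <- if (is.null(rs)) rep(NA_real_, length(dtGrid)) else
    vapply(dtGrid, function(dt) aucRank(binarize(rs$obs, dt), rs$pred),
           numeric(1L))
  data.frame(dt = dtGrid, AUC = auc)
}

#' Evaluate a prediction matrix label by label
#'
#' Combines \code{\link{scoreLabel}} and \code{\link{aucSweep}} for every
#' label and reports the headline AUC (the maximum defined AUC over the dt
#' grid) together with the dt range attaining it.
#'
#' @param yObs,yPred matrices n_samples x n_labels with identical column names
#' @param dtGrid decision-threshold grid
#' @return list with \code{metrics} (one row per label: MSE, RMSE, STDEV,
#'   v, R2_direct, R2_identity, AUC, dt_lo, dt_hi) and \code{curves}
#'   (named list of per-label AUC-vs-dt data.frames)
#' @export
evaluateLabels <- function(yObs, yPred, dtGrid = seq(0.1, 1, by = 0.1)) {
  yObs <- as.matrix(yObs); yPred <- as.matrix(yPred)
  stopifnot(ncol(yObs) == ncol(yPred))
  labs <- colnames(yObs)
  if (is.null(labs)) labs <- paste0("y", seq_len(ncol(yObs)))
  rows <- vector("list", ncol(yObs))
  curves <- stats::setNames(vector("list", ncol(yObs)), labs)
  for (j in seq_len(ncol(yObs))) {
    sc <- scoreLabel(yObs[, j], yPred[, j])
    cv <- aucSweep(yObs[, j], yPred[, j], dtGrid)
    curves[[j]] <- cv
    def <- !is.na(cv$AUC)
    if (any(def)) {
      best <- max(cv$AUC[def])
      at <- cv$dt[def & abs(cv$AUC - best) < 1e-12]
      rows[[j]] <- cbind(label = labs[j], sc, AUC = best,
                         dt_lo = min(at), dt_hi = max(at))
    } else {
      rows[[j]] <- cbind(label = labs[j], sc, AUC = NA_real_,
                         dt_lo = NA_real_, dt_hi = NA_real_)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, curves = curves)
}

#' Export per-label feature weights of a trained model
#'
#' Trees report normalized split importances (nonnegative, summing to 1 per
#' label; a feature absent from every split scores 0); linear families
#' report their fitted coefficients.
#'
#' @param model a \code{TrainedModel}
#' @return data.frame with columns \code{label}, \code{feature},
#'   \code{weight}
#' @export
exportFeatureWeights <- function(model) {
  stopifnot(is(model, "TrainedModel"))
  w <- model@coefMatrix
  data.frame(label = rep(rownames(w), each = ncol(w)),
             feature = rep(colnames(w), times = nrow(w)),
             weight = as.vector(t(w)), stringsAsFactors = FALSE)
}
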