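#' Gate labels for permutation testing
#'
#' Only labels predicted confidently in the test phase -- headline AUC
#' strictly above \code{aucThreshold} and test R^2 strictly above
#' \code{r2Threshold} -- proceed to the (expensive) permutation test.
#'
#' @param metrics the \code{metrics} data.frame from
#'   \code{\link{evaluateLabels}}
#' @param aucThreshold gate on the headline AUC (default 0.9)
#' @param r2Threshold gate on test R^2 (default 0.25)
#' @return character vector of gated label names
#' @export
gateLabels <- function(metrics, aucThreshold = 0.9, r2Threshold = 0.25) {
  ok <- !is.na(metrics$AUC) & !is.na(metrics$R2_direct) &
    metrics$AUC > aucThreshold & metrics$R2_direct > r2Threshold
  as.character(metrics$label[ok])
}

#' Permutation test for one label
#'
#' The label's training values are randomly permuted across training
#' samples, the model is refit from scratch, and the refit model is
#' re-evaluated on the untouched test split; this is repeated
#' \code{nPerm} times. For separable families (linear, lasso, elastic net,
#' decision tree) only the tested label's submodel is refit; multi-task
#' models are refit jointly with the permuted column in place. P-values
#' are the plain exceedance counts p = #(stat_perm >= stat_test) / nPerm
#' (so an observed statistic above every permuted one yields p = 0);
#' \code{smoothed = TRUE} switches to (count + 1) / (nPerm + 1).
#'
#' @param spec a \code{ModelSpec}
#' @param XTrain,YTrain normalized training matrices
#' @param XTest normalized test data matrix
#' @param yObsTest observed (normalized) test values of the label
#' @param label label name (a column of \code{YTrain})
#' @param nPerm number of permutations (default 100)
#' @param seed integer seed; permutation sequences are reproducible
#' @param dtGrid decision-threshold grid for the headline AUC
#' @param smoothed use the (count+1)/(nPerm+1) p-value convention
#' @return a \code{PermutationResult}
#' @export
permutationTest <- function(spec, XTrain, YTrain, XTest, yObsTest, label,
                            nPerm = 100L, seed = 1L,
                            dtGrid = seq(0.1, 1, by = 0.1),
                            smoothed = FALSE) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  XTrain <- as.matrix(XTrain); YTrain <- as.matrix(YTrain)
  XTest <- as.matrix(XTest)
  if (!label %in% colnames(YTrain))
    stop(sprintf("label '%s' not found in the training labels", label))
  multi <- .isMultiTask(spec@modelType)
  params <- .resolveParams(spec)
  ycol <- match(label, colnames(YTrain))

  statsOf <- function(Ytr) {
    core <- .fitCore(spec, params, XTrain, Ytr)
    pred <- .predictCore(core, XTest)[, if (multi) ycol else 1L]
    r2 <- 1 - sum((yObsTest - pred)^2) / sum((yObsTest - mean(yObsTest))^2)
    cv <- aucSweep(yObsTest, pred, dtGrid)$AUC
    c(auc = if (all(is.na(cv))) NA_real_ else max(cv, na.rm = TRUE), r2 = r2)
  }

  baseY <- if (multi) YTrain else YTrain[, ycol, drop = FALSE]
  obs <- statsOf(baseY)
  perms <- withSeed(seed, replicate(nPerm, sample.int(nrow(YTrain))))
  aucPerm <- numeric(nPerm); r2Perm <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    Yb <- baseY
    Yb[, if (multi) ycol else 1L] <- YTrain[perms[, b], ycol]
    st <- statsOf(Yb)
    aucPerm[b] <- st["auc"]; r2Perm[b] <- st["r2"]
  }
  pcount <- function(perm, ob) {
    if (is.na(ob)) return(NA_real_)
    k <- sum(perm >= ob, na.rm = TRUE)
    if (smoothed) (k + 1) / (nPerm + 1) else k / nPerm
  }
  new("PermutationResult", label = label, nPerm = as.numeric(nPerm),
      aucTest = unname(obs["auc"]), r2Test = unname(obs["r2"]),
      aucPerm = aucPerm, r2Perm = r2Perm,
      pAuc = pcount(aucPerm, obs["auc"]), pR2 = pcount(r2Perm, obs["r2"]))
}

#' Labels called significant after permutation testing
#'
#' A gated label is significant when its R^2 permutation p-value falls
#' below \code{alpha}. The R^2 statistic governs the call because the
#' headline AUC (a maximum over the dt grid) carries an irreducible null
#' exceedance of about 1/n_test -- a threshold leaving a single positive
#' yields a permuted AUC of 1 with that probability -- so its p-value
#' cannot resolve below that floor on small test sets; the AUC p-value is
#' still reported alongside.
#'
#' @param summary data.frame from \code{\link{permutationSummary}}
#' @param alpha significance level (default 0.05)
#' @return character vector of significant label names
#' @export
significantLabels <- function(summary, alpha = 0.05) {
  as.character(summary$label[!is.na(summary$p_R2) & summary$p_R2 < alpha])
}

#' Write the raw permuted statistics of one label ("validation permuts")
#' @param x a \code{PermutationResult}
#' @param dir output directory
#' @return the file path written
#' @export
writeValidationPermuts <- function(x, dir) {
  stopifnot(is(x, "PermutationResult"))
  path <- file.path(dir, sprintf("validation_permuts_%s.txt", x@label))
  utils::write.table(
    data.frame(permutation = seq_len(x@nPerm),
               AUC_perm = x@aucPerm, R2_perm = x@r2Perm),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize permutation results across labels
#' @param results list of \code{PermutationResult}s
#' @return data.frame: label, AUC_test, R2_test, p_AUC, p_R2
#' @export
permutationSummary <- function(results) {
  if (!length(results))
    return(data.frame(label = character(), AUC_test = numeric(),
                      R2_test = numeric(), p_AUC = numeric(),
                      p_R2 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(results, function(x)
    data.frame(label = x@label, AUC_test = x@aucTest, R2_test = x@r2Test,
               p_AUC = x@pAuc, p_R2 = x@pR2, stringsAsFactors = FALSE)))
}
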