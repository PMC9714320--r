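#' @rdname FeatureTable-class
#' @param object,x a \code{FeatureTable}
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureTable-class
#' @export
setGeneric("tableRole", function(x) standardGeneric("tableRole"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname CorrelationResult-class
#' @param x a \code{CorrelationResult}
#' @export
setGeneric("coefficients2", function(x) standardGeneric("coefficients2"))

#' Surviving feature pairs of a filtered correlation analysis
#' @param x a \code{CorrelationResult} after \code{filterByCorrelation}
#' @return data.frame with one row per feature pair
#' @export
setGeneric("survivingPairs", function(x) standardGeneric("survivingPairs"))

## -- FeatureTable accessors ------------------------------------------------

#' @rdname FeatureTable-class
#' @export
setMethod("sampleIDs", "FeatureTable", function(x) rownames(x@values))

#' @rdname FeatureTable-class
#' @export
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))

#' @rdname FeatureTable-class
#' @export
setMethod("tableRole", "FeatureTable", function(x) x@role)

#' @rdname FeatureTable-class
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @rdname FeatureTable-class
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (%s): %d samples x %d features\n",
              object@role, nrow(object@values), ncol(object@values)))
  cat("  samples:", paste(utils::head(rownames(object@values), 4L),
                          collapse = ", "),
      if (nrow(object@values) > 4L) "..." else "", "\n")
  cat("  features:", paste(utils::head(colnames(object@values), 4L),
                           collapse = ", "),
      if (ncol(object@values) > 4L) "..." else "", "\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult (%s, %s-adjusted): %d imaging x %d omics\n",
              object@method, object@correctionMethod,
              nrow(object@r), ncol(object@r)))
  if (!is.null(object@survivingImaging))
    cat(sprintf("  filtered at |r| > %s, p_adj < %s: %d imaging, %d omics survive\n",
                format(object@coeffThreshold), format(object@pThreshold),
                length(object@survivingImaging), length(object@survivingOmics)))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s, %d features -> %d labels\n",
              object@spec@modelType, length(object@featureNames),
              length(object@labelNames)))
  if (length(object@cvScores))
    cat(sprintf("  CV neg-MSE (%d folds): mean %.4g\n",
                length(object@cvScores), mean(object@cvScores)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult '%s': n_perm=%d AUC_test=%.3g (p=%s) R2_test=%.3g (p=%s)\n",
              object@label, object@nPerm, object@aucTest,
              format(object@pAuc), object@r2Test, format(object@pR2)))
})

setMethod("show", "RadioLinkConfig", function(object) {
  s <- object@settings
  cat("RadioLinkConfig:\n")
  keys <- c("correlationMethod", "correlationThreshold", "pCorrection",
            "dataRole", "labelRole", "trainSize", "testSize", "normalization",
            "mode", "modelType", "gridSearch", "cv", "nPermutations", "seed")
  for (k in keys) cat(sprintf("  %-21s %s\n", k, format(s[[k]])))
})

#' @rdname CorrelationResult-class
#' @export
setMethod("coefficients2", "CorrelationResult", function(x) x@r)

#' @rdname survivingPairs
#' @export
setMethod("survivingPairs", "CorrelationResult", function(x) {
  if (is.null(x@pairs))
    stop("correlation result has not been filtered yet; run filterByCorrelation()")
  as.data.frame(x@pairs, stringsAsFactors = FALSE)
})
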