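#' Pairwise imaging-vs-omics correlation with two-sided p-values
#'
#' Computes the coefficient and a two-sided p-value for every
#' (imaging feature, omics feature) pair. Spearman coefficients are Pearson
#' correlations of average ranks; p-values for both methods use the
#' t-distribution approximation t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees
#' of freedom. Zero-variance features yield r = 0 with p = 1 and a warning.
#' Correlation is intended to run on the non-normalized matched data.
#'
#' @param x imaging \code{FeatureTable} (or matrix), samples in rows
#' @param y omics \code{FeatureTable} (or matrix), same samples, same order
#' @param method \code{"pearson"} or \code{"spearman"}
#' @return list with matrices \code{r} and \code{p}
#'   (imaging features x omics features)
#' @export
correlateFeatures <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mx <- if (is(x, "FeatureTable")) x@values else as.matrix(x)
  my <- if (is(y, "FeatureTable")) y@values else as.matrix(y)
  if (nrow(mx) != nrow(my)) stop("tables must be sample-matched")
  n <- nrow(mx)
  if (n < 3L) stop("at least 3 samples are required for a correlation test")
  if (method == "spearman") {
    mx <- apply(mx, 2L, rank)   # average ranks for ties
    my <- apply(my, 2L, rank)
  }
  constX <- apply(mx, 2L, function(v) popSD(v) == 0)
  constY <- apply(my, 2L, function(v) popSD(v) == 0)
  if (any(constX) || any(constY))
    warning(sprintf("zero-variance feature(s) recorded as r = 0, p = 1: %s",
                    paste(c(colnames(mx)[constX], colnames(my)[constY]),
                          collapse = ", ")))
  r <- suppressWarnings(stats::cor(mx, my))
  r[constX, ] <- 0
  r[, constY] <- 0
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[constX, ] <- 1
  p[, constY] <- 1
  dimnames(r) <- dimnames(p) <- list(colnames(mx), colnames(my))
  list(r = r, p = p)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over the standard step-up/step-down procedures. "fdr" is an
#' alias of "BH" (also accepted lower-case).
#'
#' @param p numeric vector of raw p-values in [0,1]
#' @param method one of holm, hochberg, hommel, bonferroni, BH, BY, fdr
#' @return adjusted p-values, capped at 1, in the input order
#' @export
adjustPvalues <- function(p, method = "BH") {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  map <- c(holm = "holm", hochberg = "hochberg", hommel = "hommel",
           bonferroni = "bonferroni", bh = "BH", by = "BY", fdr = "BH")
  key <- map[tolower(method)]
  if (is.na(key)) stop(sprintf("unknown p-value correction method '%s'", method))
  stats::p.adjust(p, method = unname(key))
}

#' Full correlation analysis: coefficients, raw and adjusted p-values
#'
#' @inheritParams correlateFeatures
#' @param correction p-value adjustment method (default BH)
#' @return a \code{CorrelationResult} (unfiltered; run
#'   \code{\link{filterByCorrelation}} next)
#' @export
correlationAnalysis <- function(x, y, method = c("spearman", "pearson"),
                                correction = "BH") {
  method <- match.arg(method)
  cp <- correlateFeatures(x, y, method)
  padj <- matrix(adjustPvalues(as.vector(cp$p), correction),
                 nrow(cp$p), ncol(cp$p), dimnames = dimnames(cp$p))
  new("CorrelationResult", method = method, r = cp$r, p = cp$p, padj = padj,
      correctionMethod = correction, coeffThreshold = NA_real_,
      pThreshold = NA_real_, survivingImaging = NULL, survivingOmics = NULL,
      pairs = NULL)
}

#' Filter feature pairs by correlation strength and adjusted significance
#'
#' A pair survives iff |r| > \code{coeffThreshold} and adjusted
#' p < \code{pThreshold} (both strict); a feature survives iff it belongs to
#' at least one surviving pair. Setting \code{coeffThreshold = -1} disables
#' filtering entirely and passes every feature downstream.
#'
#' @param x a \code{CorrelationResult}
#' @param coeffThreshold minimum |r| (default 0.5); -1 disables filtering
#' @param pThreshold maximum adjusted p (default 0.05)
#' @return the \code{CorrelationResult} with survivors and the pair table
#'   filled in
#' @export
filterByCorrelation <- function(x, coeffThreshold = 0.5, pThreshold = 0.05) {
  stopifnot(is(x, "CorrelationResult"))
  disabled <- coeffThreshold == -1
  surv <- if (disabled) {
    matrix(TRUE, nrow(x@r), ncol(x@r), dimnames = dimnames(x@r))
  } else {
    abs(x@r) > coeffThreshold & x@padj < pThreshold
  }
  pairs <- data.frame(
    feature_imaging = rep(rownames(x@r), times = ncol(x@r)),
    feature_omics = rep(colnames(x@r), each = nrow(x@r)),
    r = as.vector(x@r), p_raw = as.vector(x@p), p_adj = as.vector(x@padj),
    survives = as.vector(surv), stringsAsFactors = FALSE)
  x@coeffThreshold <- coeffThreshold
  x@pThreshold <- pThreshold
  x@survivingImaging <- rownames(x@r)[rowSums(surv) > 0]
  x@survivingOmics <- colnames(x@r)[colSums(surv) > 0]
  x@pairs <- pairs
  validObject(x)
  x
}

#' Hierarchical leaf ordering of a correlation matrix for heat maps
#'
#' Rows and columns are clustered agglomeratively (average linkage) on the
#' profile-similarity distance d(i, j) = 1 - |cor(profile_i, profile_j)|;
#' a zero-variance profile is at distance 1 from everything.
#'
#' @param m numeric matrix (finite entries)
#' @return list with \code{rowOrder}, \code{colOrder} (permutations of the
#'   input indices) and the \code{hclust} trees (NULL when a dimension has
#'   fewer than 2 entries)
#' @export
clusterOrder <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("matrix must be finite")
  profDist <- function(mm) {
    k <- nrow(mm)
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (popSD(mm[i, ]) == 0 || popSD(mm[j, ]) == 0) d[i, j] <- 1
      else d[i, j] <- 1 - abs(stats::cor(mm[i, ], mm[j, ]))
      d[j, i] <- d[i, j]
    }
    stats::as.dist(d)
  }
  orderOf <- function(mm) {
    if (nrow(mm) < 2L)
      return(list(order = seq_len(nrow(mm)), tree = NULL))
    h <- stats::hclust(profDist(mm), method = "average")
    list(order = h$order, tree = h)
  }
  ro <- orderOf(m)
  co <- orderOf(t(m))
  list(rowOrder = ro$order, colOrder = co$order,
       rowTree = ro$tree, colTree = co$tree)
}

#' Write a filtered correlation result as a long-format CSV
#' @param x a filtered \code{CorrelationResult}
#' @param path output CSV path
#' @export
writeCorrelationResult <- function(x, path) {
  utils::write.csv(survivingPairs(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
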