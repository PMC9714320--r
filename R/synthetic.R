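#' Design of a synthetic paired imaging/omics dataset
#'
#' Emulates the shape of desk-scale radiogenomic case studies
#' (tens-to-hundreds of samples and features): imaging features are
#' independent standard normals; each planted omics label is a linear
#' function of one informative imaging feature (assigned round-robin) plus
#' Gaussian noise, then min-max mapped to [0,1] so the decision-threshold
#' grid is meaningful end to end; decoy labels are independent uniform
#' noise on [0,1].
#'
#' The effect size is parameterized by the population correlation
#' \code{targetR} between a planted label and its driving feature;
#' \code{targetR = sqrt(3)/2} corresponds to a signal-to-noise (variance)
#' ratio of 3, the default study condition.
#'
#' @param nSamples,nImaging,nOmics table dimensions
#' @param nInformative number of imaging features that drive labels
#' @param nPlanted number of omics labels carrying signal
#' @param targetR population correlation between a planted label and its
#'   driving feature (in (0,1]; 1 means noiseless labels)
#' @param seed integer seed
#' @return a \code{SyntheticDesign} list (class "SyntheticDesign")
#' @export
syntheticDesign <- function(nSamples = 120, nImaging = 40, nOmics = 30,
                            nInformative = 4, nPlanted = 6,
                            targetR = sqrt(3) / 2, seed = 1L) {
  if (nInformative > nImaging)
    stop("nInformative must not exceed nImaging")
  if (nPlanted > nOmics) stop("nPlanted must not exceed nOmics")
  if (min(nSamples, nImaging, nOmics, nInformative, nPlanted) < 1)
    stop("all design counts must be positive")
  if (targetR <= 0 || targetR > 1) stop("targetR must lie in (0,1]")
  ## unit-variance signal: beta = targetR, noise SD = sqrt(1 - targetR^2)
  noiseSD <- sqrt(1 - targetR^2)
  driver <- ((seq_len(nPlanted) - 1L) %% nInformative) + 1L
  effect <- matrix(0, nPlanted, nInformative)
  effect[cbind(seq_len(nPlanted), driver)] <- targetR
  structure(list(nSamples = nSamples, nImaging = nImaging, nOmics = nOmics,
                 nInformative = nInformative, nPlanted = nPlanted,
                 targetR = targetR, noiseSD = noiseSD, effect = effect,
                 seed = seed),
            class = "SyntheticDesign")
}

#' Generate a synthetic paired dataset
#'
#' @param design a \code{\link{syntheticDesign}}
#' @param dir optional directory; when given, writes
#'   \code{imaging.csv}, \code{omics.csv} and \code{manifest.csv} there
#' @return list with \code{imaging} and \code{omics} \code{FeatureTable}s
#'   and \code{manifest}, a data.frame of planted (label, feature, effect)
#'   triples
#' @export
generateSynthetic <- function(design, dir = NULL) {
  stopifnot(inherits(design, "SyntheticDesign"))
  d <- design
  out <- withSeed(d$seed, {
    ids <- sprintf("S%03d", seq_len(d$nSamples))
    X <- matrix(stats::rnorm(d$nSamples * d$nImaging), d$nSamples, d$nImaging,
                dimnames = list(ids, sprintf("IMG%02d", seq_len(d$nImaging))))
    Y <- matrix(stats::runif(d$nSamples * d$nOmics), d$nSamples, d$nOmics,
                dimnames = list(ids, sprintf("GENE%02d", seq_len(d$nOmics))))
    for (j in seq_len(d$nPlanted)) {
      raw <- X[, seq_len(d$nInformative), drop = FALSE] %*% d$effect[j, ] +
        stats::rnorm(d$nSamples, sd = d$noiseSD)
      Y[, j] <- (raw - min(raw)) / (max(raw) - min(raw))
    }
    list(X = X, Y = Y)
  })
  drv <- apply(d$effect, 1L, which.max)
  manifest <- data.frame(
    label = colnames(out$Y)[seq_len(d$nPlanted)],
    feature = colnames(out$X)[drv],
    effect = d$effect[cbind(seq_len(d$nPlanted), drv)],
    stringsAsFactors = FALSE)
  res <- list(imaging = featureTable(out$X, "imaging"),
              omics = featureTable(out$Y, "omics"),
              manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeFeatureTable(res$imaging, file.path(dir, "imaging.csv"))
    writeFeatureTable(res$omics, file.path(dir, "omics.csv"))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  res
}

#' Generate a fully independent (null) paired dataset
#'
#' Every imaging feature and omics label is drawn independently, so any
#' apparent association is a false positive; used for permutation-test
#' calibration.
#'
#' @param nSamples,nFeatures,nLabels table dimensions
#' @param seed integer seed
#' @return list with \code{imaging} and \code{omics} \code{FeatureTable}s
#' @export
nullDataset <- function(nSamples = 60, nFeatures = 10, nLabels = 5,
                        seed = 1L) {
  if (min(nSamples, nFeatures, nLabels) < 1) stop("counts must be positive")
  withSeed(seed, {
    ids <- sprintf("S%03d", seq_len(nSamples))
    X <- matrix(stats::rnorm(nSamples * nFeatures), nSamples, nFeatures,
                dimnames = list(ids, sprintf("IMG%02d", seq_len(nFeatures))))
    Y <- matrix(stats::runif(nSamples * nLabels), nSamples, nLabels,
                dimnames = list(ids, sprintf("GENE%02d", seq_len(nLabels))))
    list(imaging = featureTable(X, "imaging"),
         omics = featureTable(Y, "omics"))
  })
}
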