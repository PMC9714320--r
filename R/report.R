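## Figures and the HTML report. Plots are plain PNG files written into the
## job directory and referenced by relative path from report.html.

.pngTo <- function(path, expr, width = 720, height = 560) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  expr
  path
}

.plotCorrelationHeatmap <- function(cr, dir) {
  r <- cr@r
  ord <- clusterOrder(r)
  m <- r[ord$rowOrder, ord$colOrder, drop = FALSE]
  file <- file.path(dir, "correlation_heatmap.png")
  .pngTo(file, {
    pal <- grDevices::hcl.colors(101, "RdBu", rev = TRUE)
    graphics::par(mar = c(7, 7, 2, 1))
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                    col = pal, zlim = c(-1, 1), axes = FALSE,
                    xlab = "", ylab = "",
                    main = "Clustered correlation matrix")
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
  })
  basename(file)
}

.scenarioPlots <- function(ev, yObs, yPred, dir) {
  files <- character()
  met <- ev$metrics
  vOK <- !is.na(met$v)
  f <- file.path(dir, "v_barplot.png")
  .pngTo(f, {
    graphics::par(mar = c(8, 4, 2, 1))
    graphics::barplot(met$v[vOK], names.arg = met$label[vOK], las = 2,
                      ylab = "RMSE : STDEV (v)", cex.names = 0.7,
                      main = "Prediction error relative to label spread")
    graphics::abline(h = 1, lty = 2)
  })
  files <- c(files, basename(f))

  keep <- which(vOK & met$v <= 1)   # only labels predicted better than the mean
  if (length(keep)) {
    f <- file.path(dir, "true_vs_predicted.png")
    .pngTo(f, {
      cols <- grDevices::hcl.colors(length(keep), "Dark 3")
      lim <- range(yObs[, keep], yPred[, keep])
      graphics::plot(NA, xlim = lim, ylim = lim, xlab = "observed",
                     ylab = "predicted",
                     main = "True vs predicted (labels with v <= 1)")
      for (i in seq_along(keep))
        graphics::points(yObs[, keep[i]], yPred[, keep[i]],
                         col = cols[i], pch = 19)
      graphics::abline(0, 1, lty = 2)
      graphics::legend("topleft", legend = met$label[keep], col = cols,
                       pch = 19, cex = 0.7, bty = "n")
    })
    files <- c(files, basename(f))
  }

  f <- file.path(dir, "auc_vs_dt.png")
  .pngTo(f, {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "decision threshold (dt)", ylab = "AUC",
                   main = "AUC across binarization thresholds")
    cols <- grDevices::hcl.colors(max(length(ev$curves), 2L), "Dark 3")
    for (i in seq_along(ev$curves)) {
      cv <- ev$curves[[i]]
      graphics::lines(cv$dt, cv$AUC, col = cols[i], type = "b", pch = 20)
    }
    graphics::abline(h = 0.5, lty = 3)
    graphics::legend("bottomleft", legend = names(ev$curves), col = cols,
                     lty = 1, cex = 0.6, bty = "n", ncol = 2)
  })
  c(files, basename(f))
}

.htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.htmlTable <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0L) return("<p><em>empty</em></p>")
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = digits,
                                                format = "g") else
    .htmlEscape(as.character(v))
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  paste0("<table><tr>",
         paste0("<th>", .htmlEscape(colnames(df)), "</th>", collapse = ""),
         "</tr>\n",
         paste(apply(cells, 1L, function(r)
           paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""),
                  "</tr>")), collapse = "\n"),
         "</table>")
}

.imgTag <- function(rel) {
  if (is.null(rel) || !length(rel)) return("")
  paste0("<img src=\"", rel, "\" style=\"max-width:100%\">",
         collapse = "\n")
}

.scenarioHTML <- function(sc, relPrefix = "") {
  if (is.null(sc)) return("<p><em>This scenario produced no surviving features and is empty.</em></p>")
  rel <- function(f) paste0(relPrefix, f)
  met <- sc$evaluation$metrics
  show <- met[, c("label", "MSE", "RMSE", "STDEV", "v", "R2_direct",
                  "R2_identity", "AUC", "dt_lo", "dt_hi")]
  cvdf <- data.frame(fold = seq_along(sc$model@cvScores),
                     neg_MSE = sc$model@cvScores)
  paste0(
    "<h3>", .htmlEscape(sc$scenario), "</h3>",
    "<p>Model: <b>", .htmlEscape(sc$model@spec@modelType), "</b>; ",
    length(sc$features), " features, ", length(sc$labels), " labels.</p>",
    "<h4>Cross-validation scores (negative MSE)</h4>", .htmlTable(cvdf),
    "<h4>Per-label test metrics</h4>", .htmlTable(show),
    .imgTag(vapply(sc$plotFiles, rel, character(1L))))
}

.permHTML <- function(sc, relPrefix = "") {
  if (is.null(sc)) return("<p><em>empty scenario</em></p>")
  if (!length(sc$gated))
    return(paste0("<h3>", .htmlEscape(sc$scenario),
                  "</h3><p>No label passed the test-phase gate.</p>"))
  files <- paste0(relPrefix,
                  sprintf("validation_permuts_%s.txt", sc$gated))
  paste0("<h3>", .htmlEscape(sc$scenario), "</h3>",
         .htmlTable(sc$significance),
         "<p>Raw permuted statistics: ",
         paste0("<a href=\"", files, "\">", .htmlEscape(basename(files)),
                "</a>", collapse = ", "),
         "</p>")
}

#' Render the job's HTML report
#'
#' Produces a single self-contained HTML document with five section
#' groups: (1) input summary, (2) clustered correlation heat maps,
#' (3) surviving features and train/test parameters, (4) model
#' interpretation (metrics, CV scores, v bar plot, true-vs-predicted
#' scatter for labels with v <= 1, AUC-vs-dt curves), and (5) permutation
#' ("validation permuts") summaries. Images and permutation files are
#' referenced by relative path within the job directory.
#'
#' @param results the list returned by \code{\link{runTrain}}
#' @param path output HTML path (inside the job directory)
#' @return the path, invisibly
#' @export
renderReport <- function(results, path) {
  s <- results$config@settings
  cr <- results$correlation
  survTab <- data.frame(
    kind = c("data features", "label features"),
    surviving = c(length(cr@survivingImaging), length(cr@survivingOmics)),
    total = c(nrow(cr@r), ncol(cr@r)))
  paramTab <- data.frame(
    parameter = c("correlation method", "correlation threshold",
                  "p correction", "adjusted-p threshold", "data role",
                  "label role", "train size", "test size", "normalization",
                  "scaler fit", "model type", "grid search", "cv folds",
                  "permutations", "seed"),
    value = as.character(c(s$correlationMethod, s$correlationThreshold,
                           s$pCorrection, s$pThreshold, s$dataRole,
                           s$labelRole, s$trainSize, s$testSize,
                           s$normalization, s$scalerFit, s$modelType,
                           s$gridSearch, s$cv, s$nPermutations, s$seed)))
  selHTML <- if (!is.null(results$scenarioB))
    paste0("<p>Model-selected features (second round): ",
           .htmlEscape(paste(results$scenarioB$features, collapse = ", ")),
           "</p>") else ""
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>Radiogenomic analysis report</title>",
    "<style>body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:3px 8px;font-size:0.85em}h2{border-bottom:2px solid #444}",
    "</style></head><body>",
    "<h1>Radiogenomic analysis report</h1>",

    "<h2>1. Input data</h2>",
    "<p>Matched samples common to both tables: <b>",
    results$nMatchedSamples, "</b>. Data features (X): ",
    nrow(cr@r), " ", .htmlEscape(s$dataRole),
    " features; labels (Y): ",
    ncol(cr@r), " label features. Normalization method: <b>",
    .htmlEscape(s$normalization), "</b> (fit: ",
    .htmlEscape(s$scalerFit), ").</p>",

    "<h2>2. Correlation heat maps</h2>",
    "<p>", .htmlEscape(s$correlationMethod), " correlation, ",
    .htmlEscape(s$pCorrection), "-adjusted; |r| threshold ",
    s$correlationThreshold, ", adjusted p &lt; ", s$pThreshold, ".</p>",
    .imgTag(results$heatmapFile),

    "<h2>3. Surviving features and training/testing parameters</h2>",
    .htmlTable(survTab), selHTML, .htmlTable(paramTab),

    "<h2>4. Model interpretation</h2>",
    .scenarioHTML(results$scenarioA, ""),
    .scenarioHTML(results$scenarioB, "FeaturesSelFromModel/"),

    "<h2>5. Permutation tests (validation permuts)</h2>",
    .permHTML(results$scenarioA, ""),
    .permHTML(results$scenarioB, "FeaturesSelFromModel/"),

    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
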