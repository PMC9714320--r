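## Small in-code fixtures shared across test files.

makeTable <- function(m, role = "imaging", ids = NULL, feats = NULL) {
  if (is.null(ids))
    ids <- if (!is.null(rownames(m))) rownames(m) else
      sprintf("S%d", seq_len(nrow(m)))
  if (is.null(feats))
    feats <- if (!is.null(colnames(m))) colnames(m) else
      sprintf("F%d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, feats)
  featureTable(m, role)
}

randomTable <- function(n, p, role = "imaging", seed = 1) {
  set.seed(seed)
  makeTable(matrix(rnorm(n * p), n, p), role,
            feats = sprintf("%s%d", toupper(substr(role, 1, 3)), seq_len(p)))
}

writeTempCSV <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

## Brute-force pairwise AUC: (#concordant + 0.5 * #tied) / (n_pos * n_neg)
bruteAUC <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Brute-force step-up/step-down multiple-testing adjustments
bruteAdjust <- function(p, method) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- switch(method,
    bonferroni = pmin(1, p * m),
    holm = {
      a <- cummax(pmin(1, (m - seq_len(m) + 1) * ps))
      out <- numeric(m); out[o] <- a; out
    },
    hochberg = {
      a <- rev(cummin(rev(pmin(1, (m - seq_len(m) + 1) * ps))))
      out <- numeric(m); out[o] <- a; out
    },
    BH = {
      a <- rev(cummin(rev(pmin(1, m / seq_len(m) * ps))))
      out <- numeric(m); out[o] <- a; out
    },
    BY = {
      cm <- sum(1 / seq_len(m))
      a <- rev(cummin(rev(pmin(1, cm * m / seq_len(m) * ps))))
      out <- numeric(m); out[o] <- a; out
    })
  adj
}
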