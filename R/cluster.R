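#' Hierarchical clustering of the index battery
#'
#' Ward-D2 hierarchical clustering on the correlation-derived distance
#' `sqrt(2 (1 - r))`. By default signed correlations are used, so
#' anti-correlated indices (e.g. randomness- vs predictability-oriented
#' ones) end up distant; set `absolute = TRUE` to cluster on `|r|` instead.
#' Missing correlations are imputed by the column mean (off-diagonal) with a
#' warning.
#'
#' @param corr Correlation matrix.
#' @param k Number of flat clusters to cut (default 2).
#' @param absolute Use `|r|` instead of signed correlations.
#' @return Object of class `ward_clusters`: list with `hclust` (the
#'   dendrogram), `clusters` (named integer vector, the flat cut), `k`,
#'   `distance` ("signed" or "absolute").
#' @export
ward_clustering <- function(corr, k = 2L, absolute = FALSE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (anyNA(corr)) {
    warning("ward_clustering: missing correlations imputed by column means",
            call. = FALSE)
    for (j in seq_len(ncol(corr))) {
      bad <- is.na(corr[, j])
      corr[bad, j] <- mean(corr[, j], na.rm = TRUE)
    }
    corr <- (corr + t(corr)) / 2
    diag(corr) <- 1
  }
  r <- if (absolute) abs(corr) else corr
  d <- stats::as.dist(sqrt(pmax(2 * (1 - r), 0)))
  hc <- stats::hclust(d, method = "ward.D2")
  k <- min(as.integer(k), ncol(corr))
  structure(list(hclust = hc, clusters = stats::cutree(hc, k = k), k = k,
                 distance = if (absolute) "absolute" else "signed"),
            class = "ward_clusters")
}

#' @export
print.ward_clusters <- function(x, ...) {
  cat(sprintf("Ward-D2 clustering (%s correlation distance): %d leaves, cut at k = %d\n",
              x$distance, length(x$clusters), x$k))
  print(split(names(x$clusters), x$clusters))
  invisible(x)
}

#' @export
plot.ward_clusters <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = "Index battery dendrogram (Ward D2)", ...)
  invisible(x)
}

#' Correlation network edges
#'
#' Undirected edges between battery members whose absolute correlation
#' exceeds the threshold; edge weight is the signed correlation.
#'
#' @param corr Correlation matrix.
#' @param threshold Absolute-correlation cutoff (default 0.6).
#' @return data.frame with columns `from`, `to`, `r`.
#' @export
network_edges <- function(corr, threshold = 0.6) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            threshold >= 0, threshold <= 1)
  nm <- colnames(corr)
  ij <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  data.frame(from = nm[ij[, 1]], to = nm[ij[, 2]],
             r = corr[ij], stringsAsFactors = FALSE)
}
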