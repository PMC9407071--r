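#' Variance of the battery explained by a subset
#'
#' Operationalizes "variance explained" as the mean, over every index
#' column, of the R-squared from an ordinary-least-squares regression of
#' that column on the subset. Computed from the correlation matrix
#' (equivalent to regressions on standardized columns); singular subsets are
#' handled with a pseudoinverse, so collinear members simply add no
#' explanatory power.
#'
#' @param corr Correlation matrix of the full battery.
#' @param subset Character vector of column names in `corr`.
#' @return Scalar in [0, 1]: mean R-squared across all columns.
#' @export
variance_explained <- function(corr, subset) {
  stopifnot(all(subset %in% colnames(corr)))
  if (length(subset) == 0L) return(0)
  Rss <- corr[subset, subset, drop = FALSE]
  Rinv <- tryCatch(solve(Rss), error = function(e) MASS::ginv(Rss))
  r2 <- vapply(colnames(corr), function(y) {
    if (y %in% subset) return(1)
    ry <- corr[subset, y]
    min(max(drop(crossprod(ry, Rinv %*% ry)), 0), 1)
  }, numeric(1))
  mean(r2)
}

#' Greedy variance-explained ordering of an index subset
#'
#' Orders the members of `subset` by greedy forward selection: at each step
#' the candidate with the largest marginal gain in battery variance
#' explained ([variance_explained()]) is placed next. A collinear candidate
#' adding (numerically) nothing is still placed, with gain ~0. Cumulative
#' relative runtime per step is attached when the index matrix carries
#' battery timings.
#'
#' @param m An `index_matrix`, or a correlation matrix of the battery.
#' @param subset Names of the candidate indices (default: all index
#'   columns). Rows with missing values in the index columns are dropped for
#'   the correlation stage (reported via a message).
#' @return Object of class `selection_result`: data.frame with columns
#'   `step`, `index`, `gain`, `cum_variance` (percent of battery variance
#'   explained) and `cum_runtime` (NA when timings are unavailable).
#' @export
greedy_variance_ordering <- function(m, subset = NULL) {
  if (inherits(m, "index_matrix")) {
    X <- analysis_matrix(m, covariates = FALSE)
    complete <- stats::complete.cases(X)
    if (!all(complete))
      message(sprintf("greedy_variance_ordering: dropped %d rows with missing index values",
                      sum(!complete)))
    corr <- stats::cor(X[complete, , drop = FALSE])
    runtimes <- median_runtimes(m)
  } else {
    stopifnot(is.matrix(m), nrow(m) == ncol(m))
    corr <- m
    runtimes <- NULL
  }
  if (is.null(subset)) subset <- colnames(corr)
  stopifnot(all(subset %in% colnames(corr)))
  if (nrow(corr) * 10L > 0L && inherits(m, "index_matrix") &&
      sum(stats::complete.cases(analysis_matrix(m, FALSE))) < 10L * length(subset))
    warning("greedy_variance_ordering: fewer than 10 rows per candidate",
            call. = FALSE)
  remaining <- subset
  chosen <- character(0)
  gains <- cum_var <- numeric(0)
  current <- 0
  while (length(remaining) > 0L) {
    cand_var <- vapply(remaining, function(cc)
      variance_explained(corr, c(chosen, cc)), numeric(1))
    best <- which.max(cand_var)
    gain <- cand_var[best] - current
    if (gain <= .Machine$double.eps^0.5)
      message(sprintf("greedy_variance_ordering: '%s' adds no gain (collinear), placed with gain 0",
                      remaining[best]))
    chosen <- c(chosen, remaining[best])
    current <- cand_var[best]
    gains <- c(gains, max(gain, 0))
    cum_var <- c(cum_var, current)
    remaining <- remaining[-best]
  }
  out <- data.frame(step = seq_along(chosen), index = chosen,
                    gain = gains, cum_variance = 100 * cum_var,
                    stringsAsFactors = FALSE)
  out$cum_runtime <- if (!is.null(runtimes) && all(chosen %in% names(runtimes)))
    cumsum(runtimes[chosen]) else NA_real_
  rownames(out) <- NULL
  structure(out, class = c("selection_result", "data.frame"))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Greedy variance-explained ordering\n")
  print(as.data.frame(x), digits = 4, ...)
  invisible(x)
}

#' @export
plot.selection_result <- function(x, ...) {
  plot(x$step, x$cum_variance, type = "b", pch = 19, ylim = c(0, 100),
       xlab = "Indices selected", ylab = "Battery variance explained (%)",
       main = "Cumulative variance explained by greedy selection", ...)
  invisible(x)
}

#' Expected-value profiles of selected indices
#'
#' Mean value of each selected index per signal family, noise color and
#' intensity bin: the summary used to inspect what each index responds to
#' (e.g. line length rising monotonically with noise intensity for every
#' family). Empty family x color x bin combinations yield NA with a warning.
#'
#' @param m An `index_matrix`.
#' @param selection Index column names to profile (default: the battery's
#'   [selected_indices()] that are present).
#' @param n_bins Number of equal-width intensity bins.
#' @return data.frame with columns `index`, `family`, `beta`, `bin`,
#'   `intensity_mid`, `value` (one row per combination).
#' @export
expected_value_profiles <- function(m, selection = NULL, n_bins = 8L) {
  stopifnot(inherits(m, "index_matrix"))
  idx <- attr(m, "index_cols")
  if (is.null(selection)) selection <- intersect(selected_indices(), idx)
  stopifnot(all(selection %in% idx))
  df <- as.data.frame(m)
  br <- seq(min(df$intensity), max(df$intensity), length.out = n_bins + 1L)
  df$bin <- pmin(pmax(findInterval(df$intensity, br, rightmost.closed = TRUE),
                      1L), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  combos <- expand.grid(index = selection, family = unique(df$family),
                        beta = sort(unique(df$beta)), bin = seq_len(n_bins),
                        stringsAsFactors = FALSE)
  combos$intensity_mid <- mids[combos$bin]
  combos$value <- mapply(function(ix, fam, be, bn) {
    v <- df[df$family == fam & df$beta == be & df$bin == bn, ix]
    if (length(v) == 0L) NA_real_ else mean(v, na.rm = TRUE)
  }, combos$index, combos$family, combos$beta, combos$bin)
  if (anyNA(combos$value))
    warning("expected_value_profiles: empty combinations yield NA",
            call. = FALSE)
  combos
}
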