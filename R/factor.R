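#' Choose the number of latent factors
#'
#' Agreement across a fixed panel of estimators applied to the correlation
#' matrix: Horn's parallel analysis, the Kaiser criterion (eigenvalues > 1),
#' the acceleration factor of the scree (largest second difference), and
#' Velicer's minimum average partial (MAP). The mode of the four suggestions
#' is returned; ties are broken toward the smaller count. If no value
#' repeats, the parallel-analysis suggestion is used (reported via a
#' message). A correlation matrix with no shared variance (e.g. the
#' identity) returns 1 by convention, the minimal usable factor count.
#'
#' @param corr Correlation matrix. Non-positive-semidefinite input is
#'   repaired by clipping negative eigenvalues (with a message).
#' @param n_obs Number of observations behind `corr` (needed by parallel
#'   analysis).
#' @param n_sim Simulated datasets for parallel analysis.
#' @param seed Seed for the parallel-analysis simulation.
#' @return Integer >= 1, with attribute `panel` (the four suggestions).
#' @export
choose_n_factors <- function(corr, n_obs, n_sim = 30L, seed = 1L) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr), n_obs > nrow(corr))
  p <- ncol(corr)
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    message("choose_n_factors: input not PSD, clipping negative eigenvalues")
    v <- pmax(ev$values, 0)
    corr <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    d <- sqrt(diag(corr))
    corr <- corr / outer(d, d)
    ev <- eigen(corr, symmetric = TRUE)
  }
  lambda <- ev$values

  # Horn's parallel analysis: eigenvalues above the mean of those from
  # random normal data of the same dimensions
  set.seed(seed)
  sim <- replicate(n_sim,
                   eigen(stats::cor(matrix(stats::rnorm(n_obs * p), n_obs, p)),
                         symmetric = TRUE, only.values = TRUE)$values)
  pa <- sum(lambda > rowMeans(sim))

  kaiser <- sum(lambda > 1)

  # acceleration factor: sharpest elbow of the scree
  af <- if (p >= 3) {
    acc <- lambda[1:(p - 2)] - 2 * lambda[2:(p - 1)] + lambda[3:p]
    which.max(acc)  # elbow at i+1 => keep i factors
  } else 1L

  map <- velicer_map(corr)

  panel <- c(parallel = pa, kaiser = kaiser, acceleration = af, map = map)
  cnt <- table(panel)
  best <- as.integer(names(cnt)[cnt == max(cnt)])
  k <- if (max(cnt) > 1) min(best) else {
    message("choose_n_factors: no agreement, falling back to parallel analysis")
    pa
  }
  structure(max(1L, as.integer(k)), panel = panel)
}

# Velicer's minimum average partial criterion
velicer_map <- function(corr) {
  p <- ncol(corr)
  ev <- eigen(corr, symmetric = TRUE)
  avg_sq <- numeric(p - 1L)
  # k = 0: average squared off-diagonal correlation
  avg_sq0 <- (sum(corr^2) - p) / (p * (p - 1))
  for (k in seq_len(p - 1L)) {
    L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
    Rstar <- corr - tcrossprod(L)
    d <- sqrt(pmax(diag(Rstar), .Machine$double.eps))
    Pk <- Rstar / outer(d, d)
    avg_sq[k] <- (sum(Pk^2) - sum(diag(Pk)^2)) / (p * (p - 1))
  }
  all_avg <- c(avg_sq0, avg_sq)
  which.min(all_avg) - 1L  # 0 means "no factors"
}

#' Fit an orthogonal factor model with varimax rotation
#'
#' Principal-axis factoring on the correlation matrix (iterated
#' communalities, starting from squared multiple correlations) followed by
#' varimax rotation. For every variable the dominant factor (largest
#' absolute rotated loading, ties broken toward the earlier factor) and the
#' archetypicity are reported. Archetypicity is
#' `1 / exp(H)` where `H` is the Shannon entropy of the variable's
#' normalized squared-loading profile: it equals 1 exactly when the variable
#' loads on a single factor and decreases toward `1/k` as the loadings
#' spread over k factors.
#'
#' @param x An `index_matrix`, a numeric data matrix, or a correlation
#'   matrix (square, unit diagonal).
#' @param n_factors Number of factors (>= 1, less than the number of
#'   variables). Defaults to [choose_n_factors()].
#' @param covariates For `index_matrix` input, include covariate columns.
#' @param n_obs Number of observations (required when `x` is a correlation
#'   matrix and `n_factors` is not given).
#' @param max_iter,tol Iteration control for the communality loop.
#' @return Object of class `complexity_fa`: list with `loadings`
#'   (variables x factors, varimax-rotated), `n_factors`, `rotation`,
#'   `variance_explained` (proportion of total variance per factor),
#'   `dominant` (named factor index per variable), `archetypicity`,
#'   `communalities`, `iterations`.
#' @export
fit_factor_model <- function(x, n_factors = NULL, covariates = TRUE,
                             n_obs = NULL, max_iter = 200L, tol = 1e-6) {
  if (inherits(x, "index_matrix")) {
    X <- analysis_matrix(x, covariates)
    corr <- pearson_matrix(X)
    n_obs <- nrow(X)
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             all(abs(diag(x) - 1) < 1e-12) && max(abs(x), na.rm = TRUE) <= 1 + 1e-12) {
    corr <- x
  } else {
    X <- as.matrix(x)
    corr <- pearson_matrix(X)
    n_obs <- nrow(X)
  }
  if (anyNA(corr))
    stop("fit_factor_model: correlation matrix contains NA", call. = FALSE)
  p <- ncol(corr)
  if (is.null(n_factors)) {
    if (is.null(n_obs))
      stop("fit_factor_model: n_obs needed to choose the factor count",
           call. = FALSE)
    n_factors <- choose_n_factors(corr, n_obs)
  }
  k <- as.integer(n_factors)
  if (k < 1L || k >= p)
    stop("fit_factor_model: n_factors must be in [1, p)", call. = FALSE)

  # starting communalities: squared multiple correlations
  h2 <- tryCatch(1 - 1 / diag(solve(corr)),
                 error = function(e) apply(abs(corr - diag(p)), 1L, max))
  h2 <- pmin(pmax(h2, 0.05), 0.995)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Rh <- corr
    diag(Rh) <- h2
    ev <- eigen(Rh, symmetric = TRUE)
    L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
    h2_new <- pmin(rowSums(L^2), 0.9999)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf(
        "fit_factor_model: communality iteration did not converge (%d iterations, last change %.2e)",
        iter, delta), call. = FALSE)
  }
  Lr <- if (k > 1L) {
    rot <- stats::varimax(L, normalize = TRUE)
    L %*% rot$rotmat
  } else L
  rownames(Lr) <- colnames(corr)
  colnames(Lr) <- paste0("F", seq_len(k))
  dominant <- apply(abs(Lr), 1L, which.max)
  arch <- apply(Lr, 1L, function(l) {
    p2 <- l^2 / sum(l^2)
    1 / exp(entropy_from_probs(p2))
  })
  structure(list(loadings = Lr, n_factors = k, rotation = "varimax",
                 variance_explained = colSums(Lr^2) / p,
                 dominant = dominant, archetypicity = arch,
                 communalities = rowSums(Lr^2), iterations = iter),
            class = "complexity_fa")
}

#' @export
print.complexity_fa <- function(x, ...) {
  cat(sprintf("Factor model: %d factors (varimax), %.1f%% of total variance\n",
              x$n_factors, 100 * sum(x$variance_explained)))
  cat(sprintf("  converged in %d communality iterations\n", x$iterations))
  tab <- data.frame(dominant = paste0("F", x$dominant),
                    archetypicity = round(x$archetypicity, 3))
  print(tab, ...)
  invisible(x)
}

#' @export
coef.complexity_fa <- function(object, ...) object$loadings

#' @export
summary.complexity_fa <- function(object, ...) {
  cat(sprintf("Varimax factor model with %d factors\n", object$n_factors))
  cat("Variance explained per factor (proportion of total):\n")
  print(round(object$variance_explained, 4))
  cat("\nLoadings (|loading| < 0.2 blanked):\n")
  L <- round(object$loadings, 2)
  Lc <- format(L)
  Lc[abs(L) < 0.2] <- "."
  print(Lc, quote = FALSE)
  invisible(object)
}
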