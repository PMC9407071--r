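#' Approximate entropy (ApEn)
#'
#' Regularity statistic of Pincus: phi(m) - phi(m + 1), where phi(m) is the
#' mean log proportion of template pairs within Chebyshev tolerance `r` at
#' embedding dimension m (self-matches included).
#'
#' @param x Numeric series.
#' @param m Template length.
#' @param r Tolerance; defaults to 0.2 sd(x).
#' @return Scalar >= 0.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (!is.finite(r) || r <= 0)
    stop("approximate_entropy: tolerance must be > 0", call. = FALSE)
  phi <- function(mm) {
    E <- delay_embed(x, mm, 1L)
    n <- nrow(E)
    cnt <- cheb_counts(E, r)
    mean(log(cnt / n))
  }
  phi(m) - phi(m + 1L)
}

# per-row count of rows within Chebyshev distance r (self included)
cheb_counts <- function(E, r) {
  n <- nrow(E)
  within <- matrix(TRUE, n, n)
  for (j in seq_len(ncol(E)))
    within <- within & abs(outer(E[, j], E[, j], "-")) <= r
  rowSums(within)
}

#' Sample entropy (SampEn)
#'
#' -log(A / B), where B is the number of template pairs (i != j) within
#' Chebyshev tolerance `r` at dimension m and A the number still within
#' tolerance at m + 1. Self-matches excluded.
#'
#' @inheritParams approximate_entropy
#' @return Scalar >= 0; degenerate (A or B zero) raises an error.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (!is.finite(r) || r <= 0)
    stop("sample_entropy: tolerance must be > 0", call. = FALSE)
  n_t <- length(x) - m  # same number of templates at both dimensions
  pairs <- function(mm) {
    E <- delay_embed(x, mm, 1L)[seq_len(n_t), , drop = FALSE]
    sum(cheb_counts(E, r)) - n_t  # exclude self-matches
  }
  B <- pairs(m)
  A <- pairs(m + 1L)
  if (B == 0 || A == 0)
    stop("sample_entropy: no matching templates (degenerate input)",
         call. = FALSE)
  -log(A / B)
}

#' Dispersion entropy (DispEn)
#'
#' The series is mapped through the normal cumulative distribution function
#' to (0, 1), discretized into `n_classes` classes, and the Shannon entropy
#' (natural log) of the embedded class-pattern distribution is computed,
#' normalized by `log(n_classes^m)`.
#'
#' @inheritParams delay_embed
#' @param n_classes Number of dispersion classes.
#' @return Scalar in [0, 1].
#' @export
dispersion_entropy <- function(x, m = 3L, tau = 1L, n_classes = 6L) {
  s <- stats::sd(x)
  if (s == 0)
    stop("dispersion_entropy: zero-variance input", call. = FALSE)
  y <- stats::pnorm(x, mean = mean(x), sd = s)
  z <- pmin(pmax(ceiling(y * n_classes), 1L), n_classes)
  E <- delay_embed(z, m, tau)
  code <- as.vector(E %*% n_classes^(0:(m - 1L)))
  p <- tabulate(match(code, unique(code)))
  entropy_from_probs(p / sum(p)) / log(n_classes^m)
}

#' Binned Shannon entropy (ShanEn)
#'
#' Shannon entropy (natural log) of the histogram of values over
#' `n_bins` equal-width bins spanning the range of the series.
#'
#' @param x Numeric series.
#' @param n_bins Number of histogram bins.
#' @return Scalar in [0, log(n_bins)].
#' @export
shannon_entropy_binned <- function(x, n_bins = 10L) {
  if (diff(range(x)) == 0)
    stop("shannon_entropy_binned: constant series", call. = FALSE)
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  entropy_from_probs(cnt / sum(cnt))
}

#' Higuchi fractal dimension
#'
#' Slope-based fractal dimension from mean curve lengths L(k) over
#' subsampled series at lags k = 1..k_max; the dimension is the negative
#' slope of log L(k) versus log k.
#'
#' @param x Numeric series.
#' @param k_max Largest lag.
#' @return Scalar, about 1.5 for a random walk and 2 for white noise.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  n <- length(x)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m0) {
      idx <- seq(m0, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      (sum(abs(diff(x[idx]))) * (n - 1)) / (k * (length(idx) - 1L) * k)
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  k <- seq_len(k_max)
  -stats::coef(stats::lm(log(lk) ~ log(k)))[[2]]
}

#' Katz fractal dimension
#'
#' log10(n) / (log10(n) + log10(d / L)) with L the total curve length
#' (sum of absolute successive differences), d the maximum distance from the
#' first point, and n the number of steps.
#'
#' @param x Numeric series.
#' @return Scalar >= 1.
#' @export
katz_fd <- function(x) {
  L <- sum(abs(diff(x)))
  if (L == 0) stop("katz_fd: constant series", call. = FALSE)
  d <- max(abs(x - x[1]))
  n <- length(x) - 1L
  log10(n) / (log10(d / L) + log10(n))
}

#' Petrosian fractal dimension
#'
#' log10(n) / (log10(n) + log10(n / (n + 0.4 N_delta))) where N_delta is
#' the number of sign changes of the first difference.
#'
#' @param x Numeric series.
#' @return Scalar close to 1.
#' @export
petrosian_fd <- function(x) {
  d <- diff(x)
  nd <- sum(diff(sign(d)) != 0)
  n <- length(x)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Entropy of entropy (EnofEn)
#'
#' The series is split into non-overlapping windows; within each window the
#' values are discretized over `n_slices` equal-width slices of the global
#' range and a Shannon entropy computed. The index is the Shannon entropy
#' (natural log) of the distribution of the window entropies, discretized
#' over `n_slices` equal-width levels of their own range. Captures how
#' variable the short-time disorder of the signal is.
#'
#' @param x Numeric series.
#' @param window Window length in samples.
#' @param n_slices Number of amplitude slices (and entropy levels).
#' @return Scalar >= 0.
#' @export
entropy_of_entropy <- function(x, window = 10L, n_slices = 10L) {
  n_win <- length(x) %/% window
  if (n_win < 2L)
    stop("entropy_of_entropy: need at least 2 windows", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0)
    stop("entropy_of_entropy: constant series", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_slices + 1L)
  w <- matrix(x[seq_len(n_win * window)], nrow = window)
  hs <- apply(w, 2L, function(v) {
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_slices)
    entropy_from_probs(cnt / sum(cnt))
  })
  if (diff(range(hs)) == 0) return(0)
  hbr <- seq(min(hs), max(hs), length.out = n_slices + 1L)
  cnt <- tabulate(findInterval(hs, hbr, rightmost.closed = TRUE), n_slices)
  entropy_from_probs(cnt / sum(cnt))
}
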