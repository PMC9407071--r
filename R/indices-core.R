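#' Delay embedding matrix
#'
#' Rows are the embedded vectors (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}).
#'
#' @param x Numeric series.
#' @param m Embedding dimension (>= 2).
#' @param tau Time delay in samples (>= 1).
#' @return Matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @export
delay_embed <- function(x, m, tau = 1L) {
  if (m < 2L || tau < 1L)
    stop("delay_embed: need m >= 2 and tau >= 1", call. = FALSE)
  n <- length(x) - (m - 1L) * tau
  if (n < 1L)
    stop("delay_embed: embedding infeasible, (m-1)*tau >= length", call. = FALSE)
  out <- vapply(0:(m - 1L), function(j) x[(1L + j * tau):(n + j * tau)],
                numeric(n))
  matrix(out, nrow = n, ncol = m)
}

#' Ordinal patterns and weights of a series
#'
#' The shared kernel of the permutation-entropy family. Each embedded vector
#' is reduced to its rank pattern; ties are broken by position (the earlier
#' element ranks lower), so the pattern is always a valid permutation. The
#' weight of a vector is its population variance, as used by weighted
#' permutation entropy.
#'
#' @inheritParams delay_embed
#' @return List with `pattern` (integer codes, one per embedded vector; equal
#'   codes = identical rank patterns), `weight` (numeric, same length) and
#'   `n_patterns` (`factorial(m)`, the number of possible patterns).
#' @export
ordinal_patterns <- function(x, m = 3L, tau = 1L) {
  E <- delay_embed(x, m, tau)
  n <- nrow(E)
  # rank of column j among the m entries, stable in position
  code <- integer(n)
  for (j in seq_len(m)) {
    rj <- rep(1L, n)
    for (k in seq_len(m)) {
      if (k == j) next
      lt <- E[, k] < E[, j]
      if (k < j) lt <- lt | (E[, k] == E[, j])
      rj <- rj + lt
    }
    code <- code + (rj - 1L) * m^(j - 1L)
  }
  mu <- rowMeans(E)
  w <- rowMeans((E - mu)^2)
  list(pattern = code, weight = w, n_patterns = factorial(m))
}

entropy_from_probs <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the ordinal-pattern distribution.
#'
#' @inheritParams delay_embed
#' @param normalize Divide by `log(factorial(m))` so the value lies in
#'   [0, 1].
#' @return Scalar entropy.
#' @export
permutation_entropy <- function(x, m = 3L, tau = 1L, normalize = TRUE) {
  op <- ordinal_patterns(x, m, tau)
  p <- tabulate(match(op$pattern, unique(op$pattern)))
  h <- entropy_from_probs(p / sum(p))
  if (normalize) h / log(factorial(m)) else h
}

#' Weighted permutation entropy
#'
#' Shannon entropy (natural log) of the ordinal-pattern distribution in
#' which each embedded vector contributes its variance as weight, so
#' patterns carried by large-amplitude excursions dominate.
#'
#' @inheritParams permutation_entropy
#' @return Scalar entropy; 0 for a strictly monotone series (single
#'   pattern).
#' @export
weighted_permutation_entropy <- function(x, m = 3L, tau = 1L,
                                         normalize = TRUE) {
  op <- ordinal_patterns(x, m, tau)
  tot <- sum(op$weight)
  if (tot == 0)
    stop("weighted_permutation_entropy: zero total weight (constant series)",
         call. = FALSE)
  w <- vapply(split(op$weight, op$pattern), sum, numeric(1))
  h <- entropy_from_probs(w / tot)
  if (normalize) h / log(factorial(m)) else h
}

#' Conditional weighted permutation entropy (CWPEn)
#'
#' Difference between the unnormalized weighted permutation entropy at
#' embedding dimension `m + 1` and at `m` (same delay). Measures the extra
#' ordinal uncertainty revealed by lengthening the embedding by one sample;
#' near 0 for deterministic or monotone series, positive for noise.
#'
#' @inheritParams delay_embed
#' @return Scalar.
#' @export
cwpen <- function(x, m = 3L, tau = 1L) {
  weighted_permutation_entropy(x, m + 1L, tau, normalize = FALSE) -
    weighted_permutation_entropy(x, m, tau, normalize = FALSE)
}

#' Bubble-sort swap counts of embedded vectors
#'
#' Number of swaps bubble sort needs to order each embedded vector
#' ascending, i.e. the number of inversions (pairs out of order).
#'
#' @inheritParams delay_embed
#' @return Integer vector, one count per embedded vector, each in
#'   [0, m(m-1)/2].
#' @export
swap_counts <- function(x, m, tau = 1L) {
  E <- delay_embed(x, m, tau)
  cnt <- integer(nrow(E))
  for (j in seq_len(m - 1L))
    for (k in (j + 1L):m)
      cnt <- cnt + (E[, j] > E[, k])
  cnt
}

renyi2 <- function(counts) {
  p <- counts / sum(counts)
  -log(sum(p^2))
}

#' Bubble entropy (BubbEn)
#'
#' Permutation-family index that replaces the full rank pattern by the
#' number of bubble-sort swaps each embedded vector needs. The index is the
#' difference of Renyi-2 entropies of the swap-count distributions at
#' dimensions `m + 1` and `m`, normalized by `log((m + 1) / (m - 1))`.
#' Degenerate distributions (all swap counts equal, e.g. any monotone
#' series) give 0.
#'
#' @inheritParams delay_embed
#' @return Scalar.
#' @export
bubble_entropy <- function(x, m = 3L, tau = 1L) {
  h <- function(mm) {
    s <- swap_counts(x, mm, tau)
    renyi2(tabulate(s + 1L, nbins = mm * (mm - 1L) / 2L + 1L))
  }
  (h(m + 1L) - h(m)) / log((m + 1) / (m - 1))
}

#' Coarse-grain a series
#'
#' Means of consecutive non-overlapping windows of `scale` samples, the
#' standard multiscale-entropy coarse-graining. Output length is
#' `floor(length(x) / scale)`; trailing samples that do not fill a window
#' are dropped.
#'
#' @param x Numeric series.
#' @param scale Integer window length >= 1.
#' @return Numeric vector of the window means.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("coarse_grain: scale must be >= 1", call. = FALSE)
  if (scale > length(x))
    stop("coarse_grain: scale exceeds series length", call. = FALSE)
  if (scale == 1L) return(x)
  n <- (length(x) %/% scale) * scale
  colMeans(matrix(x[seq_len(n)], nrow = scale))
}

#' Default multiscale range
#'
#' Scales 1 to min(20, length/100), so every coarse-grained sub-series keeps
#' at least 100 points.
#'
#' @param n Series length.
#' @return Integer vector of scales.
#' @export
default_scales <- function(n) seq_len(max(1L, min(20L, n %/% 100L)))

#' Multiscale weighted permutation entropy (MSWPEn)
#'
#' Mean of the normalized weighted permutation entropy over coarse-grained
#' versions of the series. Scales at which the embedding is infeasible are
#' skipped with a warning; if no scale is feasible an error is raised.
#'
#' @inheritParams delay_embed
#' @param scales Integer vector of coarse-graining scales; defaults to
#'   [default_scales()].
#' @return Scalar in [0, 1].
#' @export
mswpen <- function(x, m = 3L, tau = 1L, scales = default_scales(length(x))) {
  vals <- numeric(0)
  for (s in scales) {
    xs <- tryCatch(coarse_grain(x, s), error = function(e) NULL)
    if (is.null(xs) || length(xs) <= (m - 1L) * tau + 1L) {
      warning(sprintf("mswpen: scale %d infeasible, skipped", s),
              call. = FALSE)
      next
    }
    vals <- c(vals, weighted_permutation_entropy(xs, m, tau, normalize = TRUE))
  }
  if (length(vals) == 0L)
    stop("mswpen: no feasible scale", call. = FALSE)
  mean(vals)
}

#' Singular value decomposition entropy (SVDEn)
#'
#' Shannon entropy (natural log) of the singular values of the delay
#' embedding matrix, normalized to sum to 1. Quantifies how many orthogonal
#' modes an adequate representation of the reconstructed dynamics needs:
#' 0 for a rank-1 embedding, up to log(m) for isotropic noise.
#'
#' @inheritParams delay_embed
#' @return Scalar in [0, log(m)].
#' @export
svd_entropy <- function(x, m = 3L, tau = 1L) {
  E <- delay_embed(x, m, tau)
  s <- svd(E, nu = 0, nv = 0)$d
  if (sum(s) == 0)
    stop("svd_entropy: all-zero embedding matrix", call. = FALSE)
  entropy_from_probs(s / sum(s))
}

#' Line length (LL)
#'
#' Mean absolute consecutive difference, a linear-time simplification of
#' Katz' fractal dimension. Captures lag-1 fluctuation amplitude, hence is
#' primarily driven by high-frequency noise.
#'
#' @param x Numeric series of length >= 2.
#' @return Scalar >= 0 (0 for a constant series).
#' @export
line_length <- function(x) {
  if (length(x) < 2L) stop("line_length: need length >= 2", call. = FALSE)
  mean(abs(diff(x)))
}

#' Hjorth mobility
#'
#' `sqrt(var(diff(x)) / var(x))`, an estimate of the mean frequency of the
#' signal (in radians per sample, up to discretization).
#'
#' @param x Numeric series of length >= 3.
#' @return Scalar > 0.
#' @export
hjorth_mobility <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0)
    stop("hjorth_mobility: zero-variance input", call. = FALSE)
  d <- diff(x)
  vd <- stats::var(d)
  if (!is.finite(vd) || vd == 0)
    stop("hjorth_mobility: zero-variance first difference", call. = FALSE)
  sqrt(vd / v)
}

#' Hjorth complexity
#'
#' Ratio of the mobility of the first derivative to the mobility of the
#' signal, i.e. the mean frequency of the derivative over the mean frequency
#' of the signal. Equals 1 for a pure sinusoid (densely sampled) and grows
#' with bandwidth; white noise gives a markedly larger value.
#'
#' @param x Numeric series of length >= 4.
#' @return Scalar >= 1 up to discretization for smooth narrowband signals.
#' @export
hjorth_complexity <- function(x) {
  hjorth_mobility(diff(x)) / hjorth_mobility(x)
}

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(pos = integer(0), type = character(0)))
  mid <- 2:(n - 1L)
  is_max <- x[mid] > x[mid - 1L] & x[mid] > x[mid + 1L]
  is_min <- x[mid] < x[mid - 1L] & x[mid] < x[mid + 1L]
  pos <- mid[is_max | is_min]
  type <- ifelse(is_max[is_max | is_min], "max", "min")
  list(pos = pos, type = type)
}

#' Attention entropy (AttEn)
#'
#' Entropy of the intervals between local extrema (key patterns) of the
#' series rather than of the raw values. Strict local maxima and minima are
#' located; four interval families are formed — between successive maxima,
#' between successive minima, from a maximum to the following minimum, and
#' from a minimum to the following maximum — and the index is the mean of
#' the Shannon entropies (natural log) of the four interval-frequency
#' distributions. A strictly periodic alternation has all intervals equal
#' and scores 0; a monotone series has no interior extrema and is a
#' degenerate input.
#'
#' @param x Numeric series.
#' @return Scalar >= 0.
#' @export
attention_entropy <- function(x) {
  ex <- local_extrema(x)
  if (length(ex$pos) < 2L)
    stop("attention_entropy: fewer than 2 local extrema", call. = FALSE)
  maxima <- ex$pos[ex$type == "max"]
  minima <- ex$pos[ex$type == "min"]
  cross <- function(from, to) {
    # interval from each `from` extremum to the next `to` extremum
    if (length(from) == 0L || length(to) == 0L) return(numeric(0))
    idx <- findInterval(from, to) + 1L
    ok <- idx <= length(to)
    to[idx[ok]] - from[ok]
  }
  ivals <- list(max_max = diff(maxima), min_min = diff(minima),
                max_min = cross(maxima, minima),
                min_max = cross(minima, maxima))
  hs <- vapply(ivals, function(v) {
    if (length(v) == 0L) return(NA_real_)
    entropy_from_probs(table(v) / length(v))
  }, numeric(1))
  if (all(is.na(hs)))
    stop("attention_entropy: no extremum intervals", call. = FALSE)
  mean(hs, na.rm = TRUE)
}
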