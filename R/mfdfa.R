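#' Default MFDFA parameters
#'
#' Moment orders q in {-5..-1, 1..5} (0 excluded, where the generalized
#' average degenerates), 10 log-spaced window sizes from 10 to length/4, and
#' linear detrending.
#'
#' @param n Series length.
#' @return List with `q_orders`, `window_sizes`, `detrend_order`.
#' @export
mfdfa_params <- function(n) {
  list(q_orders = c(-5:-1, 1:5),
       window_sizes = log_spaced_windows(10L, max(12L, n %/% 4L), 10L),
       detrend_order = 1L)
}

log_spaced_windows <- function(min_s, max_s, k) {
  s <- unique(round(exp(seq(log(min_s), log(max_s), length.out = k))))
  as.integer(s[s >= min_s])
}

# RMS fluctuation^2 per segment at one window size, both sweep directions
segment_f2 <- function(profile, s, detrend_order) {
  n <- length(profile)
  k <- n %/% s
  t <- seq_len(s)
  X <- stats::poly(t, degree = detrend_order, raw = TRUE)
  X <- cbind(1, X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  seg <- cbind(matrix(profile[seq_len(k * s)], nrow = s),
               matrix(profile[(n - k * s + 1L):n], nrow = s))
  res <- seg - H %*% seg
  colMeans(res^2)
}

#' Multifractal detrended fluctuation analysis
#'
#' Computes the multifractal singularity spectrum of a series. The profile
#' (cumulative sum of the demeaned series) is split into non-overlapping
#' segments of each window size (sweeping from both ends), each segment is
#' polynomially detrended and its mean squared residual recorded. The
#' q-generalized fluctuation function F_q(s) = (mean F^2(v,s)^(q/2))^(1/q)
#' scales as s^h(q); h(q) are the generalized Hurst exponents. The mass
#' exponent is tau(q) = q h(q) - 1, the singularity strength alpha = dtau/dq
#' (finite differences) and the singularity dimension
#' f(alpha) = q alpha - tau(q).
#'
#' @param x Numeric series; length must be at least 4 times the largest
#'   window.
#' @param q_orders Moment orders, excluding a neighborhood of 0.
#' @param window_sizes Integer window sizes (log-spaced by default).
#' @param detrend_order Polynomial detrending order (1 = linear).
#' @return Object of class `singularity_spectrum`: list with `q`, `h_q`,
#'   `tau_q`, `alpha`, `f_alpha`, `window_sizes`, `log_fq` (matrix of
#'   log F_q(s) values).
#' @export
mfdfa_spectrum <- function(x,
                           q_orders = mfdfa_params(length(x))$q_orders,
                           window_sizes = mfdfa_params(length(x))$window_sizes,
                           detrend_order = 1L) {
  n <- length(x)
  if (any(abs(q_orders) < 1e-8))
    stop("mfdfa_spectrum: q orders must exclude 0", call. = FALSE)
  window_sizes <- as.integer(window_sizes)
  if (any(window_sizes < detrend_order + 2L))
    stop("mfdfa_spectrum: window sizes must be >= detrend_order + 2",
         call. = FALSE)
  if (n < 4L * max(window_sizes))
    stop("mfdfa_spectrum: series shorter than 4 x max window", call. = FALSE)
  if (length(window_sizes) < 3L)
    stop("mfdfa_spectrum: need at least 3 window sizes", call. = FALSE)
  if (stats::var(x) == 0)
    stop("mfdfa_spectrum: degenerate (zero-variance) series", call. = FALSE)
  profile <- cumsum(x - mean(x))
  nq <- length(q_orders)
  log_fq <- matrix(NA_real_, nrow = length(window_sizes), ncol = nq,
                   dimnames = list(window_sizes, q_orders))
  for (i in seq_along(window_sizes)) {
    f2 <- segment_f2(profile, window_sizes[i], detrend_order)
    if (all(f2 <= 0))
      stop(sprintf("mfdfa_spectrum: degenerate fluctuations at window %d",
                   window_sizes[i]), call. = FALSE)
    f2 <- pmax(f2, .Machine$double.xmin)
    for (j in seq_len(nq)) {
      q <- q_orders[j]
      log_fq[i, j] <- log(mean(f2^(q / 2))) / q
    }
  }
  ls <- log(window_sizes)
  h_q <- apply(log_fq, 2L, function(y) stats::coef(stats::lm(y ~ ls))[[2]])
  tau_q <- q_orders * h_q - 1
  if (nq >= 2L) {
    alpha <- finite_diff(tau_q, q_orders)
    f_alpha <- q_orders * alpha - tau_q
  } else {
    alpha <- f_alpha <- rep(NA_real_, nq)
  }
  structure(list(q = q_orders, h_q = h_q, tau_q = tau_q, alpha = alpha,
                 f_alpha = f_alpha, window_sizes = window_sizes,
                 log_fq = log_fq),
            class = "singularity_spectrum")
}

finite_diff <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2)
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

#' @export
print.singularity_spectrum <- function(x, ...) {
  cat("Multifractal singularity spectrum\n")
  cat(sprintf("  q in [%g, %g] (%d orders), windows %d..%d\n",
              min(x$q), max(x$q), length(x$q),
              min(x$window_sizes), max(x$window_sizes)))
  cat(sprintf("  h(2) = %.3f, spectrum width = %.3f\n",
              x$h_q[which.min(abs(x$q - 2))], max(x$alpha) - min(x$alpha)))
  invisible(x)
}

#' @export
plot.singularity_spectrum <- function(x, ...) {
  plot(x$alpha, x$f_alpha, type = "b", pch = 19,
       xlab = expression(alpha), ylab = expression(f(alpha)),
       main = "Singularity spectrum", ...)
  invisible(x)
}

#' Scalar features of a singularity spectrum
#'
#' Summaries of the multifractal spectrum used as complexity indices:
#' \describe{
#'   \item{MFDFA_Max}{singularity dimension f(alpha) at the maximum
#'     singularity exponent alpha}
#'   \item{MFDFA_Width}{max(alpha) - min(alpha), the degree of
#'     multifractality}
#'   \item{MFDFA_Mean}{(max(alpha) + min(alpha)) / 2, the average
#'     fluctuation exponent}
#'   \item{MFDFA_Peak}{alpha at the peak of f(alpha), the most probable
#'     (dominant) singularity strength}
#'   \item{MFDFA_Increment}{cumulative squared increments of h(q) between
#'     consecutive moment orders, 0 for a monofractal}
#' }
#'
#' @param s A `singularity_spectrum`.
#' @return Named numeric vector with the five features; non-finite spectrum
#'   values propagate as NA with a warning.
#' @export
mfdfa_features <- function(s) {
  stopifnot(inherits(s, "singularity_spectrum"))
  if (any(!is.finite(s$alpha)) || any(!is.finite(s$f_alpha))) {
    warning("mfdfa_features: non-finite spectrum, features set to NA",
            call. = FALSE)
    return(c(MFDFA_Max = NA_real_, MFDFA_Width = NA_real_,
             MFDFA_Mean = NA_real_, MFDFA_Peak = NA_real_,
             MFDFA_Increment = NA_real_))
  }
  c(MFDFA_Max = unname(s$f_alpha[which.max(s$alpha)]),
    MFDFA_Width = max(s$alpha) - min(s$alpha),
    MFDFA_Mean = (max(s$alpha) + min(s$alpha)) / 2,
    MFDFA_Peak = unname(s$alpha[which.max(s$f_alpha)]),
    MFDFA_Increment = sum(diff(s$h_q)^2))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Monofractal DFA: slope of log RMS fluctuation versus log window size
#' (equivalent to the generalized Hurst exponent h(2) of MFDFA). About 0.5
#' for white noise, 1 for pink noise, 1.5 for Brownian noise.
#'
#' @param x Numeric series.
#' @param window_sizes Integer window sizes.
#' @param detrend_order Polynomial detrending order.
#' @return Scalar scaling exponent.
#' @export
dfa_alpha <- function(x,
                      window_sizes = mfdfa_params(length(x))$window_sizes,
                      detrend_order = 1L) {
  sp <- mfdfa_spectrum(x, q_orders = 2, window_sizes = window_sizes,
                       detrend_order = detrend_order)
  unname(sp$h_q[1])
}
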