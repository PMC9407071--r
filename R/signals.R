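#' Standardize a numeric series
#'
#' Centers to mean 0 and scales to unit standard deviation (denominator
#' `n - 1`). All simulated series pass through this before indices are
#' computed, so that index values are comparable across signal families and
#' noise intensities.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("standardize: need a numeric vector of length >= 2", call. = FALSE)
  if (any(!is.finite(x)))
    stop("standardize: non-finite values in input", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0)
    stop("standardize: zero-variance input", call. = FALSE)
  (x - mean(x)) / s
}

#' Signal family names
#'
#' The six base signal families of the simulation grid: a Gaussian random
#' walk, a quasi-periodic oscillator (two incommensurate sinusoids), a
#' harmonic oscillator (fundamental plus integer harmonics, self-repeating),
#' two Lorenz systems with different parameter sets, and an EEG-like
#' surrogate (band-limited delta-to-beta oscillations over a pink-noise
#' floor).
#'
#' @return Character vector of the six family names.
#' @export
signal_families <- function() {
  c("random_walk", "oscillatory_simple", "oscillatory_harmonic",
    "lorenz_a", "lorenz_b", "eeg_like")
}

#' Lorenz system parameter presets
#'
#' Two parameterizations of the Lorenz system used as deterministic-chaotic
#' signal sources: preset "a" with (sigma, beta, rho) = (10, 2.5, 28) and
#' preset "b" with (20, 2, 30). Integration uses a fixed-step fourth-order
#' Runge-Kutta scheme; the first `transient` steps are discarded so the
#' trajectory has settled onto the attractor.
#'
#' @param preset `"a"` or `"b"`.
#' @return A list with elements `sigma`, `beta`, `rho`, `dt` (integration
#'   step) and `transient` (steps discarded).
#' @export
lorenz_params <- function(preset = c("a", "b")) {
  preset <- match.arg(preset)
  if (preset == "a")
    list(sigma = 10, beta = 2.5, rho = 28, dt = 0.01, transient = 1000L)
  else
    list(sigma = 20, beta = 2, rho = 30, dt = 0.005, transient = 1000L)
}

#' Simulate a Lorenz-system series
#'
#' Integrates dx = sigma (y - x), dy = x (rho - z) - y, dz = x y - beta z
#' with a fixed-step 4th-order Runge-Kutta scheme, discards the transient,
#' and returns the standardized x-coordinate. The initial condition is
#' (1, 1, 1) perturbed by a small seeded Gaussian offset so that different
#' seeds give different stretches of the attractor.
#'
#' @param params List as returned by [lorenz_params()]; fields `sigma`,
#'   `beta`, `rho`, `dt`, `transient`.
#' @param length Number of samples returned (after transient removal).
#' @param seed Integer seed.
#' @return Standardized numeric vector of length `length`.
#' @export
simulate_lorenz <- function(params, length, seed) {
  stopifnot(is.list(params), length >= 10L)
  if (!is.numeric(params$dt) || params$dt <= 0)
    stop("simulate_lorenz: dt must be > 0", call. = FALSE)
  if (params$transient < 0)
    stop("simulate_lorenz: transient must be >= 0", call. = FALSE)
  set.seed(seed)
  ic <- c(x = 1, y = 1, z = 1) + stats::rnorm(3, sd = 0.1)
  n_steps <- params$transient + length - 1L
  times <- seq(0, by = params$dt, length.out = n_steps + 1L)
  deriv <- function(t, state, p) {
    list(c(p$sigma * (state[2] - state[1]),
           state[1] * (p$rho - state[3]) - state[2],
           state[1] * state[2] - p$beta * state[3]))
  }
  out <- deSolve::ode(y = ic, times = times, func = deriv, parms = params,
                      method = "rk4")
  x <- out[, "x"]
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x))[1L]
    stop(sprintf("simulate_lorenz: non-finite state at step %d", bad),
         call. = FALSE)
  }
  x <- x[(params$transient + 1L):(params$transient + length)]
  structure(standardize(x), raw_range = range(out[, "x"]))
}

#' Simulate colored (1/f)^beta noise
#'
#' Spectral synthesis: an i.i.d. complex Gaussian spectrum is scaled by
#' f^(-beta/2), the zero-frequency bin is set to 0, and the inverse Fourier
#' transform gives a real series whose power spectral density follows
#' 1/f^beta in expectation. beta = -2, -1, 0, 1, 2 correspond to violet,
#' blue, white, pink and brown noise.
#'
#' @param beta Spectral exponent, one of -2, -1, 0, 1, 2 for the standard
#'   noise colors (other finite values are accepted for exploration).
#' @param length Number of samples, at least 64.
#' @param seed Integer seed.
#' @return Standardized numeric vector of length `length`.
#' @export
simulate_colored_noise <- function(beta, length, seed) {
  if (!is.numeric(beta) || !is.finite(beta))
    stop("simulate_colored_noise: beta must be a finite number", call. = FALSE)
  if (length < 64L)
    stop("simulate_colored_noise: length must be >= 64", call. = FALSE)
  set.seed(seed)
  n <- as.integer(length)
  # frequencies of the DFT bins 0 .. n-1 (in cycles/sample, folded)
  half <- floor(n / 2)
  freq <- c(0, seq_len(half), rev(seq_len(n - 1L - half))) / n
  amp <- c(0, freq[-1]^(-beta / 2))
  # Hermitian-symmetric random spectrum => real inverse transform
  phase <- stats::runif(half, 0, 2 * pi)
  mag <- stats::rnorm(half)
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[2:(half + 1L)] <- mag * exp(1i * phase)
  if (n %% 2 == 0) spec[half + 1L] <- Re(spec[half + 1L])  # Nyquist bin real
  if (half > 1L)
    spec[n:(n - half + 2L)] <- Conj(spec[2:(half)])
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  standardize(x)
}

#' Simulate one base signal
#'
#' Generates a standardized series from one of the six signal families (see
#' [signal_families()]). Oscillatory and EEG-like families use a nominal
#' sampling rate of 100 Hz. The quasi-periodic oscillator sums sinusoids at
#' 5 Hz and 5*sqrt(2) Hz (irrational frequency ratio, hence never exactly
#' repeating); the harmonic oscillator sums a 2 Hz fundamental and its
#' integer harmonics k = 1..5 with 1/k amplitude decay, giving a
#' self-repeating, fractal-like waveform. The EEG-like surrogate sums
#' band-limited oscillations in the delta (1-4 Hz), theta (4-8), alpha
#' (8-13) and beta (13-30) bands with seeded random frequencies and phases,
#' plus a small pink-noise floor.
#'
#' @param family One of [signal_families()].
#' @param length Number of samples, at least 10.
#' @param seed Integer seed; output is a pure function of
#'   (family, length, seed).
#' @return Standardized numeric vector of length `length`.
#' @export
simulate_base_signal <- function(family, length, seed) {
  if (!is.character(family) || length(family) != 1L ||
      !(family %in% signal_families()))
    stop(sprintf("simulate_base_signal: unknown family '%s'",
                 paste(family, collapse = ",")), call. = FALSE)
  if (!is.numeric(length) || length < 10L)
    stop("simulate_base_signal: length must be >= 10", call. = FALSE)
  n <- as.integer(length)
  fs <- 100  # nominal sampling rate (Hz) for the oscillatory families
  t <- (seq_len(n) - 1L) / fs
  set.seed(seed)
  x <- switch(family,
    random_walk = cumsum(stats::rnorm(n)),
    oscillatory_simple = {
      ph <- stats::runif(2, 0, 2 * pi)
      sin(2 * pi * 5 * t + ph[1]) + sin(2 * pi * 5 * sqrt(2) * t + ph[2])
    },
    oscillatory_harmonic = {
      ph <- stats::runif(1, 0, 2 * pi)
      k <- 1:5
      rowSums(sapply(k, function(kk) sin(2 * pi * 2 * kk * t + kk * ph) / kk))
    },
    lorenz_a = return(simulate_lorenz(lorenz_params("a"), n, seed)),
    lorenz_b = return(simulate_lorenz(lorenz_params("b"), n, seed)),
    eeg_like = {
      bands <- list(delta = c(1, 4), theta = c(4, 8),
                    alpha = c(8, 13), beta = c(13, 30))
      band_amp <- c(1, 0.6, 0.8, 0.3)  # rough 1/f-shaped band weights
      sig <- numeric(n)
      for (b in seq_along(bands)) {
        f <- stats::runif(3, bands[[b]][1], bands[[b]][2])
        ph <- stats::runif(3, 0, 2 * pi)
        for (j in 1:3)
          sig <- sig + band_amp[b] / 3 * sin(2 * pi * f[j] * t + ph[j])
      }
      if (n >= 64)
        sig <- sig + 0.2 * simulate_colored_noise(1, n, seed + 77L)
      sig
    }
  )
  standardize(as.numeric(x))
}

#' Add colored noise to a signal at a given intensity
#'
#' Returns `standardize(signal + intensity * standardize(noise))`. Both the
#' noise (before scaling) and the sum (after) are standardized so that
#' `intensity` is interpretable as a noise-to-signal amplitude ratio and
#' index values stay comparable across intensities. At intensity 0 the
#' standardized signal is returned unchanged.
#'
#' @param signal Numeric vector (standardized or not; it is standardized
#'   internally).
#' @param noise Numeric vector of the same length.
#' @param intensity Non-negative scalar.
#' @return Standardized numeric vector.
#' @export
add_noise <- function(signal, noise, intensity) {
  if (length(signal) != length(noise))
    stop("add_noise: signal and noise lengths differ", call. = FALSE)
  if (!is.numeric(intensity) || intensity < 0)
    stop("add_noise: intensity must be >= 0", call. = FALSE)
  s <- standardize(signal)
  if (intensity == 0) return(s)
  standardize(s + intensity * standardize(noise))
}

#' Power-spectral-density slope
#'
#' Least-squares slope of log power versus log frequency of the smoothed
#' periodogram, used to verify that generated noise has the requested
#' spectral exponent (slope approximately -beta for (1/f)^beta noise).
#'
#' @param x Numeric series.
#' @param span Modified Daniell smoother spans passed to
#'   [stats::spec.pgram()].
#' @return Scalar slope of the log-log regression.
#' @export
psd_slope <- function(x, span = c(11, 11)) {
  sp <- stats::spec.pgram(x, spans = span, taper = 0.1, plot = FALSE,
                          detrend = TRUE)
  keep <- sp$freq > 0 & sp$spec > 0
  stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[[2]]
}
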