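test_that("base signals are standardized, finite and deterministic", {
  for (fam in signal_families()) {
    x <- simulate_base_signal(fam, 500, 3L)
    expect_length(x, 500)
    expect_true(all(is.finite(x)))
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(sd(x) - 1), 1e-10)
    y <- simulate_base_signal(fam, 500, 3L)
    expect_identical(as.numeric(x), as.numeric(y))
    z <- simulate_base_signal(fam, 500, 4L)
    expect_false(isTRUE(all.equal(as.numeric(x), as.numeric(z))))
  }
  expect_error(simulate_base_signal("no_such_family", 500, 1L), "unknown family")
  expect_error(simulate_base_signal("random_walk", 5, 1L), "length")
})

test_that("random walk is strongly autocorrelated; harmonic oscillator self-repeats", {
  rw <- simulate_base_signal("random_walk", 1000, 11L)
  expect_gt(acf(rw, lag.max = 1, plot = FALSE)$acf[2], 0.9)
  # harmonic fundamental is 2 Hz at fs = 100 -> period 50 samples
  h <- simulate_base_signal("oscillatory_harmonic", 2000, 11L)
  expect_gt(acf(h, lag.max = 50, plot = FALSE)$acf[51], 0.5)
})

test_that("Lorenz trajectories stay on the attractor and respect presets", {
  for (preset in c("a", "b")) {
    p <- lorenz_params(preset)
    x <- simulate_lorenz(p, 2000, 5L)
    expect_length(x, 2000)
    expect_true(all(is.finite(x)))
    expect_lt(max(abs(attr(x, "raw_range"))), 30)  # known attractor bound
    expect_lt(max(abs(x)), 6)                      # standardized boundedness
  }
  expect_identical(lorenz_params("a")[c("sigma", "beta", "rho")],
                   list(sigma = 10, beta = 2.5, rho = 28))
  expect_identical(lorenz_params("b")[c("sigma", "beta", "rho")],
                   list(sigma = 20, beta = 2, rho = 30))
  expect_error(simulate_lorenz(list(sigma = 10, beta = 2.5, rho = 28,
                                    dt = 0, transient = 10L), 100, 1L), "dt")
  expect_identical(simulate_lorenz(lorenz_params("a"), 300, 9L),
                   simulate_lorenz(lorenz_params("a"), 300, 9L))
})

test_that("colored noise recovers its spectral exponent", {
  # slope of log PSD vs log f is -beta; averaged over seeds at n = 4096
  for (beta in c(-2L, 0L, 2L)) {
    slopes <- vapply(1:8, function(s)
      psd_slope(simulate_colored_noise(beta, 4096, s)), numeric(1))
    expect_lt(abs(mean(slopes) - (-beta)), 0.3)
  }
  expect_error(simulate_colored_noise(0, 32, 1L), "length")
})

test_that("add_noise is an identity at intensity 0 and degrades the signal monotonically", {
  x <- simulate_base_signal("oscillatory_simple", 600, 2L)
  nz <- simulate_colored_noise(0L, 600, 21L)
  expect_equal(add_noise(x, nz, 0), standardize(x))
  r_low <- cor(add_noise(x, nz, 0.001), x)
  r_high <- cor(add_noise(x, nz, 3), x)
  expect_lt(r_high, r_low)
  expect_error(add_noise(x, nz[-1], 1), "length")
  expect_error(add_noise(x, nz, -1), "intensity")
})

test_that("the full grid has the exact factorial cardinality and intensity range", {
  g <- build_grid(123L)
  expect_equal(nrow(g), 23040L)
  ints <- sort(unique(g$intensity))
  expect_length(ints, 128L)
  expect_equal(ints[1], 0.001)
  expect_equal(ints[128], 3)
  expect_true(all(diff(diff(ints)) < 1e-12))  # evenly spaced
  expect_true(all(g$length %in% seq(500, 3000, by = 500)))
})

test_that("grids and the random control are pure functions of the master seed", {
  g1 <- build_grid(7L, lengths = 500L, intensities = 8L)
  g2 <- build_grid(7L, lengths = 500L, intensities = 8L)
  expect_identical(g1$seed, g2$seed)
  expect_identical(attach_random_control(g1), attach_random_control(g2))
  g3 <- build_grid(8L, lengths = 500L, intensities = 8L)
  expect_false(identical(g1$seed, g3$seed))
  ctrl <- attach_random_control(g1)
  expect_true(all(ctrl >= 0 & ctrl < 1))
  expect_length(ctrl, nrow(g1))
})

test_that("the random control is independent of simulated signal features", {
  # n >= 1000 draws: control vs a cheap index computed on each cell
  g <- build_grid(3L, families = c("random_walk", "eeg_like"),
                  lengths = 500L, intensities = 100L)
  ctrl <- attach_random_control(g)
  ll <- vapply(seq_len(nrow(g)), function(i)
    line_length(simulate_cell(g[i, ])), numeric(1))
  expect_lt(abs(cor(ctrl, ll)), 0.1)
})

test_that("grid manifests and series round-trip through CSV", {
  g <- build_grid(5L, families = "random_walk", lengths = 500L,
                  intensities = 4L)
  tmp <- tempfile(fileext = ".csv")
  write_grid_manifest(g, tmp)
  back <- read.csv(tmp)
  expect_equal(nrow(back), nrow(g))
  expect_equal(back$seed, g$seed)
  x <- simulate_cell(g[1, ])
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(value = x), f2, row.names = FALSE)
  expect_equal(read_series(f2), as.numeric(x))
  unlink(c(tmp, f2))
})
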