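test_that("MFDFA recovers theoretical scaling exponents", {
  h2 <- function(x) {
    sp <- mfdfa_spectrum(x)
    unname(sp$h_q[sp$q == 2])
  }
  white <- brown <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    white[s] <- h2(standardize(rnorm(3000)))
    brown[s] <- h2(standardize(cumsum(rnorm(3000))))
  }
  expect_lt(abs(mean(white) - 0.5), 0.1)
  expect_lt(abs(mean(brown) - 1.5), 0.15)
})

test_that("spectrum geometry is definitional", {
  s <- structure(list(q = c(-1, 1, 2), h_q = c(0.9, 0.6, 0.5),
                      tau_q = c(-1.9, -0.4, 0),
                      alpha = c(0.2, 0.5, 0.9), f_alpha = c(0.6, 1.0, 0.7),
                      window_sizes = c(10, 20, 40), log_fq = NULL),
                 class = "singularity_spectrum")
  f <- mfdfa_features(s)
  expect_equal(unname(f["MFDFA_Width"]), 0.7)
  expect_equal(unname(f["MFDFA_Mean"]), 0.55)
  expect_equal(unname(f["MFDFA_Peak"]), 0.5)
  expect_equal(unname(f["MFDFA_Max"]), 0.7)
  expect_equal(unname(f["MFDFA_Increment"]), (0.6 - 0.9)^2 + (0.5 - 0.6)^2)
})

test_that("monofractal limit gives ~zero width and increment", {
  # fractional-Gaussian-like monofractal: plain white noise
  widths <- incs <- numeric(5)
  for (s in 1:5) {
    set.seed(s)
    f <- mfdfa_features(mfdfa_spectrum(standardize(rnorm(3000))))
    widths[s] <- f["MFDFA_Width"]
    incs[s] <- f["MFDFA_Increment"]
  }
  expect_lt(mean(widths), 0.3)
  expect_lt(mean(incs), 0.05)
})

test_that("a binomial cascade is detected as strongly multifractal", {
  width_of <- function(x) unname(mfdfa_features(mfdfa_spectrum(x))["MFDFA_Width"])
  casc <- vapply(1:5, function(s)
    width_of(standardize(binomial_cascade(11, p = 0.7, seed = s))), numeric(1))
  wn <- vapply(1:5, function(s) {
    set.seed(s)
    width_of(standardize(rnorm(2048)))
  }, numeric(1))
  expect_gt(mean(casc), 2 * mean(wn))
  # most probable exponent of the p=0.7 cascade:
  # alpha_0 = -log2(sqrt(p (1-p))) ~ 1.126
  alpha0 <- -log2(sqrt(0.7 * 0.3))
  peaks <- vapply(1:8, function(s) {
    sp <- mfdfa_spectrum(standardize(binomial_cascade(11, p = 0.7, seed = s)))
    unname(sp$alpha[which.max(sp$f_alpha)])
  }, numeric(1))
  expect_lt(abs(mean(peaks) - alpha0), 0.15)
})

test_that("MFDFA input contracts are enforced", {
  set.seed(1)
  expect_error(mfdfa_spectrum(rnorm(30)), "4 x max window|window sizes")
  expect_error(mfdfa_spectrum(rnorm(500), q_orders = c(-1, 0, 1)), "exclude 0")
  expect_error(mfdfa_spectrum(rep(1, 500)), "degenerate")
  x <- rnorm(500)
  expect_identical(mfdfa_spectrum(x)$h_q, mfdfa_spectrum(x)$h_q)
})

test_that("DFA alpha separates white, pink and brown noise", {
  a <- vapply(c(-0, 1, 2), function(beta) {
    mean(vapply(1:5, function(s)
      dfa_alpha(simulate_colored_noise(beta, 2000, s)), numeric(1)))
  }, numeric(1))
  expect_lt(abs(a[1] - 0.5), 0.15)
  expect_lt(abs(a[2] - 1.0), 0.2)
  expect_lt(abs(a[3] - 1.5), 0.2)
})
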