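test_that("line length matches hand-computed values", {
  expect_equal(line_length(c(0, 1, 0, 1, 0)), 1)
  expect_equal(line_length(rep(2.5, 10)), 0)
  expect_equal(line_length(c(1, 3, 2)), 1.5)
  expect_error(line_length(3), "length")
})

test_that("Hjorth complexity is ~1 for a dense sinusoid and larger for white noise", {
  t <- seq(0, 2, length.out = 2000)
  expect_lt(abs(hjorth_complexity(sin(2 * pi * 5 * t)) - 1), 0.05)
  set.seed(1)
  wn <- vapply(1:20, function(s) {
    set.seed(s)
    hjorth_complexity(rnorm(2000))
  }, numeric(1))
  expect_true(all(wn > 1.05))
  expect_error(hjorth_complexity(rep(1, 100)), "variance")
})

test_that("SVD entropy has its analytic values on structured inputs", {
  per4 <- c(rep(c(1, 0, -1, 0), 25), 1)  # 100 embedded pairs, balanced
  expect_lt(abs(svd_entropy(per4, m = 2) - log(2)), 1e-6)
  # rank-1 embedding: constant nonzero series
  expect_equal(svd_entropy(rep(3, 50), m = 3), 0)
  set.seed(4)
  v <- svd_entropy(rnorm(1000), m = 3)
  expect_gt(v, 0)
  expect_lte(v, log(3))
  expect_error(svd_entropy(rep(0, 50), m = 2), "all-zero")
})

test_that("ordinal patterns use stable position tie-breaking", {
  inc <- ordinal_patterns(1:50, m = 3)
  expect_length(unique(inc$pattern), 1L)
  ties <- ordinal_patterns(c(1, 1, 1, 1), m = 2)
  expect_length(unique(ties$pattern), 1L)
  expect_identical(ties$pattern, ordinal_patterns(c(2, 2, 2, 2), m = 2)$pattern)
  set.seed(8)
  rnd <- ordinal_patterns(rnorm(10000), m = 3)
  expect_length(unique(rnd$pattern), 6L)  # all 3! patterns observed
})

test_that("permutation-family entropies have their analytic zeros and limits", {
  mono <- cumsum(runif(200) + 0.1)
  expect_equal(permutation_entropy(mono), 0)
  expect_equal(weighted_permutation_entropy(mono), 0)
  expect_equal(cwpen(mono), 0)
  expect_equal(bubble_entropy(mono), 0)
  expect_equal(mswpen(mono), 0)
  set.seed(2)
  u <- runif(10000)
  expect_gt(weighted_permutation_entropy(u, m = 3), 0.95)
  expect_gt(cwpen(u), 0)
  expect_error(weighted_permutation_entropy(rep(1, 100)), "weight")
})

test_that("weighted and unweighted permutation entropy coincide for constant weights", {
  # period-2 alternation: every embedded vector has the same variance
  x <- rep(c(0, 1), 100)
  expect_equal(weighted_permutation_entropy(x, m = 2),
               permutation_entropy(x, m = 2))
})

test_that("bubble entropy counts swaps correctly and is stable on noise", {
  expect_equal(swap_counts(c(3, 1, 2), m = 3), 2L)
  expect_equal(swap_counts(c(1, 2, 3), m = 3), 0L)
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    bubble_entropy(rnorm(2000))
  }, numeric(1))
  expect_true(all(vals > 0))
  expect_lt(sd(vals) / mean(vals), 0.2)
})

test_that("coarse-graining averages non-overlapping windows", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(1:7, 3), c(2, 5))  # trailing sample dropped
  expect_identical(coarse_grain(1:6, 1), 1:6)
  expect_error(coarse_grain(1:6, 7), "scale")
})

test_that("MSWPEn reduces to WPEn at scale 1 and separates white from pink noise", {
  set.seed(5)
  x <- rnorm(500)
  expect_equal(mswpen(x, scales = 1L),
               weighted_permutation_entropy(x, normalize = TRUE))
  w_scale1 <- p_scale1 <- w_multi <- p_multi <- numeric(20)
  for (s in 1:20) {
    w <- simulate_colored_noise(0L, 3000, s)
    p <- simulate_colored_noise(1L, 3000, s)
    w_scale1[s] <- weighted_permutation_entropy(w)
    p_scale1[s] <- weighted_permutation_entropy(p)
    w_multi[s] <- mswpen(w)
    p_multi[s] <- mswpen(p)
  }
  expect_gt(mean(w_scale1), mean(p_scale1))  # white > pink at scale 1
  # separation persists under coarse-graining: white stays near the
  # uniform-pattern ceiling at every scale, pink stays below it
  expect_gt(mean(w_multi), mean(p_multi))
  per_scale <- vapply(1:10, function(sc) {
    w <- mean(vapply(1:10, function(s) weighted_permutation_entropy(
      coarse_grain(simulate_colored_noise(0L, 3000, s), sc)), numeric(1)))
    p <- mean(vapply(1:10, function(s) weighted_permutation_entropy(
      coarse_grain(simulate_colored_noise(1L, 3000, s), sc)), numeric(1)))
    w - p
  }, numeric(1))
  expect_true(all(per_scale > 0))
})

test_that("attention entropy is 0 for strict alternation and errors without extrema", {
  expect_equal(attention_entropy(rep(c(0, 1), 50)), 0)
  expect_error(attention_entropy(1:100), "extrema")
  set.seed(3)
  x <- rnorm(2000)
  expect_gt(attention_entropy(x), 0)
  set.seed(3)
  expect_equal(attention_entropy(x), attention_entropy(rnorm(2000)))
})

test_that("permutation-family and AttEn are invariant under positive affine maps; LL scales linearly", {
  set.seed(9)
  x <- rnorm(300)
  y <- 3.7 * x + 11
  expect_equal(permutation_entropy(x), permutation_entropy(y))
  expect_equal(bubble_entropy(x), bubble_entropy(y))
  expect_equal(attention_entropy(x), attention_entropy(y))
  # weights scale uniformly under affine maps, leaving WPEn unchanged
  expect_equal(weighted_permutation_entropy(x), weighted_permutation_entropy(y))
  expect_equal(line_length(y), 3.7 * line_length(x))
})

test_that("every registered index matches its naive reference on random series", {
  # spot equivalence on a handful of series; the full 50-series sweep runs in
  # the acceptance suite
  reg <- index_registry()
  for (s in 1:5) {
    set.seed(s)
    x <- standardize(rnorm(sample(100:500, 1)))
    got <- compute_battery(x, reg)$values
    want <- naive_battery(x)
    expect_equal(got[names(want)], want, tolerance = 1e-8)
  }
})

test_that("compute_battery never aborts and reports failures as missing", {
  reg <- index_registry()
  out <- suppressWarnings(compute_battery(rep(1, 300), reg))
  expect_named(out$values, registry_outputs(reg))
  expect_equal(unname(out$values["LL"]), 0)
  expect_true(is.na(out$values["WPEn"]))   # degenerate for constant input
  expect_true(is.na(out$values["SampEn"]))
  expect_gt(length(out$errors), 0)
  set.seed(1)
  ok <- compute_battery(standardize(rnorm(400)), reg)
  expect_false(anyNA(ok$values))
  expect_named(ok$runtime, registry_outputs(reg))
})

test_that("multiscale indices cost more than line length", {
  set.seed(6)
  x <- standardize(rnorm(3000))
  t_ll <- system.time(for (i in 1:20) line_length(x))[["elapsed"]]
  t_ms <- system.time(mswpen(x))[["elapsed"]]
  expect_gt(t_ms, t_ll)
})
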