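# small index matrix shared by tests in this file
tiny_matrix <- local({
  g <- build_grid(17L, families = c("random_walk", "eeg_like"),
                  lengths = 500L, betas = 0L, intensities = 4L)
  suppressWarnings(compute_index_matrix(g, index_registry()))
})

test_that("the index matrix has one row per cell and flags its columns", {
  expect_equal(nrow(tiny_matrix), 2 * 1 * 1 * 4)
  expect_setequal(attr(tiny_matrix, "covariate_cols"),
                  c("length", "intensity", "dom_freq", "random_control"))
  expect_true(all(attr(tiny_matrix, "index_cols") %in%
                  registry_outputs(index_registry())))
  expect_named(median_runtimes(tiny_matrix),
               registry_outputs(index_registry()))
})

test_that("matrix content is independent of the worker count", {
  g <- build_grid(23L, families = "oscillatory_simple", lengths = 500L,
                  betas = 1L, intensities = 3L)
  reg <- index_registry("selected")
  m1 <- compute_index_matrix(g, reg, workers = 1L)
  m2 <- compute_index_matrix(g, reg, workers = 2L)
  expect_equal(analysis_matrix(m1), analysis_matrix(m2))
})

test_that("redundant columns are dropped, keeping the earlier-registered one", {
  m <- tiny_matrix
  df <- as.data.frame(m)
  df$LL_copy <- df$LL
  df$LL_neg <- -df$LL
  attr(df, "index_cols") <- c(attr(m, "index_cols"), "LL_copy", "LL_neg")
  attr(df, "covariate_cols") <- attr(m, "covariate_cols")
  class(df) <- class(m)
  pruned <- suppressMessages(drop_redundant(df))
  expect_false(any(c("LL_copy", "LL_neg") %in% attr(pruned, "index_cols")))
  expect_true("LL" %in% attr(pruned, "index_cols"))
  expect_equal(unname(attr(pruned, "dropped")[c("LL_copy", "LL_neg")]),
               c("LL", "LL"))
  # no perfect pairs at tol 0: unchanged
  same <- drop_redundant(m, tol = 0)
  expect_identical(attr(same, "index_cols"), attr(m, "index_cols"))
})

test_that("pearson matrix is symmetric with unit diagonal and pairwise-complete", {
  r <- pearson_matrix(tiny_matrix, min_obs = 5L)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  # independent simulated columns decorrelate at large n
  set.seed(10)
  X <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_lt(abs(pearson_matrix(X)[1, 2]), 0.05)
  # missing values: pairwise handling
  X[1:50, 1] <- NA
  expect_false(anyNA(pearson_matrix(X)))
})

test_that("the factor-count panel recovers planted structure", {
  for (k in 2:4) {
    X <- plant_battery(k, p_per = 5, n = 2000, loading = 0.8, seed = k)
    nf <- choose_n_factors(cor(X), n_obs = 2000)
    expect_equal(as.integer(nf), k)
  }
  expect_equal(as.integer(choose_n_factors(diag(8), n_obs = 200)), 1L)
  r1 <- tcrossprod(rep(0.9, 6))
  diag(r1) <- 1
  expect_equal(as.integer(choose_n_factors(r1, n_obs = 500)), 1L)
})

test_that("the varimax factor model recovers planted loadings and archetypicity", {
  X <- plant_battery(2, p_per = 5, n = 2000, seed = 7)
  fa <- fit_factor_model(cor(X), n_factors = 2)
  truth <- attr(X, "truth")
  # indicators of the same planted factor share a dominant factor
  expect_equal(length(unique(fa$dominant[truth == 1])), 1L)
  expect_equal(length(unique(fa$dominant[truth == 2])), 1L)
  expect_false(fa$dominant[1] == fa$dominant[6])
  # rotation preserves communalities
  unrot <- fit_factor_model(cor(X), n_factors = 2)
  expect_equal(rowSums(fa$loadings^2), fa$communalities, tolerance = 1e-6)
  expect_true(all(fa$archetypicity > 0 & fa$archetypicity <= 1))
  # a pure single-factor profile has archetypicity exactly 1
  L <- matrix(c(0.9, 0, 0, 0.8), 2, 2)
  p2 <- L[1, ]^2 / sum(L[1, ]^2)
  expect_equal(1 / exp(-sum(p2[p2 > 0] * log(p2[p2 > 0]))), 1)
  expect_equal(unname(fa$variance_explained),
               unname(colSums(fa$loadings^2) / ncol(X)))
})

test_that("ward clustering on correlation distance recovers planted blocks", {
  b <- matrix(0.2, 8, 8)
  b[1:4, 1:4] <- 0.8
  b[5:8, 5:8] <- 0.8
  diag(b) <- 1
  colnames(b) <- rownames(b) <- paste0("i", 1:8)
  wc <- ward_clustering(b, k = 2)
  expect_equal(unname(wc$clusters), rep(1:2, each = 4))
  expect_true(all(diff(wc$hclust$height) >= -1e-12))  # monotone merges
  # duplicated indices merge first at ~zero height
  b2 <- cbind(b, i1bis = b[, 1])
  b2 <- rbind(b2, i1bis = c(b[1, ], 1))
  b2["i1", "i1bis"] <- b2["i1bis", "i1"] <- 1
  wc2 <- ward_clustering(b2, k = 2)
  first <- wc2$hclust$merge[1, ]
  expect_setequal(wc2$hclust$labels[-first], c("i1", "i1bis"))
  expect_lt(wc2$hclust$height[1], 1e-8)
})

test_that("network edges obey the threshold and shrink as it rises", {
  b <- matrix(0.2, 6, 6)
  b[1:3, 1:3] <- 0.8
  b[4:6, 4:6] <- 0.8
  diag(b) <- 1
  colnames(b) <- rownames(b) <- paste0("i", 1:6)
  e06 <- network_edges(b, 0.6)
  expect_equal(nrow(e06), 6)  # 3 within each block
  expect_true(all(abs(e06$r) > 0.6))
  expect_equal(nrow(network_edges(b, 1.0)), 0)
  ths <- seq(0, 0.95, by = 0.05)
  counts <- vapply(ths, function(t) nrow(network_edges(b, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy selection orders by marginal gain with a sane curve", {
  X <- plant_battery(2, p_per = 5, n = 2000, seed = 3)
  corr <- cor(X)
  sel <- greedy_variance_ordering(corr, subset = c("V1", "V2", "V6", "V7"))
  # first two picks span the two planted factors
  truth <- c(V1 = 1, V2 = 1, V6 = 2, V7 = 2)
  expect_setequal(unname(truth[sel$index[1:2]]), c(1, 2))
  expect_true(all(diff(sel$cum_variance) >= -1e-9))
  expect_true(all(diff(sel$gain) <= 1e-9))  # concave: gains non-increasing
  # full battery reaches 100%
  full <- greedy_variance_ordering(corr)
  expect_equal(max(full$cum_variance), 100)
  # exhaustive check: greedy first pick is the single best index
  singles <- vapply(colnames(corr), function(cc)
    variance_explained(corr, cc), numeric(1))
  expect_equal(full$index[1], names(which.max(singles)))
  # collinear candidate still placed with ~zero gain
  corr2 <- cbind(rbind(corr, V1bis = corr["V1", ]), V1bis = c(corr[, "V1"], 1))
  sel2 <- suppressMessages(greedy_variance_ordering(corr2,
                                                    subset = c("V1", "V1bis")))
  expect_equal(nrow(sel2), 2L)
  expect_lt(sel2$gain[2], 1e-8)
})

test_that("expected-value profiles have the constructed shape", {
  prof <- suppressWarnings(expected_value_profiles(tiny_matrix,
                                                   selection = c("LL", "SVDEn"),
                                                   n_bins = 4))
  expect_equal(nrow(prof), 2 * 2 * 1 * 4)  # indices x families x betas x bins
  # LL rises with noise intensity within every family
  for (fam in unique(prof$family)) {
    ll <- prof[prof$index == "LL" & prof$family == fam, ]
    ll <- ll[order(ll$intensity_mid), ]
    expect_gt(cor(ll$intensity_mid, ll$value, method = "spearman",
                  use = "complete.obs"), 0)
  }
})
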