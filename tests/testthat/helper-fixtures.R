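# Programmatic fixtures shared across tests.

# battery with k planted orthogonal factors, p_per indicators each
plant_battery <- function(k, p_per = 5, n = 2000, loading = 0.8, seed = 1) {
  set.seed(seed)
  F <- matrix(rnorm(n * k), n, k)
  X <- sapply(seq_len(k * p_per), function(j) {
    f <- (j - 1) %/% p_per + 1
    loading * F[, f] + sqrt(1 - loading^2) * rnorm(n)
  })
  colnames(X) <- paste0("V", seq_len(k * p_per))
  attr(X, "truth") <- rep(seq_len(k), each = p_per)
  X
}

# binomial multiplicative cascade: a canonical multifractal with analytic
# singularity spectrum; most probable exponent alpha0 = -log2(sqrt(p*(1-p)))
binomial_cascade <- function(levels = 11, p = 0.7, seed = 1) {
  set.seed(seed)
  w <- 1
  for (l in seq_len(levels)) {
    swap <- sample(c(TRUE, FALSE), length(w), replace = TRUE)
    a <- ifelse(swap, 1 - p, p)
    w <- as.vector(rbind(w * a, w * (1 - a)))
  }
  w
}

# reduced-grid fit shared by the heavyweight acceptance checks; computed at
# most once per test run
reduced_fit_cache <- new.env(parent = emptyenv())
get_reduced_fit <- function(master_seed = 42L) {
  key <- paste0("fit_", master_seed)
  if (is.null(reduced_fit_cache[[key]]))
    reduced_fit_cache[[key]] <- suppressWarnings(suppressMessages(
      tscomplexity::complexity_structure(master_seed = master_seed)))
  reduced_fit_cache[[key]]
}
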