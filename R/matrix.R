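#' Dominant frequency of a series
#'
#' Frequency (cycles/sample) of the largest periodogram ordinate, excluding
#' the zero-frequency bin.
#'
#' @param x Numeric series.
#' @return Scalar in (0, 0.5].
#' @export
dominant_frequency <- function(x) {
  n <- length(x)
  pw <- Mod(stats::fft(x - mean(x)))^2
  half <- seq(2L, n %/% 2 + 1L)
  (which.max(pw[half])) / n
}

#' Compute the index matrix over a simulation grid
#'
#' For every grid cell the cell series is simulated ([simulate_cell()]), the
#' full index battery evaluated ([compute_battery()]), and the covariates
#' recorded: series length, noise intensity, dominant frequency, and the
#' random manipulation-check value ([attach_random_control()]). Content is
#' deterministic given the grid (hence the master seed) irrespective of the
#' worker count, because every cell carries its own seed. Indices failing on
#' more than half the cells are excluded with a warning.
#'
#' @param grid A [build_grid()] result.
#' @param registry An [index_registry()].
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return Object of class `index_matrix`: a data.frame with one row per
#'   cell. Attributes: `index_cols`, `covariate_cols`, `meta_cols`,
#'   `median_runtime` (named, relative units), `excluded` (names of dropped
#'   indices).
#' @export
compute_index_matrix <- function(grid, registry = index_registry(),
                                 workers = 1L) {
  stopifnot(inherits(grid, "simulation_grid"), nrow(grid) > 0L)
  one_cell <- function(i) {
    cell <- grid[i, ]
    x <- simulate_cell(cell)
    bat <- compute_battery(x, registry)
    list(values = bat$values, runtime = bat$runtime,
         dom_freq = dominant_frequency(x))
  }
  res <- if (workers > 1L)
    parallel::mclapply(seq_len(nrow(grid)), one_cell, mc.cores = workers)
  else
    lapply(seq_len(nrow(grid)), one_cell)
  vals <- do.call(rbind, lapply(res, `[[`, "values"))
  runtimes <- do.call(rbind, lapply(res, `[[`, "runtime"))
  idx_cols <- colnames(vals)
  na_share <- colMeans(is.na(vals))
  excluded <- idx_cols[na_share > 0.5]
  if (length(excluded) > 0) {
    warning(sprintf("compute_index_matrix: excluded indices with >50%% failures: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
    idx_cols <- setdiff(idx_cols, excluded)
  }
  out <- data.frame(family = grid$family, length = grid$length,
                    beta = grid$beta, intensity = grid$intensity,
                    seed = grid$seed,
                    dom_freq = vapply(res, `[[`, numeric(1), "dom_freq"),
                    random_control = attach_random_control(grid))
  out <- cbind(out, as.data.frame(vals[, idx_cols, drop = FALSE]))
  structure(out,
            index_cols = idx_cols,
            covariate_cols = c("length", "intensity", "dom_freq",
                               "random_control"),
            meta_cols = c("family", "beta", "seed"),
            median_runtime = apply(runtimes, 2L, stats::median, na.rm = TRUE),
            excluded = excluded,
            master_seed = attr(grid, "master_seed"),
            class = c("index_matrix", "data.frame"))
}

#' @export
print.index_matrix <- function(x, ...) {
  cat(sprintf("Index matrix: %d cells x %d indices (+%d covariates)\n",
              nrow(x), length(attr(x, "index_cols")),
              length(attr(x, "covariate_cols"))))
  cat("  indices:", paste(attr(x, "index_cols"), collapse = ", "), "\n")
  invisible(x)
}

#' Columns entering the structure analysis
#'
#' Index columns plus (optionally) covariates, as a numeric matrix.
#'
#' @param m An `index_matrix`.
#' @param covariates Include the covariate columns.
#' @return Numeric matrix.
#' @export
analysis_matrix <- function(m, covariates = TRUE) {
  cols <- attr(m, "index_cols")
  if (covariates) cols <- c(cols, attr(m, "covariate_cols"))
  as.matrix(as.data.frame(m)[, cols, drop = FALSE])
}

#' Median relative runtimes of the battery
#'
#' Per-index median wall time over the grid, in arbitrary relative units
#' (meaningful only for comparisons within one run).
#'
#' @param m An `index_matrix`.
#' @return Named numeric vector.
#' @export
median_runtimes <- function(m) attr(m, "median_runtime")

#' Drop statistically redundant indices
#'
#' Among index-column pairs whose absolute Pearson correlation is at least
#' `1 - tol`, the later-registered column is dropped; the drops are recorded
#' (with the name of the kept partner) in the `dropped` attribute and
#' reported via a message.
#'
#' @param m An `index_matrix`.
#' @param tol Tolerance off perfect correlation; default `1e-8` keeps only
#'   numerically perfect duplicates out.
#' @return The pruned `index_matrix` (attribute `dropped` added).
#' @export
drop_redundant <- function(m, tol = 1e-8) {
  idx <- attr(m, "index_cols")
  if (length(idx) < 2L) return(m)
  r <- stats::cor(as.data.frame(m)[, idx, drop = FALSE],
                  use = "pairwise.complete.obs")
  dropped <- character(0)
  keep <- idx
  for (j in seq_along(idx)[-1]) {
    earlier <- keep[keep %in% idx[seq_len(j - 1L)]]
    hit <- earlier[which(abs(r[earlier, idx[j]]) >= 1 - tol)]
    if (length(hit) > 0 && idx[j] %in% keep) {
      dropped[idx[j]] <- hit[1]
      keep <- setdiff(keep, idx[j])
    }
  }
  if (length(dropped) > 0)
    message("drop_redundant: dropped ", paste(names(dropped), collapse = ", "),
            " (redundant with ", paste(dropped, collapse = ", "), ")")
  attr(m, "index_cols") <- keep
  attr(m, "dropped") <- dropped
  m
}

#' Pearson correlation matrix of the battery
#'
#' Pairwise-complete Pearson correlations of the index (and optionally
#' covariate) columns. Pairs with fewer than `min_obs` complete observations
#' are set to NA with a warning.
#'
#' @param m An `index_matrix` (or plain numeric matrix/data.frame).
#' @param covariates Include covariate columns (for `index_matrix` input).
#' @param min_obs Minimum pairwise-complete observations.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(m, covariates = FALSE, min_obs = 30L) {
  X <- if (inherits(m, "index_matrix")) analysis_matrix(m, covariates)
       else as.matrix(m)
  if (ncol(X) < 2L)
    stop("pearson_matrix: need at least 2 columns", call. = FALSE)
  r <- stats::cor(X, use = "pairwise.complete.obs")
  ok <- !is.na(X)
  n_pair <- crossprod(ok)
  low <- n_pair < min_obs & upper.tri(n_pair, diag = FALSE)
  if (any(low)) {
    warning("pearson_matrix: pairs with insufficient overlap set to NA",
            call. = FALSE)
    r[low | t(low)] <- NA_real_
  }
  diag(r) <- 1
  r
}
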