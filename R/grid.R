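#' Deterministic per-cell seed
#'
#' Stable 31-bit hash of (master_seed, family, length, beta, intensity
#' index), used to derive every cell's random seed from the grid's master
#' seed. Polynomial rolling hash over the character encoding, modulo
#' 2^31 - 1, so derived seeds stay valid R integers.
#'
#' @param master_seed Integer master seed.
#' @param family Signal family name.
#' @param length Series length.
#' @param beta Noise spectral exponent.
#' @param intensity_index 1-based index of the intensity level.
#' @return Integer vector in [1, 2^31 - 2] (arguments are recycled).
#' @export
cell_seed <- function(master_seed, family, length, beta, intensity_index) {
  key <- paste(master_seed, family, length, beta, intensity_index, sep = "|")
  codes <- lapply(key, utf8ToInt)
  len <- lengths(codes)
  max_len <- max(len)
  mat <- matrix(0L, nrow = base::length(key), ncol = max_len)
  for (i in seq_along(codes)) mat[i, seq_len(len[i])] <- codes[[i]]
  h <- numeric(base::length(key))
  m <- 2147483647  # 2^31 - 1; products stay < 2^53, so doubles are exact
  for (pos in seq_len(max_len)) {
    upd <- pos <= len
    h[upd] <- (h[upd] * 131 + mat[upd, pos]) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

#' Grid default levels
#'
#' The factor levels of the full simulation grid: 6 signal families, 6
#' lengths (500 to 3000 by 500), 5 noise colors (beta in -2..2) and 128
#' noise intensities evenly spaced from 0.001 to 3. The Cartesian product
#' has 6 x 6 x 5 x 128 = 23,040 cells.
#'
#' @return Named list with `families`, `lengths`, `betas`, `intensities`.
#' @export
grid_levels <- function() {
  list(families = signal_families(),
       lengths = seq(500L, 3000L, by = 500L),
       betas = c(-2L, -1L, 0L, 1L, 2L),
       intensities = seq(0.001, 3, length.out = 128))
}

#' Build the simulation grid
#'
#' Constructs the full factorial grid of signal specifications (one row per
#' cell) with reproducible per-cell seeds derived from `master_seed` via
#' [cell_seed()]. Passing subsets of the default levels gives reduced,
#' desk-scale grids; the defaults give the full 23,040-cell grid.
#'
#' @param master_seed Integer master seed; the entire grid (and everything
#'   computed from it) is a pure function of this value.
#' @param families Character vector of signal families.
#' @param lengths Integer vector of series lengths.
#' @param betas Integer vector of noise spectral exponents.
#' @param intensities Numeric vector of noise intensities, or a single
#'   integer count n to use n evenly spaced values from 0.001 to 3.
#' @return Object of class `simulation_grid`: a data.frame with columns
#'   `family`, `length`, `beta`, `intensity`, `intensity_index`, `seed`,
#'   plus attribute `master_seed`.
#' @export
build_grid <- function(master_seed,
                       families = grid_levels()$families,
                       lengths = grid_levels()$lengths,
                       betas = grid_levels()$betas,
                       intensities = grid_levels()$intensities) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  if (length(intensities) == 1L && intensities >= 2 &&
      intensities == round(intensities))
    intensities <- seq(0.001, 3, length.out = intensities)
  if (!all(betas %in% c(-2L, -1L, 0L, 1L, 2L)))
    stop("build_grid: betas must be in {-2,-1,0,1,2}", call. = FALSE)
  if (!all(families %in% signal_families()))
    stop("build_grid: unknown family", call. = FALSE)
  cells <- expand.grid(intensity_index = seq_along(intensities),
                       beta = as.integer(betas),
                       length = as.integer(lengths),
                       family = families,
                       stringsAsFactors = FALSE)
  # order: family slowest, intensity fastest
  cells <- cells[, c("family", "length", "beta", "intensity_index")]
  o <- order(match(cells$family, families), cells$length, cells$beta,
             cells$intensity_index)
  cells <- cells[o, , drop = FALSE]
  rownames(cells) <- NULL
  cells$intensity <- intensities[cells$intensity_index]
  cells$seed <- cell_seed(master_seed, cells$family, cells$length,
                          cells$beta, cells$intensity_index)
  structure(cells, master_seed = master_seed,
            class = c("simulation_grid", "data.frame"))
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("Simulation grid: %d cells (%d families x %d lengths x %d noise colors x %d intensities), master seed %s\n",
              nrow(x), length(unique(x$family)), length(unique(x$length)),
              length(unique(x$beta)), length(unique(x$intensity_index)),
              format(attr(x, "master_seed"))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more cells\n", nrow(x) - 6L))
  invisible(x)
}

#' Simulate the series for one grid cell
#'
#' Generates the base signal for the cell's family and length (seeded by the
#' cell seed), generates colored noise of the cell's beta (seeded by cell
#' seed + 1) and mixes them at the cell's intensity via [add_noise()].
#'
#' @param cell One-row data.frame (a row of a [build_grid()] result) or a
#'   list with fields `family`, `length`, `beta`, `intensity`, `seed`.
#' @return Standardized numeric vector of length `cell$length`.
#' @export
simulate_cell <- function(cell) {
  base <- simulate_base_signal(cell$family, cell$length, cell$seed)
  noise <- simulate_colored_noise(cell$beta, cell$length,
                                  (cell$seed + 1L) %% 2147483646L + 1L)
  add_noise(base, noise, cell$intensity)
}

#' Attach the random manipulation-check column
#'
#' Draws one uniform [0, 1) number per grid cell, seeded from the cell seed,
#' to serve as a known-unrelated control covariate: downstream
#' dimensionality analyses must not assign it to any latent factor.
#'
#' @param grid A `simulation_grid`.
#' @return Numeric vector of `nrow(grid)` values in [0, 1).
#' @export
attach_random_control <- function(grid) {
  vapply(grid$seed, function(s) {
    set.seed((s + 2L) %% 2147483646L + 1L)
    stats::runif(1)
  }, numeric(1))
}

#' Write the grid manifest as CSV
#'
#' One row per cell: family, length, beta, intensity, seed.
#'
#' @param grid A `simulation_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_manifest <- function(grid, path) {
  utils::write.csv(as.data.frame(grid)[, c("family", "length", "beta",
                                           "intensity", "seed")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a single-column series from text/CSV
#'
#' Accepts a plain text file with one value per line or a CSV whose first
#' column (header optional) holds the series.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header)
  x <- as.numeric(df[[1]])
  if (any(!is.finite(x)))
    stop("read_series: non-finite values in input", call. = FALSE)
  x
}
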