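#' Default run configuration
#'
#' Desk-scale defaults: the reduced 960-cell grid (6 families x 2 lengths x
#' 5 noise colors x 16 intensities), the full 24-index battery, one worker,
#' redundancy tolerance 1e-8, network edge threshold 0.6 and a 0.2
#' control-loading threshold for the manipulation check. `reduced = FALSE`
#' switches to the full 23,040-cell grid (6 lengths, 128 intensities).
#'
#' @param master_seed Integer master seed.
#' @param reduced Use the reduced desk-scale grid.
#' @param out_dir Output directory (NULL = no files written).
#' @return Named list (a run configuration).
#' @export
default_config <- function(master_seed = 42L, reduced = TRUE,
                           out_dir = NULL) {
  lv <- grid_levels()
  list(master_seed = as.integer(master_seed),
       families = lv$families,
       lengths = if (reduced) c(500L, 1000L) else lv$lengths,
       betas = lv$betas,
       n_intensities = if (reduced) 16L else 128L,
       battery = "full",
       selection = selected_indices(),
       workers = 1L,
       out_dir = out_dir,
       redundancy_tol = 1e-8,
       edge_threshold = 0.6,
       control_loading = 0.2,
       n_factors = NULL,
       n_clusters = 2L,
       n_bins = 8L)
}

#' Validate a run configuration
#'
#' @param config Named list as produced by [default_config()] or
#'   [read_config()].
#' @return The config, with defaults filled in; invalid fields raise errors.
#' @export
validate_config <- function(config) {
  base <- default_config()
  for (nm in names(base))
    if (is.null(config[[nm]]) && nm != "out_dir") config[[nm]] <- base[[nm]]
  if (!is.finite(config$master_seed))
    stop("config: master_seed must be a finite integer", call. = FALSE)
  for (th in c("redundancy_tol", "edge_threshold", "control_loading")) {
    v <- config[[th]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("config: %s must lie in [0, 1]", th), call. = FALSE)
  }
  if (!all(config$families %in% signal_families()))
    stop("config: unknown signal family", call. = FALSE)
  if (config$n_intensities < 2L)
    stop("config: n_intensities must be >= 2", call. = FALSE)
  if (config$workers < 1L)
    stop("config: workers must be >= 1", call. = FALSE)
  config
}

#' Read / write a run configuration (YAML)
#'
#' The serialized configuration is written alongside the outputs of every
#' run; re-running from it reproduces all non-timing outputs exactly.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config`: the validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# md5 of a data.frame's CSV serialization, minus timing columns
stable_md5 <- function(df, drop_cols = character(0)) {
  df <- as.data.frame(df)
  df <- df[, setdiff(colnames(df), drop_cols), drop = FALSE]
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Fit the full complexity-structure analysis
#'
#' The package's main entry point: simulates the signal x noise grid,
#' computes the index battery on every cell, removes redundant indices,
#' and analyses the latent structure of the battery — Pearson correlations,
#' varimax factor model with the random-number manipulation check,
#' Ward-D2 clustering, correlation-network edges, greedy variance-explained
#' ordering of the selected subset, and expected-value profiles.
#'
#' @param master_seed Integer master seed; every stage is a pure function of
#'   it.
#' @param config Run configuration ([default_config()]); overrides
#'   `master_seed` when it carries one explicitly.
#' @param ... Fields overriding the configuration (e.g. `lengths`,
#'   `n_intensities`, `workers`).
#' @return Object of class `complexity_structure`: list with elements
#'   `config`, `grid`, `index_matrix`, `correlations`, `factor_model`,
#'   `control_check` (max |loading| of the random control and pass flag),
#'   `clusters`, `edges`, `selection`, `profiles`.
#' @export
complexity_structure <- function(master_seed = 42L,
                                 config = default_config(master_seed), ...) {
  dots <- list(...)
  config[names(dots)] <- dots
  if (!missing(master_seed)) config$master_seed <- as.integer(master_seed)
  config <- validate_config(config)

  grid <- build_grid(config$master_seed, families = config$families,
                     lengths = config$lengths, betas = config$betas,
                     intensities = config$n_intensities)
  registry <- index_registry(config$battery)
  m <- compute_index_matrix(grid, registry, workers = config$workers)
  m <- drop_redundant(m, tol = config$redundancy_tol)

  X <- analysis_matrix(m, covariates = TRUE)
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  varying <- is.finite(sds) & sds > 0
  if (!all(varying))
    message("complexity_structure: zero-variance columns excluded from factor analysis: ",
            paste(colnames(X)[!varying], collapse = ", "))
  corr <- pearson_matrix(X[, varying, drop = FALSE])
  nf <- if (is.null(config$n_factors))
    choose_n_factors(corr, n_obs = nrow(m)) else config$n_factors
  fa <- fit_factor_model(corr, n_factors = nf)
  fa$n_factor_panel <- attr(nf, "panel")
  ctrl <- max(abs(fa$loadings["random_control", ]))
  control_check <- list(max_loading = ctrl,
                        threshold = config$control_loading,
                        pass = ctrl < config$control_loading)

  corr_idx <- pearson_matrix(m, covariates = FALSE)
  cl <- ward_clustering(corr_idx, k = config$n_clusters)
  ed <- network_edges(corr_idx, threshold = config$edge_threshold)
  sel_names <- intersect(config$selection, attr(m, "index_cols"))
  sel <- greedy_variance_ordering(m, subset = sel_names)
  prof <- expected_value_profiles(m, selection = sel_names,
                                  n_bins = config$n_bins)

  structure(list(config = config, grid = grid, index_matrix = m,
                 correlations = corr, factor_model = fa,
                 control_check = control_check, clusters = cl, edges = ed,
                 selection = sel, profiles = prof),
            class = "complexity_structure")
}

#' Run the pipeline and write its outputs
#'
#' Executes [complexity_structure()] for a configuration and writes the
#' stage outputs as CSV to `config$out_dir`: `index_matrix.csv`,
#' `correlations.csv`, `loadings.csv`, `clusters.csv` (with merge heights),
#' `edges.csv`, `selection.csv`, `profiles.csv`, plus the serialized
#' configuration (`config.yaml`), per-index timings (`timings.csv`) and a
#' manifest (`manifest.csv`) listing each stage output with a content hash.
#' Timing columns are excluded from the hashes, so re-running the same
#' configuration gives identical hashes.
#'
#' @param config Run configuration with a non-NULL `out_dir`.
#' @return The `complexity_structure` fit, with the manifest attached as
#'   element `manifest`.
#' @export
run_pipeline <- function(config = default_config(out_dir = "tscomplexity_run")) {
  config <- validate_config(config)
  if (is.null(config$out_dir))
    stop("run_pipeline: config$out_dir must be set", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- complexity_structure(config$master_seed, config = config)

  out <- function(f) file.path(config$out_dir, f)
  m <- fit$index_matrix
  files <- list()
  files[["index_matrix.csv"]] <- as.data.frame(m)
  files[["correlations.csv"]] <- data.frame(index = rownames(fit$correlations),
                                            as.data.frame(fit$correlations))
  L <- fit$factor_model$loadings
  files[["loadings.csv"]] <- data.frame(index = rownames(L),
                                        as.data.frame(L),
                                        dominant = fit$factor_model$dominant,
                                        archetypicity = fit$factor_model$archetypicity)
  hc <- fit$clusters$hclust
  files[["clusters.csv"]] <- data.frame(index = names(fit$clusters$clusters),
                                        cluster = fit$clusters$clusters,
                                        merge_height = c(hc$height,
                                                         rep(NA, length(fit$clusters$clusters) - length(hc$height))))
  files[["edges.csv"]] <- fit$edges
  files[["selection.csv"]] <- as.data.frame(fit$selection)
  files[["profiles.csv"]] <- fit$profiles

  timing_cols <- list("selection.csv" = "cum_runtime")
  manifest <- data.frame(file = names(files), md5 = NA_character_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(files)) {
    f <- names(files)[i]
    utils::write.csv(files[[f]], out(f), row.names = FALSE)
    manifest$md5[i] <- stable_md5(files[[f]],
                                  drop_cols = timing_cols[[f]] %||% character(0))
  }
  utils::write.csv(data.frame(index = names(median_runtimes(m)),
                              median_runtime = unname(median_runtimes(m))),
                   out("timings.csv"), row.names = FALSE)
  write_config(config, out("config.yaml"))
  utils::write.csv(manifest, out("manifest.csv"), row.names = FALSE)
  fit$manifest <- manifest
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.complexity_structure <- function(x, ...) {
  m <- x$index_matrix
  cat("Complexity-structure analysis\n")
  cat(sprintf("  grid: %d cells (families: %s; lengths: %s; betas: %s; %d intensities)\n",
              nrow(x$grid), length(unique(x$grid$family)),
              paste(unique(x$grid$length), collapse = "/"),
              paste(sort(unique(x$grid$beta)), collapse = "/"),
              length(unique(x$grid$intensity_index))))
  cat(sprintf("  battery: %d indices (%d excluded)\n",
              length(attr(m, "index_cols")), length(attr(m, "excluded"))))
  cat(sprintf("  factors: %d (varimax); random-control max |loading| = %.3f (%s)\n",
              x$factor_model$n_factors, x$control_check$max_loading,
              if (x$control_check$pass) "pass" else "FAIL"))
  cat(sprintf("  selection: %d indices explain %.1f%% of battery variance\n",
              nrow(x$selection), max(x$selection$cum_variance)))
  invisible(x)
}

#' @export
summary.complexity_structure <- function(object, ...) {
  print(object)
  cat("\nGreedy selection curve:\n")
  print(as.data.frame(object$selection), digits = 4)
  cat("\nFactor variance explained:\n")
  print(round(object$factor_model$variance_explained, 4))
  invisible(object)
}

#' @export
coef.complexity_structure <- function(object, ...) object$factor_model$loadings

#' @export
plot.complexity_structure <- function(x, which = c("selection", "dendrogram"),
                                      ...) {
  which <- match.arg(which)
  if (which == "selection") plot(x$selection, ...)
  else plot(x$clusters, ...)
  invisible(x)
}
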