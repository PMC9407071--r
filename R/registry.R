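#' The selected 12-index battery
#'
#' Names of the twelve indices retained as a parsimonious, complementary
#' battery: conditional weighted permutation entropy, line length, bubble
#' entropy, multiscale weighted permutation entropy, five multifractal DFA
#' spectrum features, Hjorth complexity, SVD entropy and attention entropy.
#'
#' @return Character vector of 12 index names.
#' @export
selected_indices <- function() {
  c("CWPEn", "LL", "BubbEn", "MSWPEn", "MFDFA_Max", "Hjorth", "SVDEn",
    "MFDFA_Width", "MFDFA_Mean", "MFDFA_Peak", "MFDFA_Increment", "AttEn")
}

#' The extended classical battery
#'
#' Twelve additional widely used indices that enrich the structure analysis:
#' approximate, sample, permutation, weighted-permutation, dispersion and
#' binned Shannon entropies, the DFA scaling exponent, Higuchi/Katz/
#' Petrosian fractal dimensions, Hjorth mobility and entropy-of-entropy.
#'
#' @return Character vector of 12 index names.
#' @export
extended_indices <- function() {
  c("ApEn", "SampEn", "PEn", "WPEn", "DispEn", "ShanEn", "DFA",
    "HiguchiFD", "KatzFD", "PetrosianFD", "HjorthMobility", "EnofEn")
}

#' Build the index registry
#'
#' A registry is an ordered list of named entries, each holding a function
#' of one standardized series returning one (or, for the MFDFA family, five)
#' named index values with a fixed parameterization. The permutation family
#' uses delay 1 and embedding dimension 3 by default; ApEn/SampEn use
#' templates of length 2 with tolerance 0.2 sd; dispersion entropy uses 6
#' classes; MFDFA uses q in {-5..-1, 1..5} with 10 log-spaced windows.
#' `MFDFA_Fluctuation` is accepted as an alias of `MFDFA_Increment`.
#'
#' @param battery `"full"` (24 indices), `"selected"` (the 12 of
#'   [selected_indices()]) or `"extended"`.
#' @param config Named list of per-entry parameter overrides, e.g.
#'   `list(PEn = list(m = 4))`.
#' @return Object of class `index_registry`.
#' @export
index_registry <- function(battery = c("full", "selected", "extended"),
                           config = list()) {
  battery <- match.arg(battery)
  p <- function(entry, name, default) {
    v <- config[[entry]][[name]]
    if (is.null(v)) default else v
  }
  entries <- list(
    CWPEn = list(outputs = "CWPEn", fn = function(x)
      c(CWPEn = cwpen(x, m = p("CWPEn", "m", 3L), tau = p("CWPEn", "tau", 1L)))),
    LL = list(outputs = "LL", fn = function(x) c(LL = line_length(x))),
    BubbEn = list(outputs = "BubbEn", fn = function(x)
      c(BubbEn = bubble_entropy(x, m = p("BubbEn", "m", 3L),
                                tau = p("BubbEn", "tau", 1L)))),
    MSWPEn = list(outputs = "MSWPEn", fn = function(x)
      c(MSWPEn = mswpen(x, m = p("MSWPEn", "m", 3L),
                        tau = p("MSWPEn", "tau", 1L)))),
    MFDFA = list(outputs = c("MFDFA_Max", "MFDFA_Width", "MFDFA_Mean",
                             "MFDFA_Peak", "MFDFA_Increment"),
                 fn = function(x) mfdfa_features(mfdfa_spectrum(x))),
    Hjorth = list(outputs = "Hjorth", fn = function(x)
      c(Hjorth = hjorth_complexity(x))),
    SVDEn = list(outputs = "SVDEn", fn = function(x)
      c(SVDEn = svd_entropy(x, m = p("SVDEn", "m", 3L),
                            tau = p("SVDEn", "tau", 1L)))),
    AttEn = list(outputs = "AttEn", fn = function(x)
      c(AttEn = attention_entropy(x))),
    ApEn = list(outputs = "ApEn", fn = function(x)
      c(ApEn = approximate_entropy(x, m = p("ApEn", "m", 2L)))),
    SampEn = list(outputs = "SampEn", fn = function(x)
      c(SampEn = sample_entropy(x, m = p("SampEn", "m", 2L)))),
    PEn = list(outputs = "PEn", fn = function(x)
      c(PEn = permutation_entropy(x, m = p("PEn", "m", 3L),
                                  tau = p("PEn", "tau", 1L)))),
    WPEn = list(outputs = "WPEn", fn = function(x)
      c(WPEn = weighted_permutation_entropy(x, m = p("WPEn", "m", 3L),
                                            tau = p("WPEn", "tau", 1L)))),
    DispEn = list(outputs = "DispEn", fn = function(x)
      c(DispEn = dispersion_entropy(x, m = p("DispEn", "m", 3L),
                                    n_classes = p("DispEn", "n_classes", 6L)))),
    ShanEn = list(outputs = "ShanEn", fn = function(x)
      c(ShanEn = shannon_entropy_binned(x, n_bins = p("ShanEn", "n_bins", 10L)))),
    DFA = list(outputs = "DFA", fn = function(x) c(DFA = dfa_alpha(x))),
    HiguchiFD = list(outputs = "HiguchiFD", fn = function(x)
      c(HiguchiFD = higuchi_fd(x, k_max = p("HiguchiFD", "k_max", 10L)))),
    KatzFD = list(outputs = "KatzFD", fn = function(x) c(KatzFD = katz_fd(x))),
    PetrosianFD = list(outputs = "PetrosianFD", fn = function(x)
      c(PetrosianFD = petrosian_fd(x))),
    HjorthMobility = list(outputs = "HjorthMobility", fn = function(x)
      c(HjorthMobility = hjorth_mobility(x))),
    EnofEn = list(outputs = "EnofEn", fn = function(x)
      c(EnofEn = entropy_of_entropy(x, window = p("EnofEn", "window", 10L)))))
  keep <- switch(battery,
    full = names(entries),
    selected = c("CWPEn", "LL", "BubbEn", "MSWPEn", "MFDFA", "Hjorth",
                 "SVDEn", "AttEn"),
    extended = extended_indices())
  reg <- entries[keep]
  out_names <- unlist(lapply(reg, `[[`, "outputs"), use.names = FALSE)
  stopifnot(!anyDuplicated(out_names))
  structure(reg, output_names = out_names, class = "index_registry")
}

#' @export
print.index_registry <- function(x, ...) {
  cat(sprintf("Index registry: %d entries, %d index outputs\n",
              length(x), length(attr(x, "output_names"))))
  cat(" ", paste(attr(x, "output_names"), collapse = ", "), "\n")
  invisible(x)
}

#' Index names produced by a registry
#'
#' @param registry An `index_registry`.
#' @return Character vector of output column names.
#' @export
registry_outputs <- function(registry) attr(registry, "output_names")

#' Compute the full index battery on one series
#'
#' Evaluates every registry entry on the series with its fixed parameters.
#' A failing index is recorded as NA (with its error message kept) and never
#' aborts the batch; wall time per entry is recorded for relative comparison
#' only (multi-output entries share one timing).
#'
#' @param x Numeric series (standardized series expected).
#' @param registry An [index_registry()].
#' @return List with `values` (named numeric, one per registry output),
#'   `runtime` (named numeric, seconds per output) and `errors` (named
#'   character, messages of failed entries).
#' @export
compute_battery <- function(x, registry = index_registry()) {
  stopifnot(inherits(registry, "index_registry"), length(registry) > 0L)
  values <- runtime <- stats::setNames(
    rep(NA_real_, length(attr(registry, "output_names"))),
    attr(registry, "output_names"))
  errors <- character(0)
  for (entry_name in names(registry)) {
    entry <- registry[[entry_name]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(suppressWarnings(entry$fn(x)), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    runtime[entry$outputs] <- dt
    if (inherits(res, "error")) {
      errors[entry_name] <- conditionMessage(res)
    } else {
      values[entry$outputs] <- res[entry$outputs]
    }
  }
  list(values = values, runtime = runtime, errors = errors)
}
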