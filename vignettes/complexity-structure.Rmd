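---
title: "Mapping the latent structure of a complexity-index battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the latent structure of a complexity-index battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a battery, and why a bench

Dozens of scalar "complexity" indices exist for physiological time series,
and most empirical work picks a few by habit. The premise of this package
is that index choice should be empirical: generate signals whose character
and noise contamination are fully controlled, compute many indices on all
of them, and study which indices carry shared versus independent
information. The analysis makes no attempt to mimic real physiological
recordings; the simulated grid exists to create controlled, reproducible
variability across which index co-variation can be mapped. What transfers
to real data is the *relationship map* between indices, not any individual
index value.

## The simulation bench

Six base-signal families span stochastic trend (random walk), quasi-
periodicity (two incommensurate sinusoids), exact self-repetition (a 2 Hz
fundamental plus harmonics k = 1..5 with 1/k amplitudes — the
autocorrelation peaks above 0.5 at the fundamental lag), deterministic
chaos (two Lorenz systems, (σ, β, ρ) = (10, 2.5, 28) and (20, 2, 30)), and
a quasi-physiological mixture (band-limited delta–beta oscillations with
seeded random frequencies/phases over a small pink-noise floor). Signal
parameters the underlying study design leaves open — oscillator
frequencies, EEG-band weights, Lorenz integration settings — are fixed
here once: a nominal 100 Hz sampling rate, RK4 with dt = 0.01 (preset "a")
or 0.005 ("b"), a 1000-step transient discard, and per-seed perturbed
initial conditions. These are conventional values; nothing downstream is
sensitive to them beyond giving each family its qualitative character.

Colored noise is synthesized in the frequency domain (i.i.d. Gaussian
spectrum scaled by f^(−β/2), zero DC bin, inverse FFT), which gives the
target 1/f^β density in expectation; the generator recovers slopes −β
within ±0.3 at n = 4096. Noise is standardized *before* intensity scaling
and the sum re-standardized — the design leaves this open; fixing both
keeps the intensity parameter interpretable as a noise-to-signal amplitude
ratio and keeps indices comparable across intensities.

The full grid is 6 families × 6 lengths (500–3000) × 5 colors × 128
intensities (0.001–3, evenly spaced) = 23,040 cells. Every cell's seed is
a stable 31-bit hash of (master seed, family, length, color, intensity
rank), so the entire bench — including the uniform random manipulation-
check number drawn per cell — is a pure function of one master seed,
regardless of worker count.

**Desk scale.** The default configuration analyses 960 cells (lengths 500
and 1000, 16 intensities). The two shortest lengths were chosen so a full
run takes minutes on a single core; the structure analysis is about
correlations across cells, which stabilize long before the grid is dense.

## The index battery

Defaults for parameters the literature leaves to the user: the permutation
family uses delay τ = 1 and embedding dimension m = 3 (m+1 internally for
the conditional and bubble variants); ordinal ties break by position
(earlier element ranks lower) so patterns are always valid permutations;
entropies use natural logarithms, with normalized variants divided by
ln(m!). ApEn/SampEn use m = 2, r = 0.2·sd. MFDFA uses q ∈ {−5..−1, 1..5},
ten log-spaced windows from 10 to n/4, linear detrending, and both sweep
directions; α and f(α) come from finite differences of τ(q) = q·h(q) − 1.
Multiscale WPEn averages normalized WPEn over scales 1..min(20, n/100).
Attention entropy is the mean of the natural-log Shannon entropies of the
four inter-extremum interval distributions (max→max, min→min, max→min,
min→max); this is a deliberate, simpler variant of the original log2
formulation — monotone inputs are rejected as degenerate and strict
alternations score exactly 0. Bubble entropy returns 0 when both
swap-count distributions are degenerate (zero-uncertainty convention).
Entropy-of-entropy is likewise a documented simple variant: Shannon
entropy of windowed Shannon entropies over ten amplitude slices.

Degenerate inputs follow one rule: indices that are undefined (constant
series for variance-weighted entropies, monotone series for attention
entropy) raise errors when called directly, and are recorded as missing —
never aborting the batch — when computed through `compute_battery()`.

Numerical notes. Analytic anchors used in the tests: monotone series give
exactly 0 for the whole permutation family; a balanced period-4
alternation gives SVDEn = ln 2 at m = 2 (the embedding must contain full
periods, otherwise the two singular values differ at O(1/n)); MFDFA h(2)
is 0.5 on white and 1.5 on integrated white noise; the p = 0.7 binomial
cascade has most-probable exponent −log2(√(p(1−p))) ≈ 1.13, which the
spectrum peak reproduces within 0.15. One classic expectation did *not*
survive testing: the "pink noise declines more slowly than white across
scales" story from SampEn-based multiscale entropy does not hold for
normalized weighted permutation entropy (both curves are nearly flat at
these lengths; white simply stays above pink at every scale), so the tests
assert the separation, not the decline.

## The structure stage

Redundancy pruning drops the later-registered member of any index pair
with |r| at 1 (tolerance 1e−8). Correlations are pairwise-complete
Pearson; pairs with fewer than 30 joint observations become missing. The
factor count is the mode of four estimators — Horn's parallel analysis
(mean simulated eigenvalues), Kaiser, the scree acceleration factor, and
Velicer's MAP — with ties broken toward fewer factors and a fallback to
parallel analysis when all four disagree; an identity-like matrix returns
1, the minimal usable count. Extraction is principal-axis factoring
(iterated communalities from squared multiple correlations, eigenvalue
clipping for non-PSD input) with varimax rotation, which preserves
communalities; archetypicity is 1/exp(entropy of the squared-loading
profile), exactly 1 for a single-factor profile. Clustering uses Ward D2
on sqrt(2(1 − r)) with *signed* correlations — randomness- and
predictability-type indices are anti-correlated by design and should be
distant; an `absolute = TRUE` flag provides the |r| alternative. "Variance
explained by a subset" is operationalized as the mean over all index
columns of the OLS R² on the subset (computed from the correlation matrix,
pseudoinverse for collinear subsets), and the selection curve is a greedy
forward pass over the chosen 12; collinear candidates are placed with zero
gain rather than dropped.

## What passing tests do and do not show

The random manipulation check behaves as intended: on the 960-cell grid
the control number's largest absolute loading is ~0.02–0.05, an order of
magnitude under the 0.2 criterion, and it is never any factor's dominant
index. Planted 2-, 3- and 4-factor batteries (loadings 0.8, n = 2000) are
recovered exactly, with 100% dominant-factor assignment accuracy.

One property of the original full-battery design does **not** reproduce at
desk scale, and the package reports it honestly rather than engineering it:
with a 24-index battery of which the 12 selected indices are half, *any*
12-subset explains 93–95% of battery variance (the curve saturates), so
the selected set beats a random dozen only ~60–70% of the time, not ≥90%.
That contrast requires a battery much larger than the selection — with 112
indices a random dozen leaves real coverage gaps; with 24 it cannot. The
selection's value at this scale is its interpretability and cost profile,
not a variance-coverage edge.

## Known limitations

Index values are reported raw; heavy-tailed indices (Hjorth complexity,
Katz FD, the MFDFA features on short noisy series) weaken Pearson
correlations relative to rank-based alternatives. The EEG surrogate is a
stationary band mixture — no spindles, artifacts, or nonstationarity.
Runtime columns are wall-clock and meaningful only as relative orderings
within one run (multiscale indices cost hundreds of times more than line
length; that ordering is stable, the magnitudes are not). The battery is
24 indices, not a census: conclusions about "the structure of complexity
indices" extend only as far as the families represented.
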