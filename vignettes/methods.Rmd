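---
title: "Methods: time-to-threshold enumeration from plate-reader growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-to-threshold enumeration from plate-reader growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platecount)
```

## The measurement model

Each well of a 96-well plate is inoculated with a fixed volume (5 µL by
default) of a sample dilution and grown in a plate reader that records
optical density (OD₆₆₀) on a fixed time grid. During exponential growth the
biomass `N(t)` doubles every `Td` minutes, so the time `t_c` at which the
raw OD first reaches an absolute threshold (0.3 for the yeast- and E. coli-
like strains, 0.15 for the lactobacillus-like strain) is a clock for the
inoculum size: a well seeded with half as many viable cells crosses exactly
one doubling time later. Inverting this,

    Vn = 2^(-(t_c - t_c,ref) / Td_ref)

is the viable fraction of a well relative to a reference well, and an
absolute count follows from one conventional spread-plate count `N_min`
(CFU per inoculum) at the reference dilution:

    Q = N_min × Vn × (1000 / V_µL)   # exactly ×200 at V = 5 µL

Ten-fold dilution steps must therefore drop `log10(survival)` by one decade
per step. The package calibrates this *linear range* by regressing
`log10(survival)` on the dilution exponent over every contiguous run of at
least three consecutive exponents and accepting runs with slope within
1 ± 0.1 and R² ≥ 0.99; the longest accepted run wins, with ties going to
the less-diluted run. The width of the accepted run is the dynamic range in
decades.

## Per-well kinetics

For each well the package estimates:

* **Baseline**: the median of the first `baseline_n` (default 3) readings,
  or a user-supplied known medium background. Corrected OD is floored at
  `1e-4` to keep logarithms finite.
* **Threshold crossing**: linear interpolation of the *raw* OD onto the
  absolute threshold. Wells already at threshold at `t = 0` are labelled
  `saturated`; wells that never reach it within the run are `censored`.
* **Doubling time**: the maximum slope of `log2(corrected OD)` over a
  sliding window (default width 5 points) restricted to a fitting band
  `[max(3·noise_sd, 0.01·od_max), 0.75·od_max]`. The band keeps the fit
  out of the baseline noise (lower edge) and out of the logistic bend
  (upper edge); the `0.01·od_max` term is this package's addition so the
  lower edge scales with signal when noise is negligible.
* **Tangent lag**: the intersection of the max-slope tangent with the
  initial log-OD level, `lag = t_w - (log2(OD_w) - log2(OD_0)) / s`,
  clamped at zero.

## Identifiability of the tangent lag

With self-estimated baselines the initial biomass signal is subtracted
together with the medium background, so the corrected initial OD collapses
to the floor and the tangent construction measures the time to grow from
the floor, not from the true inoculum: the lag is **not identifiable**. It
becomes identifiable when the medium background is known independently
(e.g. from blank wells), which preserves the inoculum's own signal. Pass
`fit_config(background = <blank OD>)` to use this mode; the lag-recovery
tests and the heat-damage lag decomposition do. Survival and doubling time
do not depend on this choice.

## Noisy data settings

The max-over-windows slope statistic is biased upward under multiplicative
reader noise: on the log2 scale the noise standard deviation is
approximately `cv · OD_raw / (x · ln 2)`, which blows up near the bottom of
the fitting band, and the maximum over many windows selects the luckiest
noise excursion. At 5% OD noise the default settings can halve the
apparent doubling time and break calibration. The documented mitigation is

```r
cfg <- fit_config(window_w = 15, median_filter = TRUE)
```

a 3-point running median before fitting plus a wider window, which averages
the noise down before the max is taken. With these settings the doubling
time is recovered within ~3% and the full 7-decade calibration within 25%
of truth at 1–5% noise. Use them whenever curves are visibly noisy; the
defaults are tuned for clean curves.

## Reference selection and saturated wells

The provisional reference is the least-diluted exponent at which every
replicate crossed the threshold strictly after `t = 0`. Its mean crossing
anchors the survival clock, but its doubling time may be distorted by
baseline subtraction when the inoculum itself contributes measurable OD, so
`Td_ref` is taken from the *most*-diluted fully detected exponent, whose
inocula are smallest. Dilution points containing saturated wells (crossing
at `t = 0`) only bound the survival from below and are excluded from the
linear-range search.

## Anchoring the absolute count

`quantify_run()` accepts the spread-plate anchor at any measured dilution:
if `n_min_exponent` differs from the accepted reference, the anchor is
rescaled through the measured survival ratio at that exponent. The
noise-free recovery tests anchor at 10⁻², exercising the rescaling path;
the noisy tests anchor at the reference itself, mirroring the hybrid
protocol (one spread plate plus the microplate ladder).

## Trace statistics

For trace samples the package provides the limiting-dilution (MPN)
estimator `λ = -ln(p₀)` from the sterile-well fraction, exact
binomial occupancy probabilities for colonies scattered over grid sectors
(with the Poisson approximation reported alongside), and the
count-limited dynamic-range floor `floor(log10(N_min)) + 1` decades.

## The simulator as oracle

`simulate_well()` grows a logistic-with-lag culture,
`N(t) = K / (1 + (K/n0 - 1) e^{-µ(t - lag)})`, maps cells to OD through
`od_per_cell` plus a background, and multiplies each reading by unit-mean
lognormal noise with a chosen CV. `simulate_dilution_series()` seeds each
well with a Poisson draw at `λ = stock · 10^e · V/1000` and returns the
run, the layout and a truth table; `simulate_heat_treatment()` adds
binomial thinning (kill) and a lag extension (sublethal injury). Every
simulator is deterministic under a seed and restores the caller's RNG
state. Known simplifications: no well-to-well temperature or evaporation
gradients, no strain interactions, a single global background, and
diauxic/biphasic curves are out of scope.

## Problem sizes

All analyses operate on one 96-well plate at a time (≤ 96 series of
~300 time points); every function in the package runs in well under a
second on one CPU, and the full synthetic test suite in seconds.
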