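---
title: "Methods: from transmitted-intensity traces to free-energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transmitted-intensity traces to free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanotrap)
```

## The signal and its model

A nanoaperture optical tweezer reads out a trapped protein through the
laser power transmitted through the aperture, digitised as an APD voltage
at 100 kHz with a least significant bit (LSB) of 0.002441 V. The package
models a trapped-segment voltage as

> level of the current conformational state
> &plus; thermal motion in the optical potential (Ornstein--Uhlenbeck,
>   corner frequency f~c~, stationary sd σ~t~)
> &plus; white measurement (laser) noise, about 20× smaller than σ~t~
> &plus; quantisation to the LSB grid,

with conformational dynamics as a two-state continuous-time Markov chain
that shifts the level but not the instantaneous thermal coordinate. Every
analysis stage in the package is the inverse of one piece of this model,
and `simulateTrace()` is its exact forward simulation: OU updates use the
exact discretisation `x <- x*exp(-dt/tau) + sigma*sqrt(1-exp(-2 dt/tau))*xi`
(stationary statistics exact at any sampling rate), dwell times are drawn
from their exponential distributions on the continuous time axis and
rounded to the nearest sample, and the seed is split into independent
streams for dwells, OU noise and measurement noise so changing one leaves
the others untouched. An optional `minDwell` refractory time (shifted-
exponential dwells; default 0, i.e. exactly Markov) generates telegraph
signals whose switches are guaranteed to be resolvable by a 10 Hz filter —
the regime used in the step-detection validation.

Defaults place the simulation in the observable regime of a trapped ~76 kDa
protein: two levels 0.110 and 0.140 V (mean 0.125 V, so 6% of the mean is
0.0075 V, the single-state sd scale), f~c~ = 46 Hz, both switching rates
1 Hz. What the generator does *not* emulate: drift and 1/f laser noise,
line-frequency ripple, surface sticking, partial trap escapes, and any
intrinsic within-state level spread beyond thermal motion. Passing tests
on synthetic data therefore validate the estimators under the stated noise
model, not the instrument's full pathology; the detrending and
noise-floor-fitting stages exist precisely for the real-data effects the
generator omits.

## Trapping-event detection

A trapping event is a sustained jump of the 10 Hz low-pass signal above
`baseline mean + jumpSigma × baseline sd` (defaults 5 and the first 1 s of
trace) accompanied by an increase of the high-frequency residual rms —
thermal motion of the trapped molecule. Two robustness choices matter:

* "remains above threshold for `sustain` = 0.5 s" is implemented as *at
  least 95% of the sustain window above threshold*, because the trapped
  signal's own low-frequency fluctuation dips below any fixed line;
* the rms comparison excludes a `guard` = 0.1 s neighbourhood of the onset
  (the filter smears the edge into both sides) and requires a 5% margin
  (`noiseFactor = 1.05`), since with equal noise levels a plain `>` would
  be decided by sampling fluctuation.

The analysed trapped segment starts `guard` seconds after onset so the
transition edge contaminates neither spectra nor histograms. Baseline
statistics are computed strictly before the onset sample. Indices are
1-based and inclusive throughout, the natural R convention.

## Spectral estimation and the Lorentzian fit

`estimatePSD()` is a Welch estimator: 1 s Hann-tapered sub-segments, 50%
overlap, one-sided scaling such that the integral of the density equals
the variance (Parseval; verified on white noise in the tests). The 1 s
sub-segment default trades 1 Hz resolution against variance — adequate for
corners of tens to hundreds of Hz over a 10 s analysis window.

`fitLorentzian()` fits `S(f) = s0/(1+(f/fc)^2) + floor` to `log10 S` over
5 Hz–5 kHz after averaging the spectrum into ~50 log-spaced bins, so each
decade carries comparable weight. A subtle but important numerical choice:
the *model is averaged within each bin exactly as the data are*, so the
binning bias cancels and an exact Lorentzian input is recovered to
numerical precision. Parameters are optimised on the log scale
(positivity for free), by Levenberg--Marquardt, from a deterministic start
(`s0` = mean density of the lowest decade, `fc` = first frequency below
`s0/2`). The additive white floor is fitted by default: real traces have
one, and omitting it biases `fc` upward; it can be fixed to 0. The fitted
model satisfies `S(fc) - floor = s0/2` identically — the 3 dB definition
of the corner.

## Zero-power extrapolation

`fitZeroPower()` is unweighted OLS of corner frequency on the mean APD
voltage of the trapped segment (laser power in mW is an equivalent
abscissa up to proportionality; the intercept at zero is the same
quantity). No per-point uncertainties are available from a single fit, so
weighting is optional rather than default, and the module reports effect
sizes with standard errors, never significance claims. Negative intercepts
are physically meaningful (net repulsive surface interaction) and returned
as-is. Sample comparisons (`compareZeroPower()`) are made on the
*magnitude* of the intercept, with a z-like score from the root-sum-square
of the standard errors.

## Step detection

Candidates come from the first difference of the 10 Hz zero-phase
Butterworth low-pass (4th order, forward--backward). The published rule —
flag samples where |d| exceeds 3× the standard deviation of |d| over the
whole segment — has a self-defeating property on step-rich traces: the
steps themselves inflate sd(|d|) several-fold, pushing the threshold up to
the step amplitude. The package therefore re-estimates the scale once with
the first-pass candidate runs excluded (`refineThreshold = TRUE`; the
single-pass variant remains available). Candidate runs separated by less
than the 5 ms guard merge, and each run collapses to its
extremal-derivative sample: one physical step, smeared over tens of
milliseconds by the filter, yields one candidate.

Validation distinguishes genuine steps from transients by local statistics
in 0.1 s windows before and after the candidate (excluding ±5 ms around
it): the level change must exceed `levelFactor = 2` times the larger local
standard deviation. These statistics are measured on the **raw** signal:
its local sd is the thermal fluctuation amplitude that a genuine
conformational step must beat, whereas the filtered signal's within-window
sd underestimates the noise so badly that slow noise wander passes the
test. A 1 ms transient fails validation because both windows straddle the
same level.

Labelling (`assignStates()`) is one-dimensional two-means over segment
levels with deterministic extreme-point initialisation — no RNG in the
labelling path. Label 0 is the lower-voltage state; occupancies are
duration-weighted and sum to 1. A single segment, or segments with
indistinguishable levels, yield one state with occupancy 1.

## Free-energy landscapes

The chain is dither → histogram → Richardson--Lucy → Boltzmann inversion:

1. **Dither**: seeded uniform noise of one LSB total width removes the
   quantisation comb before histogramming. Bins default to one LSB (finer
   bins would re-introduce comb structure relative to the remaining
   discreteness; coarser bins blur the ~12-bin level separation), padded
   by 3 bins beyond the data range, normalised to unit integral.
2. **Richardson--Lucy** (51 iterations, fixed, no early stopping) removes
   the Gaussian broadening of thermal translational/rotational motion.
   The PSF σ is estimated as the standard deviation of the longest
   single-state stretch of the state sequence — a segment dominated by
   thermal motion, the measurement noise being ~20× smaller and therefore
   not subtracted in quadrature — with 6% of the segment mean as fallback.
   The transfer matrix is a ±5σ-truncated Gaussian with *columns
   renormalised to unit sum*; with that convention each multiplicative RL
   update maps total mass exactly onto the data mass, so non-negativity
   and normalisation hold at every iteration by construction rather than
   within a tolerance. Denominators carry an ε = 1e-12 guard.
3. **Boltzmann inversion**: U(V) = −ln P(V) in k~B~T units, defined only
   where the density exceeds 1% of its peak (log of near-empty bins is
   noise), shifted so the global minimum is 0. Conversion to Joules via
   k~B~ = 1.380649e-23 J/K is a display option (`energyJoules()`).

Local minima are defined bins strictly below both neighbours; on a flat
plateau the leftmost bin wins; if more than two minima exist the two
lowest are kept. The sign convention is fixed and documented:
**ΔG = U(higher-voltage minimum) − U(lower-voltage minimum)**, so ΔG > 0
means the lower-voltage (compact) state is more stable, and a *maximum* of
ΔG(T) is the temperature of maximum stability of that state. Fewer than
two minima raise a "single-state landscape" condition, which the pipeline
converts to an `NA` ΔG with a warning.

Local temperature comes from the laser power via `thermalModel()`
(0.58 K/mW for a 980 nm laser at a gold double nanohole). The ambient
temperature is a required user input, not a constant: the power-to-
temperature offset depends on the experiment. `fitStabilityCurve()` is an
ordinary quadratic least-squares fit with vertex −b/(2a), flagged
`isMaximum` only when the curvature is negative.

## Classification

The published gate — corner frequencies of 36–56 Hz at 9 mW are
conalbumin, lower ones ovalbumin — is implemented literally, with the
guard that all events must lie within 10% of the reference power because
f~c~ scales with power. An unsupervised alternative (`two_means`) clusters
standardised (f~c~, fluctuation amplitude) pairs with deterministic
extreme-point initialisation; the higher-frequency cluster takes the
conalbumin label. The gate uses f~c~ only; the amplitude's role in the
original clustering is not specified, so it participates only in the
unsupervised mode.

## Numerical choices worth knowing

* `signal::filtfilt` starts from zero state; all filtering goes through an
  odd-reflection pad of 10 filter time constants with the mean removed and
  restored, which suppresses the startup transient to numerical noise.
  Residual edge effects are confined to the pad-joint neighbourhoods.
* The on-disk binary trace format is little-endian float64 plus a JSON
  sidecar; float64 makes `readTrace(writeTrace(x))` bit-exact (quantised
  multiples of 0.002441 V are not float32-representable; float32 remains
  available where file size matters, exact to ~1e-7 relative).
* Degenerate inputs fail loudly and early: traces shorter than 2 samples,
  non-finite samples, cutoffs at or above Nyquist, densities that do not
  integrate to 1, stability fits with fewer than 3 distinct temperatures.
* ΔG read-out noise: the deconvolved wells of an idealised two-level
  simulation are nearly delta-shaped, so the minimum-bin energies inherit
  amplified histogram noise; with ~1.4e4 effectively independent samples
  per 100 s trace (the OU correlation time sets the effective n) the
  per-trace ΔG error is unbiased with a spread of order 0.1 k~B~T. The
  validation suite therefore summarises recovery by the median over
  seeded replicates. Real proteins have intrinsic within-state spread that
  keeps the deconvolved wells wider and this read-out better behaved.

## Problem sizes used in validation

Corner-frequency recovery is validated at the instrument's native
100 kHz sampling (10 s traces, corners 20–500 Hz, 20 seeds per corner).
Stages whose physics does not depend on oversampling run at 10–20 kHz —
the 10 Hz filter, tens-of-Hz corners and second-scale dwells are two to
three decades below even those Nyquist frequencies — with durations of
10 s (spectral), 20 s (telegraph detection), 100 s (ΔG recovery) and
200 s per temperature (stability scan, ~600 switches per trace so that
occupancy sampling noise does not dominate the vertex). These sizes are
the package's choice of a well-powered but desk-scale validation design.

## Known limitations

* The state model is strictly two-state; multi-step staircases (as seen
  for iron-bound conalbumin) are detected as transitions but labelled into
  two clusters. No hidden-Markov or Bayesian change-point inference.
* No conversion of corner frequency to stiffness in N/m (needs the drag
  coefficient) and no kinetic barrier analysis (Kramers) — only state
  energies.
* The zero-power intercept is reported as an effect size with standard
  errors; the package deliberately attaches no hypothesis tests.
* Landscapes are one-dimensional in transmitted voltage; no attempt is
  made to infer a structural reaction coordinate.
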