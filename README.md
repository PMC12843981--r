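# nanotrap

Analysis of nanoaperture optical tweezer (NOT) single-protein traces in R.

A nanoaperture optical tweezer holds a single protein (here: conalbumin, a
76 kDa iron-transport protein, in its iron-bound *holo* and iron-free *apo*
forms) in the optical hot-spot of a double nanohole in a gold film. The only
observable is the laser power transmitted through the aperture, recorded as
an avalanche-photodiode (APD) voltage at 100 kHz. Everything about the
trapped molecule — trap stiffness, surface electrostatics, conformational
dynamics, and state thermodynamics — has to be extracted from this one
noisy, quantised time series. `nanotrap` implements that extraction as a
tested pipeline, together with a synthetic-trace generator with exact ground
truth so that every stage can be validated without instrument data.

## What it computes

**Corner-frequency spectroscopy.** After removal of linear drift, the power
spectral density of a trapped segment is estimated by Welch averaging and
fitted with a Lorentzian

S(f) = S₀ / (1 + (f/f_c)²) + S_floor,

where the corner frequency f_c (the 3 dB roll-off) is proportional to the
trap stiffness. The fit is performed on log₁₀ S over log-spaced frequency
bins, with the model averaged within bins exactly as the data.

**Zero-power extrapolation.** f_c is linear in transmitted power; ordinary
least squares of f_c on the mean APD voltage gives the intercept f_c(0),
the *residual* corner frequency caused by electrostatic protein–surface
interaction. A negative intercept measures how much confining potential
would be needed to cancel a net repulsive interaction; iron-bound
conalbumin shows a much larger magnitude than the iron-free form.

**Two-state recognition.** Conformational transitions appear as discrete
jumps between two transmission levels. Candidates are taken from the first
derivative of the 10 Hz low-pass signal (threshold: 3× the standard
deviation of the absolute derivative, re-estimated once with candidate runs
excluded) and validated against the local mean and standard deviation in
0.1 s windows of the raw signal, which rejects millisecond transients.
Segments are labelled by two-means into the lower-voltage (0) and
higher-voltage (1) state, with occupancies and dwell times.

**Free-energy landscapes.** The trapped-segment voltage distribution is
dithered with ±LSB/2 uniform noise (LSB = 0.002441 V), histogrammed,
deconvolved by 51 Richardson–Lucy iterations with a Gaussian point spread
function (σ = the standard deviation of the longest single-state stretch,
the thermal-motion broadening), and converted to Gibbs free energy by
Boltzmann inversion U(V) = −k_B T ln P(V). The free-energy difference
ΔG = U(high-V minimum) − U(low-V minimum) between the two wells, tracked
across laser powers (local temperature rises by 0.58 K/mW), is fitted with
a quadratic whose vertex is the temperature of maximum stability of the
lower-voltage state.

**Event classification.** Egg-white trapping events are classified by a
corner-frequency gate (36–56 Hz at 9 mW → conalbumin; lower → ovalbumin)
or by unsupervised two-means on (f_c, fluctuation amplitude).

## Worked example

```r
library(nanotrap)

# a two-state trace with known ground truth: levels 0.110/0.140 V,
# corner frequency 46 Hz, thermal sigma 5 mV, second-scale switching
sim <- simulateTrace(simulationConfig(
  duration = 20, samplingRate = 2e4,
  states = list(stateSpec(0.110, 46, 0.005), stateSpec(0.140, 46, 0.005)),
  rates = c(1.5, 1.5), minDwell = 0.35, seed = 1))

seq <- assignStates(detectTransitions(lowpassTrace(sim$trace, 10)))
seq
#> StateSequence: 21 validated transitions, 22 segments
#>   state 0: 0.395, state 1: 0.605

# corner-frequency spectroscopy runs on single-state (non-switching) traces
one <- simulateTrace(simulationConfig(
  duration = 10, samplingRate = 2e4,
  states = list(stateSpec(0.125, 46, 0.0075)), rates = c(0, 0), seed = 2))
fit <- fitLorentzian(estimatePSD(detrendVoltage(samples(one$trace)), 2e4))
fit
#> LorentzianFit: fc = 45.74 Hz, s0 = 7.89e-07 V^2/Hz, floor = 9.29e-11 V^2/Hz
#>   band [5, 5000] Hz, log10 rss 0.1633
```

All 21 simulated switches are recovered, and the detected occupancy
(0.395/0.605) matches the ground-truth realised occupancy (0.394) of this
particular trace. The fitted corner frequency (45.7 Hz) recovers the
simulated 46 Hz within the estimator's few-percent dispersion.
`landscapePipeline()` turns a trapping event plus its state sequence into
an `EnergyLandscape` whose `deltaG()` approximates ln(occupancy ratio) —
the consistency check used throughout the test suite.

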