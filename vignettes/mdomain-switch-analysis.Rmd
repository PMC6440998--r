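---
title: "Photon-level analysis of a fast conformational switch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-level analysis of a fast conformational switch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchfret)
```

## The system and the measurement

The M domain of the bacterial disaggregase ClpB is a coiled-coil appendage
that toggles between a tilted "active" conformation and a parallel
"inactive" one, and this toggle gates the machine's collaboration with the
DnaK chaperone. switchfret implements the complete analysis chain used to
characterize such a switch from diffusion-based single-molecule FRET:
photon-level simulation, burst processing, photon-by-photon hidden Markov
inference of the exchange kinetics, thermokinetic post-processing, and
FRET-restrained rigid-body triangulation of the domain orientation.

In the experiment being emulated, single double-labeled molecules diffuse
through a confocal spot and emit bursts of photons. Donor and acceptor
lasers alternate at a 3:1 pulse ratio (pulsed interleaved excitation, PIE)
at 40 MHz, so every photon carries a detection channel and an excitation
slot. FRET efficiency is computed from donor-excitation photons; the
stoichiometry computed from both slots sorts double-labeled molecules from
single-dye contaminants. The exchange of interest is fast — hundreds of
microseconds — so it blurs the per-burst FRET histogram and must be read
photon by photon.

## The generative model

`simulate_photon_stream()` produces a synthetic measurement from a
`kinetic_model` (per-state efficiencies `E`, conservative rate matrix `Q`)
and a `sim_config`. Its structure, and the deliberate simplifications:

* **Bursts are rectangular** with exponentially distributed durations
  (default mean 1 ms) and exponential inter-burst gaps (default 5 ms),
  rather than arising from explicit 3-D diffusion through a Gaussian focus.
  This reproduces the burst-size and interphoton statistics every
  downstream stage depends on, at a fraction of the cost; brightness
  fluctuation within a transit is not modelled.
* **The clock is integral.** Arrival times are integer ticks of the laser
  repetition period (25 ns), mirroring TCSPC hardware. All interphoton
  intervals downstream are clock-quantized.
* **Colors.** Within a burst, the conformational state follows an exact
  Gillespie simulation of the continuous-time Markov chain, started from
  the stationary distribution. A donor-slot photon is a direct-excitation
  acceptor photon with probability `direct_excitation`; otherwise it is
  FRET-transferred with the current state's probability `E`, and a
  donor-emitted photon is re-classified into the acceptor channel with
  probability `leakage`. Acceptor-slot photons report the acceptor dye.
  This reclassification model is chosen so that the burst-processing
  correction is its exact inverse and estimate-then-apply round-trips.
* **Species brightness.** Donor-only and acceptor-only contaminants emit at
  the full in-burst rate through the photon classes available to them
  (donor slots only, and acceptor slots plus direct-excitation events,
  respectively). With slot-proportional brightness an acceptor-only
  molecule would fall below the burst-search threshold and the
  direct-excitation factor would be unmeasurable; real instruments balance
  excitation powers for the same reason.
* **Background** fills the inter-burst gaps at configurable per-channel
  rates (defaults 1500 and 800 s^-1). During bursts the signal exceeds
  background by two orders of magnitude, matching the choice not to
  background-correct burst quantities.
* **Not modelled:** blinking, bleaching, triplet states, optics. Passing
  tests on this generator therefore demonstrates the correctness of the
  analysis under the stated statistical model, not robustness to
  photophysical artifacts absent from it.

A single RNG stream seeded from `rng_seed` drives every draw in a
documented order (per burst: species, duration, state path, photon times,
slots, colors; then background), so simulations are bitwise reproducible.

## Burst processing

`detect_bursts()` smooths interphoton times with a centered running average
of 15 photons and takes maximal runs below the 10 microsecond cutoff; run
edges expand outward over any raw interval still below the cutoff, which
makes edge assignment deterministic. A burst must hold at least 30 photons,
counted across both channels and both excitation slots (the most literal
reading of the selection rule). Raw quantities per burst are
`E_raw = n_DA / (n_DD + n_DA)` and
`S_raw = (n_DD + n_DA) / (n_DD + n_DA + n_AA)`; degenerate denominators are
flagged, never silently dropped, and raw values are not clipped.

`estimate_corrections()` reads the two artifact factors off the single-dye
populations: leakage is the pooled apparent E of the donor-only population
(S above 0.9 by default) and direct excitation comes from the acceptor-only
population's stoichiometry, rescaled by the PIE pulse ratio to a
per-donor-slot-event probability. `apply_corrections_and_filter()` then
restores leaked photons to the donor channel (`n_DD / (1 - l)`), subtracts
leakage and direct-excitation contributions from `n_DA`, and keeps bursts
inside a stoichiometry window (default [0.3, 0.8]; the window is stated
only graphically in the source experiments, so it is a configurable default
here, not an assertion). Corrected E/S may fall slightly outside [0, 1] and
are reported as-is with a flag. With the generator's reclassification
model, the corrected E of a double-labeled burst is exactly unbiased — the
basis of the round-trip tests.

`shot_noise_reference()` redraws each burst's acceptor count binomially at
a fixed efficiency, giving the histogram a static molecule would produce;
dynamic exchange broadens the measured histogram beyond it (about
three-fold for the wild-type model).

## Photon-by-photon kinetic inference

The likelihood treats each burst as a hidden continuous-time Markov chain
observed through photon colors: between photons separated by `dt` the state
distribution propagates by `exp(Q dt)`, and each photon is acceptor-colored
with its state's efficiency. Bursts are independent and start from the
stationary distribution. Two implementation decisions matter:

* **Propagators by eigendecomposition.** `exp(Q dt)` is evaluated for all
  distinct clock-quantized intervals at once from a single
  eigendecomposition of `Q` (with a scaling-and-squaring fallback when the
  eigenvector basis is ill-conditioned). Because intervals are integer
  ticks, a few thousand distinct propagators cover hundreds of thousands of
  photons. At clock resolution this is mathematically equivalent to
  recursing over hidden transitions tick by tick; the equivalence is
  enforced in tests against exhaustive path enumeration with an independent
  matrix exponential.
* **Direct likelihood ascent.** `fit_h2mm()` maximizes the exact forward
  log-likelihood by quasi-Newton ascent on an unconstrained scale (logit
  efficiencies, log rates) instead of expectation-maximization. For a
  continuous-time chain observed at irregular photon times the EM M-step
  has no closed form without re-discretizing to the clock, whereas the
  forward likelihood is cheap and exact; with at most a dozen free
  parameters, quasi-Newton converges in a few hundred evaluations. The
  reported `loglik_trace` is the best-so-far value over objective
  evaluations and is non-decreasing by construction, the ascent analogue of
  the EM monotonicity guarantee.

Initialization takes state efficiencies from quantiles of the per-burst
acceptor fractions (descending) and all rates at one tenth of the photon
rate; five random restarts (jittered efficiencies, log-normal rate jitter)
guard against local maxima, with best-of selection. Convergence is a
relative log-likelihood change below 1e-6 or 1000 iterations; a
non-converged fit is flagged, not discarded. The default connectivity is
sequential (1-2-3 chain), the topology found for the M domain; full
connectivity is available. Fitted models are reported in canonical order —
descending efficiency, so state 1 is the high-E active state — and
emission uses raw (uncorrected) colors, so fitted efficiencies are on the
raw scale of the burst histogram. Uncertainties come from
`h2mm_bootstrap()` (20 burst resamples by default, refit from the point
estimate), kept out of the fitting path so a single fit stays cheap.

`select_state_number()` reports, per candidate K, the log-likelihood, a
Bayesian information criterion (`-2 logL + p log n_photons`), and the
recoloring discrepancy below; the recommendation is the smallest K whose
recoloring discrepancy passes, since recoloring is the validation this
field trusts, with the BIC minimum as fallback.

## The four validation analyses

**Recoloring.** `recolor()` re-simulates hidden state paths over each
burst's real photon arrival times from the fitted model and redraws the
colors; a model that describes the data regenerates the measured burst-E
histogram including its dynamic broadening. `recoloring_check()` reduces
the comparison to a Pearson chi-square over histogram bins (sparse bins
pooled to an expected count of five; expectation averaged over ten
recolorings), passing below a reduced chi-square of 2. The generating model
scores near 1; a model with ten-fold-wrong rates scores in the tens,
because faster exchange time-averages the histogram into a narrow peak.

**Dwell times.** Viterbi paths are segmented at midpoints between
opposite-state photons. Edge dwells are censored by the burst window, so
exit rates use the censoring-aware exponential estimator — observed exits
divided by total time at risk — which is unbiased under censoring alone.
There is, however, a genuine resolution limit: a dwell containing at most
one photon is invisible to any photon-level decoder, and its neighbours
fuse, inflating apparent dwells by roughly `k / (k + r)` terms (k the
relevant rate, r the photon rate). At the wild-type flux of 190,000
photons/s and rates above 5000 s^-1 this bias reaches 10-16%; the package's
dwell validation therefore runs in a well-separated regime (state
efficiencies 0.99/0.01, 600,000 photons/s) where the residual bias is a few
percent. Dwell means at standard flux should be read as upper bounds — they
are labelled as such in the analysis drivers.

**Segmentation.** Each Viterbi dwell with at least `min_photons` photons
contributes one efficiency value. Because a segment sits within one state,
the segment histogram resolves the state efficiencies that time averaging
blurs in the per-burst histogram, with peak variance shrinking as `1/m`.

**Cross-correlation.** `donor_acceptor_crosscorrelation()` bins each
burst's donor-excitation photons by color (default 10 microsecond bins),
pools the normalized donor-acceptor product over bursts and lags, and fits
`G(tau) = a + b exp(-tau / tau_R)`. Anticorrelated FRET dynamics give
`b < 0` relaxing to the baseline; for a two-state system
`tau_R = 1 / (k12 + k21)` exactly, and the validation simulations for the
cross-correlation run at three-millisecond mean burst durations so the lag
range spans several relaxation times. A K-state chain relaxes with K-1
eigenmodes, so for three-state data the single-exponential fit lands
between the two eigen-times — the drivers print both for comparison.

## Thermokinetic post-processing

`stationary_distribution()` solves `pi Q = 0` by a dense linear solve and
is checked against the detailed-balance closed form for chains
(`pi1/pi2 = k21/k12`, `pi3/pi2 = k23/k32`) to 1e-12. The active/inactive
ratio is `pi1/pi2`, which for a chain equals `k21/k12` exactly.
`free_energy_profile()` applies the Arrhenius relation
`dG_ij = ln(A / k_ij)` in kBT with a default pre-exponential factor of
`1e5 s^-1` — a conservative choice for large-scale conformational motion;
every barrier shifts by `ln(factor)` if A is rescaled, and rates exceeding
A are flagged rather than silently producing negative barriers. State free
energies come from occupancy ratios. Units stay in kBT throughout.

`labeling_distribution()` evaluates the binomial statistics of assembling
hexamers from labeled and unlabeled protomers: at the working 1:100 mix,
the probability of exactly one labeled protomer is 5.7% (two significant
figures) and of two is 0.141%; the latter is the exact binomial value
`15 p^2 (1-p)^4`, which a commonly quoted 0.15% reproduces only if the
`(1-p)^4` factor is dropped. `fit_hill()` and `fit_binding_isotherm()` are
constrained Levenberg-Marquardt fits with starts taken from data quantiles
and the half-rise point; no real assay data ship with the package, so both
are exercised on synthetic curves at the reported parameter values
(ATPase: Vmax 3.2 min^-1, Hill coefficient 3.1; dose-response: ratio 1.00
to 1.85 with Kd = 3 uM).

## Rigid-body triangulation

The structural stage asks which rigid rotation of a mobile domain about its
anchor best explains a set of measured per-pair efficiencies.

* **Rotation grid.** Intrinsic z-y-z Euler angles on a uniform grid, 25
  points per axis by default (15,625 conformers), always containing the
  identity. The original scheme does not state its parameterization or
  ranges; here the defaults sweep the azimuth fully and tilt up to 135
  degrees — deliberately overshooting what sterics allow so the clash
  filter is doing real work — and all ranges are configurable. The z-y-z
  grid double-covers some orientations (the alpha/gamma aliasing at the
  tilt extremes and the 180-degree wrap); duplicates predict identical
  efficiencies and appear as exact ties in the ranking, resolved stably by
  conformer index.
* **Clash filter.** A conformer is rejected if any domain atom sits closer
  to any non-domain atom than the sum of their van der Waals radii minus a
  0.3 Angstrom threshold. A bounding-box prefilter keeps the scan
  tractable and is verified to agree with the all-pairs oracle on every
  grid conformer.
* **Dye clouds.** `accessible_volume()` is a geometric accessible-volume
  model: grid positions within the linker length of the attachment atom,
  excluding dye-sphere overlap with any atom, and requiring half a linker
  width of clearance at sampled points along the straight attachment path.
  That last check stands in for a full flexible-path search; convoluted
  tunnels that a real linker could not thread may be retained. Grid spacing
  auto-tunes to a target cloud size (600-1200 positions by default).
  Defaults — 20 Angstrom linker, 4.5 width, 3.5 dye radius — suit
  Alexa-class maleimide dyes and are all overridable. Orientation
  averaging (kappa-squared = 2/3) is assumed folded into each pair's
  Forster radius, which is a required input per pair.
* **Prediction and ranking.** The model efficiency of a pair is the exact
  mean of `1 / (1 + (r/R0)^6)` over all donor-acceptor position pairs;
  only beyond four million pairs does a seeded subsample replace the exact
  mean (standard error well below measurement uncertainty). Ranking
  minimizes the plain sum of squared efficiency residuals over pairs,
  computed once per measured-state vector, with stable (chi-square, index)
  ordering and a top-10 selection by default. RMSD to a reference is taken
  in the fixed body frame with no superposition — conformers share that
  frame by construction — and the tilt angle compares first principal axes,
  folded into [0, 90] degrees, flagging near-degenerate (spherical)
  domains.

The package ships no experimental hexamer model; the triangulation is
validated end-to-end on a generated toy complex (a packed-sphere body with
an anchored rod domain and three body-domain dye pairs), where a designated
true conformer's predictions, fed back as "measured" values, must return
that conformer at rank 1 with chi-square exactly zero. Published headline
numbers that depend on the authors' unpublished hexamer model and dye
parameters (specific RMSD and tilt values, the ~5% clash survival) are
expressly not reproduced.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at the sizes the analyses were
designed around: 3000 simulated transits (~600,000 photons) for the
wild-type recovery fit, 700-burst replicates across ten seeds for
recoloring, 1200 bursts for each two-state validation, a full 15,625-point
grid for the clash census and a 343-point grid (with 3 Angstrom cloud
spacing) for the toy triangulation. Likelihood comparisons against
exhaustive enumeration use bursts of at most seven photons, where the sum
over hidden paths is tractable. Ties in burst-edge assignment, ranking
order, and canonical state order are all resolved by the deterministic
rules above, so every pipeline stage is exactly reproducible from its
seeds.

## Known limitations

The generator's idealizations (no diffusion profile, no photophysics
beyond leakage and direct excitation) mean parameter-recovery results
bound algorithmic, not instrumental, error. Dwell-time means at standard
flux carry the resolution bias discussed above. The accessible-volume
model checks straight-path clearance only. Multi-protomer coordination,
lifetime information, and the biological identity of the minor low-E state
are out of scope.
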