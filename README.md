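# switchfret

Photon-level analysis of fast conformational switching measured by
diffusion-based single-molecule FRET, built around the M domain of the
bacterial disaggregase ClpB — a coiled-coil "toggle" that exchanges between
an active (tilted, high-FRET) and an inactive (parallel, mid-FRET)
conformation on the hundreds-of-microseconds timescale, far faster than the
machine's catalytic cycle.

The package is for single-molecule spectroscopists who want a tested,
end-to-end reference implementation of this analysis chain:

1. **Synthetic measurements** — photon streams of diffusing-molecule bursts
   under 3:1 pulsed interleaved excitation (40 MHz clock), with per-state
   FRET efficiencies, leakage, direct excitation, single-dye contaminants
   and background (`simulate_photon_stream()`).
2. **Burst processing** — sliding-window burst search (15-photon running
   average, 10 µs cutoff, ≥ 30 photons), raw `E`/`S`, leakage and
   direct-excitation corrections estimated from the single-dye populations,
   stoichiometry filtering, FRET histograms and their shot-noise reference
   (`detect_bursts()` and friends).
3. **Photon-by-photon kinetics** — maximum-likelihood inference of a
   K-state hidden continuous-time Markov model directly from photon colors
   and arrival times. Between photons the state propagates by `exp(Q Δt)`;
   each donor-excitation photon is acceptor-colored with its state's
   efficiency `E_i`. Fitting (`fit_h2mm()`) recovers `(E, Q)`, with model
   selection, Viterbi decoding, and the four validation analyses:
   stochastic recoloring, dwell times, segmentation, and donor–acceptor
   cross-correlation.
4. **Thermokinetics** — stationary occupancies (`πQ = 0`), active/inactive
   ratios (`π₁/π₂ = k₂₁/k₁₂` for a chain), Arrhenius free-energy profiles
   `ΔG‡ = ln(A/k)` in units of kBT (A = 10⁵ s⁻¹ by default), binomial
   labeling statistics for hexamers, and Hill / binding-isotherm fits.
5. **Triangulation** — FRET-restrained rigid-body placement of a mobile
   domain: a 25³ Euler rotation grid about the anchor, van der Waals clash
   filtering (`d < R_v(i) + R_v(j) − 0.3 Å`), accessible-volume dye clouds,
   cloud-averaged pair efficiencies `⟨1/(1 + (r/R₀)⁶)⟩`, and χ² ranking
   `χ²_E = Σᵢ (E_meas(i) − E_model(i))²` against measured state
   efficiencies.

The methods vignette (`vignettes/mdomain-switch-analysis.Rmd`) documents
the models, defaults, numerical conventions, and known limitations.

## Worked example

Simulate a wild-type-like measurement from the three-state sequential model
(E = 0.80/0.47/0.15; k₁₂ = 5300, k₂₁ = 5700, k₂₃ = 800, k₃₂ = 2300 s⁻¹),
detect bursts, and re-infer the model from the photon record:

```r
library(switchfret)

model <- wt_mdomain_model()
sim   <- simulate_photon_stream(sim_config(n_bursts = 3000, rng_seed = 11), model)
bursts <- compute_raw_es(detect_bursts(sim$stream))
bp    <- burst_photons(sim$stream, bursts)
fit   <- fit_h2mm(bp, K = 3, connectivity = "sequential", n_restarts = 3, seed = 1)
print(fit)
```

```
<h2mm_fit> K = 3, loglik = -246602.93 (400597 photons, 2621 bursts)
<kinetic_model> 3 state(s)
  E : 0.802  0.474  0.151 
  pi: 0.435  0.424  0.141 
  rates (s^-1):
        [,1]    [,2]    [,3]
[1,] -5507.7  5507.7     0.0
[2,]  5643.2 -6450.9   807.7
[3,]     0.0  2430.1 -2430.1
```

Every generating parameter is recovered: rates within a few percent,
efficiencies within ±0.005, and the state-1 occupancy (0.435) within 0.01
of the analytic stationary value. Downstream, `free_energy_profile(fit$model)`
converts the rates to barriers of ~3 kBT, and
`active_inactive_ratio(fit$model)` gives the π₁/π₂ ratio that dose-response
experiments modulate.

The numbered scripts under `analysis/` run the full workflow as a
narrative — simulation, burst processing, fitting and model selection, the
four validations, thermokinetics, and toy-complex triangulation — writing
small summary tables under `results/`.

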