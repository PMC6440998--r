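#!/usr/bin/env Rscript
# Burst processing: sliding-window burst search (15-photon running average,
# 10 us cutoff, >= 30 photons), raw E/S, leakage / direct-excitation
# estimation from the single-dye populations of an artifact-laden companion
# simulation, stoichiometry filtering, and the FRET histogram against its
# shot-noise reference.

suppressPackageStartupMessages(library(switchfret))
dir.create("results", showWarnings = FALSE)

model <- wt_mdomain_model()
sim <- simulate_photon_stream(sim_config(n_bursts = 3000, rng_seed = 2026), model)
bursts <- compute_raw_es(detect_bursts(sim$stream))
cat(sprintf("Detected %d bursts (>= 30 photons) from %d simulated transits.\n",
            nrow(bursts), 3000))

h <- fret_histogram(bursts$E_raw, n_bins = 40)
ref <- shot_noise_reference(bursts, mean(bursts$E_raw, na.rm = TRUE), seed = 1)
cat(sprintf("Burst E histogram sd %.3f vs shot-noise reference %.3f: dynamic broadening x%.2f.\n",
            sd(bursts$E_raw, na.rm = TRUE), sd(attr(ref, "E")),
            sd(bursts$E_raw, na.rm = TRUE) / sd(attr(ref, "E"))))
write.csv(data.frame(E_mid = h$mids, count = h$counts,
                     shot_noise_count = ref$counts),
          "results/02_fret_histogram.csv", row.names = FALSE)

# corrections demonstrated where the artifacts exist: 5% leakage, 3% direct
# excitation, 18% donor-only and 12% acceptor-only contaminants
cfg_art <- sim_config(n_bursts = 2000, leakage = 0.05, direct_excitation = 0.03,
                      donor_only_fraction = 0.18, acceptor_only_fraction = 0.12,
                      rng_seed = 2027)
sim_art <- simulate_photon_stream(cfg_art, model)
bt_art <- compute_raw_es(detect_bursts(sim_art$stream))
fac <- estimate_corrections(bt_art)
cat(sprintf("Estimated leakage %.3f (true 0.050), direct excitation %.3f (true 0.030).\n",
            fac$leakage, fac$direct_excitation))
filt <- apply_corrections_and_filter(bt_art, fac, s_window = c(0.3, 0.8))
cat(sprintf("Stoichiometry window [0.3, 0.8] keeps %d of %d bursts (removed %d single-dye).\n",
            nrow(filt), nrow(bt_art), attr(filt, "n_removed")))
write.csv(data.frame(quantity = c("leakage", "direct_excitation",
                                  "n_bursts", "n_after_s_filter"),
                     value = c(fac$leakage, fac$direct_excitation,
                               nrow(bt_art), nrow(filt))),
          "results/02_corrections.csv", row.names = FALSE)
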