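test_that("burst search finds dense photon runs and ignores sparse background", {
  clock <- 2.5e-8
  ms <- 1e-3 / clock
  # uniform background at 1 ms spacing: no bursts
  bg <- photon_stream((0:299) * ms, rep(0L, 300), rep(0L, 300))
  expect_equal(nrow(detect_bursts(bg)), 0)

  # 100 photons at 5 us spacing embedded in that background: exactly one burst
  us5 <- 5e-6 / clock
  dense_t <- 150 * ms + (0:99) * us5
  tt <- sort(c((0:299) * ms, dense_t))
  st <- photon_stream(tt, rep(0L, length(tt)), rep(0L, length(tt)))
  bt <- detect_bursts(st)
  expect_equal(nrow(bt), 1)
  # oracle: the dense run is precisely the photons with interphoton time < cutoff
  in_burst <- bt$start_idx:bt$end_idx
  expect_setequal(tt[in_burst], dense_t)

  expect_error(detect_bursts(st, cutoff = 0), "cutoff")
  expect_error(detect_bursts(st, window = 0), "window")
})

test_that("burst detection is invariant to time offset and stream concatenation", {
  cfg <- sim_config(n_bursts = 80, rng_seed = 21)
  sim <- simulate_photon_stream(cfg, wt_mdomain_model())
  st <- sim$stream
  b0 <- detect_bursts(st)

  shifted <- photon_stream(st$timestamp + 1e9, st$detector, st$excitation)
  b1 <- detect_bursts(shifted)
  expect_equal(b0[, -7], b1[, -7])  # identical indices and counts
  expect_equal(b0$duration, b1$duration)

  # concatenating a second stream far beyond the cutoff preserves both burst sets
  sim2 <- simulate_photon_stream(sim_config(n_bursts = 40, rng_seed = 22),
                                 wt_mdomain_model())
  off <- max(st$timestamp) + 1e9
  cat_st <- photon_stream(c(st$timestamp, sim2$stream$timestamp + off),
                          c(st$detector, sim2$stream$detector),
                          c(st$excitation, sim2$stream$excitation))
  bc <- detect_bursts(cat_st)
  b2 <- detect_bursts(sim2$stream)
  expect_equal(nrow(bc), nrow(b0) + nrow(b2))
  expect_equal(bc$start_idx, c(b0$start_idx, b2$start_idx + nrow(st)))
  expect_equal(bc$n_DA, c(b0$n_DA, b2$n_DA))
})

test_that("raw E and S follow the photon-count definitions, flagging degenerate bursts", {
  b <- data.frame(n_DD = c(50, 25, 0, 0), n_DA = c(0, 25, 0, 30),
                  n_AA = c(0, 50, 40, 10))
  r <- compute_raw_es(b)
  expect_equal(r$E_raw, c(0, 0.5, NA, 1))
  expect_equal(r$S_raw, c(1, 0.5, 0, 0.75))
  expect_equal(r$valid, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("leakage and direct excitation round-trip through estimate and apply", {
  cfg <- sim_config(n_bursts = 2000, leakage = 0.05, direct_excitation = 0.03,
                    donor_only_fraction = 0.18, acceptor_only_fraction = 0.18,
                    rng_seed = 31)
  sim <- simulate_photon_stream(cfg, kinetic_model(0.8, matrix(0, 1, 1)))
  bt <- compute_raw_es(detect_bursts(sim$stream))
  fac <- estimate_corrections(bt)
  expect_lt(abs(fac$leakage - 0.05), 0.01)
  expect_lt(abs(fac$direct_excitation - 0.03), 0.01)

  # corrected E of the double-labeled population recovers the true efficiency
  corr <- apply_corrections_and_filter(bt, fac, s_window = c(0.3, 0.85))
  expect_equal(mean(corr$E_corr), 0.80, tolerance = 0.01)

  # idempotence: residual leakage / direct excitation of corrected single-dye
  # populations is ~0
  all_corr <- apply_corrections_and_filter(bt, fac, s_window = c(0, 1))
  don <- all_corr$S_corr > 0.9
  acc <- all_corr$S_corr < 0.2
  resid_leak <- mean(all_corr$E_corr[don])
  s_acc <- mean(all_corr$S_corr[acc])
  resid_direct <- s_acc / (1 - s_acc) / 3   # back to the per-event factor scale
  expect_lt(abs(resid_leak), 0.01)
  expect_lt(abs(resid_direct), 0.01)

  # zero-artifact control estimates ~0
  cfg0 <- sim_config(n_bursts = 800, donor_only_fraction = 0.2,
                     acceptor_only_fraction = 0.2, rng_seed = 32)
  bt0 <- compute_raw_es(detect_bursts(simulate_photon_stream(
    cfg0, kinetic_model(0.8, matrix(0, 1, 1)))$stream))
  fac0 <- estimate_corrections(bt0)
  expect_lt(abs(fac0$leakage), 0.01)
  expect_lt(abs(fac0$direct_excitation), 0.01)

  expect_error(estimate_corrections(bt[bt$S_raw < 0.85, ]), "donor-only")
})

test_that("stoichiometry filtering removes single-dye species with high purity", {
  cfg <- sim_config(n_bursts = 1200, donor_only_fraction = 0.3,
                    rng_seed = 33)
  sim <- simulate_photon_stream(cfg, kinetic_model(0.5, matrix(0, 1, 1)))
  bt <- compute_raw_es(detect_bursts(sim$stream))
  species <- detected_species(bt, sim)
  fac <- list(leakage = 0, direct_excitation = 0)

  all_kept <- apply_corrections_and_filter(bt, fac, s_window = c(0, 1))
  expect_equal(nrow(all_kept), nrow(bt))

  filt <- apply_corrections_and_filter(bt, fac, s_window = c(0.3, 0.8))
  kept <- species[match(filt$start_idx, bt$start_idx)]
  expect_gte(mean(kept == "double", na.rm = TRUE), 0.99)
  expect_lt(nrow(filt), nrow(bt))
})

test_that("histograms conserve counts and expose population structure", {
  E <- c(rep(0.42, 7), 0.61)
  h <- fret_histogram(E, n_bins = 20)
  expect_equal(sum(h$counts), h$n_bursts)
  expect_equal(h$n_bursts, 8)
  expect_equal(sum(h$counts > 0), 2)

  # all-identical efficiencies occupy a single bin
  h1 <- fret_histogram(rep(0.5, 50), n_bins = 25)
  expect_equal(sum(h1$counts > 0), 1)

  # WT-like dynamics: bimodal, major peak between the two high-E states
  cfg <- sim_config(n_bursts = 1500, rng_seed = 41)
  sim <- simulate_photon_stream(cfg, wt_mdomain_model())
  bt <- compute_raw_es(detect_bursts(sim$stream))
  h2 <- fret_histogram(bt$E_raw, n_bins = 30)
  pk <- histogram_peaks(h2, n_peaks = 2)
  major <- pk$position[1]
  expect_gt(major, 0.47)
  expect_lt(major, 0.8)
  # minor low-E population carries visible mass near state 3
  expect_gt(mean(bt$E_raw < 0.3, na.rm = TRUE), 0.03)
})

test_that("shot-noise reference matches the binomial width and flags dynamic broadening", {
  # static molecule: measured width within 10% of the shot-noise reference
  cfg <- sim_config(n_bursts = 1000, background_rate_donor = 0,
                    background_rate_acceptor = 0, rng_seed = 42)
  sim <- simulate_photon_stream(cfg, kinetic_model(0.5, matrix(0, 1, 1)))
  bt <- compute_raw_es(detect_bursts(sim$stream))
  ref <- shot_noise_reference(bt, 0.5, seed = 7)
  expect_equal(sd(bt$E_raw) / sd(attr(ref, "E")), 1, tolerance = 0.1)
  # reference variance ~ E(1-E)/N
  N <- bt$n_DD + bt$n_DA
  expect_equal(var(attr(ref, "E")), mean(0.25 / N), tolerance = 0.12)

  # switching dynamics broaden the measured histogram beyond shot noise
  simw <- simulate_photon_stream(sim_config(n_bursts = 1000, rng_seed = 43),
                                 wt_mdomain_model())
  btw <- compute_raw_es(detect_bursts(simw$stream))
  refw <- shot_noise_reference(btw, mean(btw$E_raw), seed = 7)
  expect_gt(var(btw$E_raw), 1.5 * var(attr(refw, "E")))
})
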