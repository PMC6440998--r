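test_that("forward likelihood equals brute-force path enumeration (K <= 3, <= 7 photons)", {
  set.seed(101)
  models <- list(
    kinetic_model(0.5, matrix(0, 1, 1)),
    two_state_model(),
    wt_mdomain_model(),
    kinetic_model(c(0.9, 0.5, 0.1),
                  rate_matrix_chain(1:3, c(1.2e4, 300), c(900, 7.7e3)))
  )
  for (m in models) {
    for (rep in 1:5) {
      n <- sample(2:7, 1)
      bp <- make_bp(colors = rbinom(n, 1, 0.5),
                    dt = c(NA, sample(c(10, 200, 3000, 4e4), n - 1, replace = TRUE)))
      ll <- photon_likelihood(m, bp)
      expect_equal(ll, brute_force_loglik(m, bp), tolerance = 1e-10)
    }
  }

  # multiple bursts: likelihoods add
  bp2 <- make_bp(colors = c(1, 0, 1, 0, 0, 1), dt = c(NA, 50, 900, NA, 40, 40),
                 burst = c(1, 1, 1, 2, 2, 2))
  expect_equal(photon_likelihood(models[[3]], bp2),
               brute_force_loglik(models[[3]], bp2), tolerance = 1e-10)
})

test_that("likelihood is closed-form for one state and invariant to state relabeling", {
  bp <- make_bp(colors = c(1, 0, 1, 1), dt = c(NA, 100, 100, 100))
  m1 <- kinetic_model(0.5, matrix(0, 1, 1))
  expect_equal(photon_likelihood(m1, bp), 4 * log(0.5))

  m <- wt_mdomain_model()
  perm <- c(3, 1, 2)
  mp <- kinetic_model(m$E[perm], m$Q[perm, perm])
  expect_equal(photon_likelihood(m, bp), photon_likelihood(mp, bp),
               tolerance = 1e-12)
})

test_that("fitting one-state data gives the acceptor fraction exactly", {
  set.seed(7)
  colors <- rbinom(400, 1, 0.37)
  bp <- make_bp(colors, dt = c(NA, rep(150, 399)))
  f <- fit_h2mm(bp, 1)
  expect_equal(f$model$E, mean(colors))
  expect_true(f$converged)
})

test_that("two-state parameters are recovered from a modest simulation", {
  m <- two_state_model(E = c(0.8, 0.2), k12 = 4000, k21 = 6000)
  cfg <- sim_config(n_bursts = 400, rng_seed = 55)
  sim <- simulate_photon_stream(cfg, m)
  bp <- burst_photons_from_truth(sim)
  f <- fit_h2mm(bp, 2, n_restarts = 2, seed = 1)
  expect_equal(f$model$E, c(0.8, 0.2), tolerance = 0.03)
  expect_equal(f$model$Q[1, 2] / 4000, 1, tolerance = 0.2)
  expect_equal(f$model$Q[2, 1] / 6000, 1, tolerance = 0.2)
  # ascent trace is monotone non-decreasing
  expect_true(all(diff(f$loglik_trace) >= 0))
  # canonical order: descending E
  expect_true(all(diff(f$model$E) < 0))
})

test_that("state-number selection prefers the generating model", {
  # one-state data: K = 1 recommended
  cfg <- sim_config(n_bursts = 150, rng_seed = 61)
  sim <- simulate_photon_stream(cfg, kinetic_model(0.45, matrix(0, 1, 1)))
  bp <- burst_photons_from_truth(sim)
  sel <- select_state_number(bp, K_range = 1:2, n_restarts = 1, seed = 1)
  expect_equal(sel$recommended_K, 1)
  # the parsimony criterion cannot prefer an overfitted K
  expect_lte(sel$table$bic[1], sel$table$bic[2] + 1e-6)
})

test_that("Viterbi paths track well-separated states and respect bounds", {
  # K = 1: everything in state 1
  bp1 <- make_bp(colors = rbinom(30, 1, 0.5), dt = c(NA, rep(100, 29)))
  m1 <- kinetic_model(0.5, matrix(0, 1, 1))
  expect_true(all(viterbi_paths(m1, bp1) == 1L))

  # near-noiseless colors, slow exchange: path matches ground truth >= 99%
  m <- two_state_model(E = c(0.99, 0.01), k12 = 300, k21 = 300)
  sim <- simulate_photon_stream(sim_config(n_bursts = 120, rng_seed = 62), m)
  bp <- burst_photons_from_truth(sim)
  path <- viterbi_paths(m, bp)
  expect_gte(mean(path == bp$truth_state), 0.99)

  # the single best path cannot be more likely than the summed likelihood
  bp3 <- make_bp(colors = c(1, 0, 1, 0, 1), dt = c(NA, 80, 80, 80, 80))
  mm <- wt_mdomain_model()
  path3 <- viterbi_paths(mm, bp3)
  logp_path <- {
    P <- ctmc_propagators(mm$Q, rep(80 * bp3$clock_period, 4))
    em <- ifelse(bp3$color == 1, mm$E[path3], 1 - mm$E[path3])
    lp <- log(mm$pi[path3[1]]) + sum(log(em))
    for (t in 2:5) lp <- lp + log(P[path3[t - 1], path3[t], t - 1])
    lp
  }
  expect_lte(logp_path, photon_likelihood(mm, bp3) + 1e-12)
})

test_that("recoloring a one-state model reproduces the binomial reference law", {
  m1 <- kinetic_model(0.6, matrix(0, 1, 1))
  sim <- simulate_photon_stream(sim_config(n_bursts = 400, rng_seed = 63), m1)
  bt <- compute_raw_es(detect_bursts(sim$stream))
  bp <- burst_photons(sim$stream, bt)
  rc <- recolor(m1, bp, seed = 3, n_rep = 4)
  sizes <- tabulate(bp$burst)
  expect_equal(mean(rc), 0.6, tolerance = 0.01)
  expect_equal(var(as.vector(rc[, 1])), mean(0.6 * 0.4 / sizes), tolerance = 0.15)

  # the generating model passes its own recoloring check
  chk <- recoloring_check(m1, bp, seed = 5)
  expect_true(chk$pass)
})

test_that("dwell times and segment efficiencies are internally consistent", {
  m <- two_state_model(E = c(0.95, 0.05), k12 = 800, k21 = 800)
  sim <- simulate_photon_stream(sim_config(n_bursts = 250, rng_seed = 64), m)
  bp <- burst_photons_from_truth(sim)
  path <- viterbi_paths(m, bp)
  dw <- dwell_time_analysis(path, bp)
  expect_equal(dw$state1$exit_rate, 800, tolerance = 0.15)
  expect_equal(dw$state1$exit_rate,
               sum(m$Q[1, -1]), tolerance = 0.15 * sum(m$Q[1, -1]))

  seg <- segmentation_histogram(path, bp, min_photons = 15)
  pk <- histogram_peaks(seg, n_peaks = 2)
  expect_equal(sort(pk$position), c(0.05, 0.95), tolerance = 0.08)

  # one-state data: every dwell is censored by the burst window
  sim1 <- simulate_photon_stream(sim_config(n_bursts = 40, rng_seed = 65),
                                 kinetic_model(0.5, matrix(0, 1, 1)))
  bp1 <- burst_photons_from_truth(sim1)
  p1 <- viterbi_paths(kinetic_model(0.5, matrix(0, 1, 1)), bp1)
  expect_message(dw1 <- dwell_time_analysis(p1, bp1), "skipped")
  expect_true(all(dw1$state1$censored))
})

test_that("cross-correlation is flat without dynamics", {
  m1 <- kinetic_model(0.5, matrix(0, 1, 1))
  sim <- simulate_photon_stream(sim_config(n_bursts = 500, rng_seed = 66), m1)
  bp <- burst_photons_from_truth(sim)
  cc <- donor_acceptor_crosscorrelation(bp, max_lag = 4e-4)
  expect_lt(max(abs(cc$G - 1)), 0.05)
})

test_that("bootstrap returns finite uncertainties of plausible scale", {
  m <- two_state_model(E = c(0.8, 0.2), k12 = 4000, k21 = 6000)
  sim <- simulate_photon_stream(sim_config(n_bursts = 150, rng_seed = 67), m)
  bp <- burst_photons_from_truth(sim)
  f <- fit_h2mm(bp, 2, n_restarts = 1, seed = 1)
  bs <- h2mm_bootstrap(f, bp, n_boot = 5, seed = 2)
  expect_true(all(is.finite(bs$E_se)))
  expect_lt(max(bs$E_se), 0.05)
  expect_true(all(is.finite(bs$rate_se[f$model$connectivity])))
})
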