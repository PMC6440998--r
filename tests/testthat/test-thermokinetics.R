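test_that("binomial labeling statistics match the closed form", {
  mix <- labeling_distribution(n = 6, labeled_conc = 1, unlabeled_conc = 100)
  p <- 1 / 101
  expect_equal(sum(mix$P), 1, tolerance = 1e-12)
  expect_equal(mix$P_one, 6 * p * (1 - p)^5, tolerance = 1e-12)
  # one labeled protomer per hexamer: 5.7% at the working 1:100 mix
  expect_equal(signif(100 * mix$P_one, 2), 5.7)
  # two labeled protomers: the exact binomial value (0.141%, i.e. 15 p^2 (1-p)^4)
  expect_equal(unname(mix$P["k2"]), 15 * p^2 * (1 - p)^4, tolerance = 1e-12)
  expect_equal(unname(100 * mix$P["k2"]), 0.1414, tolerance = 1e-3)

  expect_equal(labeling_distribution(6, 0, 1)$P[["k0"]], 1)
  # mode at round(np) in the unimodal regime
  mix2 <- labeling_distribution(6, 1, 1)
  expect_equal(unname(which.max(mix2$P)) - 1L, 3L)
  expect_error(labeling_distribution(6, 0, 0))
})

test_that("active/inactive ratio follows the balance equations", {
  m_eq <- two_state_model(k12 = 1000, k21 = 1000)
  expect_equal(active_inactive_ratio(m_eq)$ratio, 1)

  m <- wt_mdomain_model()
  expect_equal(active_inactive_ratio(m)$ratio, 5700 / 5300, tolerance = 1e-12)

  # ATP-binding-deficient-like rates give the elevated ratio
  m2 <- kinetic_model(c(0.8, 0.47, 0.15),
                      rate_matrix_chain(1:3, c(3500, 800), c(5800, 2300)))
  expect_equal(active_inactive_ratio(m2)$ratio, 5800 / 3500, tolerance = 1e-12)
  expect_equal(active_inactive_ratio(m2)$ratio, 1.66, tolerance = 0.01)
})

test_that("free-energy profiles invert the Arrhenius relation exactly", {
  m <- wt_mdomain_model()
  prof <- free_energy_profile(m, A = 1e5)
  expect_equal(prof$barrier_G[1, 2], log(1e5 / 5300), tolerance = 1e-12)
  expect_equal(prof$barrier_G[1, 2], 2.94, tolerance = 0.01)  # ~3 kBT
  # state free energies from occupancy ratios
  expect_equal(prof$state_G[2] - prof$state_G[1], log(m$pi[1] / m$pi[2]),
               tolerance = 1e-12)
  # k = A gives a zero barrier; doubling A raises every barrier by ln 2
  m0 <- two_state_model(k12 = 1e5, k21 = 1e3)
  expect_equal(free_energy_profile(m0, A = 1e5)$barrier_G[1, 2], 0)
  p1 <- free_energy_profile(m, A = 1e5)$barrier_G
  p2 <- free_energy_profile(m, A = 2e5)$barrier_G
  expect_equal(p2 - p1, matrix(ifelse(is.na(p1), NA, log(2)), 3, 3))

  # round trip rates -> profile -> rates
  expect_equal(rates_from_profile(prof), m$Q, tolerance = 1e-12)

  # rates above the pre-exponential are flagged
  expect_warning(free_energy_profile(two_state_model(k12 = 2e5, k21 = 10), A = 1e5),
                 "negative barrier")
})

test_that("Hill fits recover generator parameters within 2 sigma under noise", {
  d0 <- simulate_kinetic_curves("hill", list(Vmax = 3.2, K05 = 0.6, n = 3.1),
                                noise_sd = 0, n_points = 14, seed = 2)
  f0 <- fit_hill(d0$x, d0$y)
  expect_equal(c(f0$Vmax, f0$K05, f0$n), c(3.2, 0.6, 3.1), tolerance = 1e-6)

  d <- simulate_kinetic_curves("hill", list(Vmax = 3.2, K05 = 0.6, n = 3.1),
                               noise_sd = 0.16, n_points = 14, seed = 3)
  f <- fit_hill(d$x, d$y)
  expect_lt(abs(f$Vmax - 3.2), 2 * f$se[["Vmax"]])
  expect_lt(abs(f$n - 3.1), 2 * f$se[["n"]])

  # fixing n = 1 reduces to the hyperbolic fit
  dh <- simulate_kinetic_curves("hill", list(Vmax = 2, K05 = 1, n = 1),
                                noise_sd = 0.05, seed = 4)
  f1 <- fit_hill(dh$x, dh$y, fix_n = 1)
  fr <- minpack.lm::nlsLM(y ~ Vmax * x / (x + K05), data = dh,
                          start = list(Vmax = 2, K05 = 1))
  expect_equal(sum(resid(f1$fit)^2), sum(resid(fr)^2), tolerance = 1e-8)
})

test_that("binding isotherm fit recovers the dissociation constant", {
  # dose-response of the active/inactive ratio: 1.00 -> 1.85, Kd = 3 uM
  d0 <- simulate_kinetic_curves("isotherm",
                                list(r0 = 1.0, amplitude = 0.95, Kd = 3),
                                noise_sd = 0, n_points = 12, seed = 5,
                                x_max = 25)
  f0 <- fit_binding_isotherm(d0$x, d0$y)
  expect_equal(c(f0$r0, f0$amplitude, f0$Kd), c(1.0, 0.95, 3), tolerance = 1e-6)

  d <- simulate_kinetic_curves("isotherm",
                               list(r0 = 1.0, amplitude = 0.95, Kd = 3),
                               noise_sd = 0.05, n_points = 12, seed = 6,
                               x_max = 25)
  f <- fit_binding_isotherm(d$x, d$y)
  expect_lt(abs(f$Kd - 3), 2 * f$se[["Kd"]])
  # half-amplitude point sits at c = Kd
  pred <- f$r0 + f$amplitude * f$Kd / (f$Kd + f$Kd)
  expect_equal(pred, f$r0 + f$amplitude / 2, tolerance = 1e-12)
})
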