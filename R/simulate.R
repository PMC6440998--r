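#' Simulation configuration for diffusing-molecule photon streams
#'
#' Collects the experiment-level parameters of the photon-level generative
#' model: burst arrival statistics, in-burst brightness, pulsed-interleaved
#' excitation (PIE) ratio, detection artifacts and contaminant species. The
#' defaults emulate the acquisition regime of the M-domain measurements:
#' roughly millisecond bursts at around 190,000 detected photons per second,
#' a 3:1 donor:acceptor PIE pulse ratio and a 40 MHz laser clock.
#'
#' @param n_bursts Number of molecule transits to simulate.
#' @param burst_duration_mean Mean burst duration (s); durations are
#'   exponential (rectangular burst envelope).
#' @param in_burst_photon_rate Total detected photon rate during a burst
#'   (photons/s, both channels and excitation slots combined).
#' @param background_rate_donor,background_rate_acceptor Background count
#'   rates (photons/s) in each detection channel, filling inter-burst gaps.
#' @param pie_ratio Integer pair, donor:acceptor excitation pulse ratio.
#' @param laser_rep_rate Laser repetition rate, Hz; one clock tick per pulse.
#' @param leakage Probability that an emitted donor photon is registered in
#'   the acceptor channel.
#' @param direct_excitation Probability that a donor-slot detection event is a
#'   directly excited acceptor photon.
#' @param donor_only_fraction,acceptor_only_fraction Fractions of molecules
#'   carrying only one dye.
#' @param inter_burst_gap_mean Mean gap between consecutive bursts (s).
#' @param rng_seed Integer seed; the simulation consumes a single RNG stream
#'   seeded from this value.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_bursts = 3000,
                       burst_duration_mean = 1e-3,
                       in_burst_photon_rate = 1.9e5,
                       background_rate_donor = 1500,
                       background_rate_acceptor = 800,
                       pie_ratio = c(3L, 1L),
                       laser_rep_rate = 4e7,
                       leakage = 0,
                       direct_excitation = 0,
                       donor_only_fraction = 0,
                       acceptor_only_fraction = 0,
                       inter_burst_gap_mean = 5e-3,
                       rng_seed = 1L) {
  cfg <- list(n_bursts = as.integer(n_bursts),
              burst_duration_mean = burst_duration_mean,
              in_burst_photon_rate = in_burst_photon_rate,
              background_rate_donor = background_rate_donor,
              background_rate_acceptor = background_rate_acceptor,
              pie_ratio = as.integer(pie_ratio),
              laser_rep_rate = laser_rep_rate,
              leakage = leakage,
              direct_excitation = direct_excitation,
              donor_only_fraction = donor_only_fraction,
              acceptor_only_fraction = acceptor_only_fraction,
              inter_burst_gap_mean = inter_burst_gap_mean,
              rng_seed = as.integer(rng_seed))
  rates <- c(cfg$in_burst_photon_rate, cfg$background_rate_donor,
             cfg$background_rate_acceptor, cfg$laser_rep_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  fr <- c(cfg$leakage, cfg$direct_excitation, cfg$donor_only_fraction,
          cfg$acceptor_only_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$donor_only_fraction + cfg$acceptor_only_fraction > 1) {
    stop("contaminant fractions must sum to at most 1")
  }
  if (length(cfg$pie_ratio) != 2 || any(cfg$pie_ratio < 1)) {
    stop("pie_ratio must be two positive integers (donor:acceptor)")
  }
  if (cfg$n_bursts < 1 || cfg$burst_duration_mean <= 0 ||
      cfg$inter_burst_gap_mean <= 0) {
    stop("n_bursts, burst_duration_mean and inter_burst_gap_mean must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Exact stochastic simulation of a continuous-time Markov state path
#'
#' Gillespie simulation of the conformational state trajectory: the dwell in
#' state i is exponential with that state's total exit rate, and the jump
#' target is drawn in proportion to the outgoing rates.
#'
#' @param model A [kinetic_model()].
#' @param duration Trajectory length (s).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   consumed (the convention used inside [simulate_photon_stream()]).
#' @param initial_state Optional starting state; default draws from the
#'   stationary distribution.
#' @return A data frame with columns `state`, `t0`, `t1` (piecewise-constant
#'   dwell intervals covering `[0, duration]`).
#' @export
simulate_state_path <- function(model, duration, seed = NULL,
                                initial_state = NULL) {
  stopifnot(inherits(model, "kinetic_model"), duration > 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_state_path(model, duration, initial_state = initial_state)))
  }
  K <- model$K
  exit <- -diag(model$Q)
  s <- if (is.null(initial_state)) {
    if (K == 1) 1L else sample.int(K, 1, prob = model$pi)
  } else as.integer(initial_state)
  states <- integer(0); t0 <- numeric(0)
  t <- 0
  while (t < duration) {
    states <- c(states, s)
    t0 <- c(t0, t)
    if (exit[s] <= 0) break   # absorbing (or single) state: dwell to the end
    t <- t + rexp(1, exit[s])
    if (t >= duration) break
    rates <- model$Q[s, ]
    rates[s] <- 0
    s <- sample.int(K, 1, prob = rates)
  }
  data.frame(state = states, t0 = t0, t1 = c(t0[-1], duration))
}

#' Simulate a photon stream of diffusing-molecule bursts
#'
#' Generates a full time-tagged photon record under the package's generative
#' model: bursts with exponential durations and inter-burst gaps; during each
#' burst, detection events arrive as a Poisson process at the configured
#' in-burst rate and are assigned to PIE excitation slots at the pulse-ratio
#' probability. For a double-labeled molecule a donor-slot event is, with
#' probability `direct_excitation`, a directly excited acceptor photon;
#' otherwise it reports FRET: acceptor-emitted with probability `E` of the
#' conformational state at that instant, else donor-emitted and re-classified
#' into the acceptor channel with probability `leakage`. Acceptor-slot events
#' report the acceptor dye directly (used downstream for stoichiometry).
#' Single-dye contaminants follow an equal-brightness convention — every
#' species transit emits at the full in-burst rate through the photon classes
#' available to it, so all species clear the burst-detection threshold:
#' donor-only molecules emit only donor-slot photons (subject to leakage);
#' acceptor-only molecules emit acceptor-slot photons plus direct-excitation
#' donor-slot events. Background photons fill the inter-burst gaps.
#'
#' Draws consume a single RNG stream seeded from `config$rng_seed`, in burst
#' order (species, duration, state path, photon times, slots, colors), then
#' background.
#'
#' @param config A [sim_config()].
#' @param model A [kinetic_model()] for the double-labeled species.
#' @return A list with `stream` (a [photon_stream()]) and `truth`: per-photon
#'   `burst_id` (NA for background) and true `state` (NA for background and
#'   contaminants), a per-burst table (`burst_id`, `species`, `t_start`,
#'   `duration`), and the generating `model`.
#' @export
simulate_photon_stream <- function(config, model) {
  stopifnot(inherits(config, "sim_config"), inherits(model, "kinetic_model"))
  withr::with_seed(config$rng_seed, {
    tick <- 1 / config$laser_rep_rate
    p_donor_slot <- config$pie_ratio[1] / sum(config$pie_ratio)
    total_span_guess <- config$n_bursts *
      (config$burst_duration_mean + config$inter_burst_gap_mean) * 3
    if (total_span_guess / tick > 2^52) {
      stop("simulation span overflows the integer clock representation")
    }

    gaps <- rexp(config$n_bursts, 1 / config$inter_burst_gap_mean)
    durs <- rexp(config$n_bursts, 1 / config$burst_duration_mean)
    t_start <- cumsum(gaps) + cumsum(c(0, head(durs, -1)))
    species <- sample(c("double", "donor_only", "acceptor_only"),
                      config$n_bursts, replace = TRUE,
                      prob = c(1 - config$donor_only_fraction - config$acceptor_only_fraction,
                               config$donor_only_fraction,
                               config$acceptor_only_fraction))

    res <- vector("list", config$n_bursts)
    for (b in seq_len(config$n_bursts)) {
      dur <- durs[b]
      sp <- species[b]
      if (sp == "double") {
        n <- rpois(1, config$in_burst_photon_rate * dur)
        if (n == 0) next
        tt <- sort(runif(n, 0, dur))
        path <- simulate_state_path(model, dur)
        st <- path$state[findInterval(tt, path$t0)]
        slot <- ifelse(runif(n) < p_donor_slot, 0L, 1L)
        det <- integer(n)
        dslot <- slot == 0L
        nd <- sum(dslot)
        if (nd) {
          is_direct <- runif(nd) < config$direct_excitation
          fret_acc <- runif(nd) < model$E[st[dslot]]
          leaked <- runif(nd) < config$leakage
          det[dslot] <- as.integer(is_direct | fret_acc | (!fret_acc & leaked))
        }
        det[!dslot] <- 1L  # acceptor-slot detections are acceptor photons
        res[[b]] <- data.frame(t = t_start[b] + tt, detector = det,
                               excitation = slot, burst_id = b,
                               state = st)
      } else if (sp == "donor_only") {
        # equal-brightness convention: every species transit emits at the
        # full in-burst rate through its available photon classes
        n <- rpois(1, config$in_burst_photon_rate * dur)
        if (n == 0) next
        tt <- sort(runif(n, 0, dur))
        det <- as.integer(runif(n) < config$leakage)
        res[[b]] <- data.frame(t = t_start[b] + tt, detector = det,
                               excitation = 0L, burst_id = b,
                               state = NA_integer_)
      } else {
        n_aa <- rpois(1, config$in_burst_photon_rate * dur)
        n_de <- rpois(1, config$in_burst_photon_rate *
                        (p_donor_slot / (1 - p_donor_slot)) *
                        config$direct_excitation * dur)
        n <- n_aa + n_de
        if (n == 0) next
        tt <- sort(runif(n, 0, dur))
        slot <- sample(c(rep(1L, n_aa), rep(0L, n_de)))
        res[[b]] <- data.frame(t = t_start[b] + tt, detector = 1L,
                               excitation = slot, burst_id = b,
                               state = NA_integer_)
      }
    }
    ph <- do.call(rbind, res)

    # background photons over the inter-burst gaps
    t_end_all <- t_start[config$n_bursts] + durs[config$n_bursts]
    gap_lo <- c(0, t_start + durs)[seq_len(config$n_bursts)]
    gap_hi <- t_start
    gap_len <- pmax(gap_hi - gap_lo, 0)
    bg <- lapply(c(donor = 0L, acceptor = 1L), function(chan) {
      rate <- if (chan == 0L) config$background_rate_donor else config$background_rate_acceptor
      if (rate <= 0) return(NULL)
      n_g <- rpois(length(gap_len), rate * gap_len)
      if (sum(n_g) == 0) return(NULL)
      tt <- unlist(lapply(which(n_g > 0), function(g) {
        runif(n_g[g], gap_lo[g], gap_hi[g])
      }))
      data.frame(t = tt, detector = chan,
                 excitation = as.integer(runif(length(tt)) >= p_donor_slot),
                 burst_id = NA_integer_, state = NA_integer_)
    })
    ph <- rbind(ph, do.call(rbind, bg))
    ph <- ph[order(ph$t), , drop = FALSE]

    stream <- photon_stream(round(ph$t / tick), ph$detector, ph$excitation,
                            clock_period = tick)
    list(stream = stream,
         truth = list(burst_id = ph$burst_id,
                      state = ph$state,
                      bursts = data.frame(burst_id = seq_len(config$n_bursts),
                                          species = species,
                                          t_start = t_start,
                                          duration = durs),
                      model = model,
                      span = t_end_all))
  })
}

#' Simulate small kinetic titration curves
#'
#' Generates (x, y) tables from either the Hill equation
#' `v = Vmax x^n / (x^n + K05^n)` or a one-site binding isotherm
#' `y = r0 + amplitude * x / (x + Kd)`, with additive Gaussian noise. Used to
#' exercise the closed-form fitting routines.
#'
#' @param kind `"hill"` or `"isotherm"`.
#' @param params Named list. Hill: `Vmax`, `K05`, `n`. Isotherm: `r0`,
#'   `amplitude`, `Kd`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param n_points Number of x points.
#' @param seed Integer seed.
#' @param x_max Upper end of the x range; defaults to several times the
#'   half-saturation constant so the curve brackets it.
#' @return Data frame with columns `x`, `y`.
#' @export
simulate_kinetic_curves <- function(kind = c("hill", "isotherm"), params,
                                    noise_sd = 0, n_points = 12, seed = 1,
                                    x_max = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(unlist(params) > 0) || kind == "isotherm")
  need <- if (kind == "hill") c("Vmax", "K05", "n") else c("r0", "amplitude", "Kd")
  if (!all(need %in% names(params))) {
    stop("params must contain: ", paste(need, collapse = ", "))
  }
  if (n_points < length(need)) stop("n_points must be at least the number of free parameters")
  withr::with_seed(seed, {
    half <- if (kind == "hill") params$K05 else params$Kd
    if (is.null(x_max)) x_max <- 8 * half
    x <- seq(0, x_max, length.out = n_points)
    y <- if (kind == "hill") {
      params$Vmax * x^params$n / (x^params$n + params$K05^params$n)
    } else {
      params$r0 + params$amplitude * x / (x + params$Kd)
    }
    data.frame(x = x, y = y + rnorm(n_points, 0, noise_sd))
  })
}
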