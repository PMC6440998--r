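# hand-built photon-burst objects and independent likelihood oracles

make_bp <- function(colors, dt, burst = rep(1L, length(colors)),
                    clock = 2.5e-8) {
  dt[c(1, which(diff(burst) != 0) + 1)] <- NA
  t <- ave(ifelse(is.na(dt), 0, dt), burst, FUN = cumsum)
  structure(list(color = as.integer(colors), dt = dt, t = t,
                 burst = as.integer(burst), clock_period = clock,
                 n_bursts = length(unique(burst))),
            class = "photon_bursts")
}

# exhaustive hidden-path enumeration; propagators via Matrix::expm,
# independent of the package's eigendecomposition route
brute_force_loglik <- function(model, bp) {
  total <- 0
  for (b in unique(bp$burst)) {
    idx <- which(bp$burst == b)
    colors <- bp$color[idx]
    dts <- bp$dt[idx][-1] * bp$clock_period
    K <- model$K
    P <- lapply(dts, function(d) as.matrix(Matrix::expm(model$Q * d)))
    emis <- function(s, c) if (c == 1) model$E[s] else 1 - model$E[s]
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), length(colors))))
    tot <- 0
    for (r in seq_len(nrow(paths))) {
      s <- paths[r, ]
      p <- model$pi[s[1]] * emis(s[1], colors[1])
      for (t in seq_along(colors)[-1]) {
        p <- p * P[[t - 1]][s[t - 1], s[t]] * emis(s[t], colors[t])
      }
      tot <- tot + p
    }
    total <- total + log(tot)
  }
  total
}

# two-state toy kinetic models used across files
two_state_model <- function(E = c(0.8, 0.2), k12 = 5300, k21 = 5700) {
  kinetic_model(E, rate_matrix_chain(E, k12, k21))
}

# map detected bursts back to the simulator's ground-truth burst labels
# (majority label over the photons inside the detected range)
detected_species <- function(bursts, sim) {
  vapply(seq_len(nrow(bursts)), function(i) {
    ids <- sim$truth$burst_id[bursts$start_idx[i]:bursts$end_idx[i]]
    ids <- ids[!is.na(ids)]
    if (!length(ids)) return(NA_character_)
    top <- as.integer(names(which.max(table(ids))))
    sim$truth$bursts$species[top]
  }, character(1))
}
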