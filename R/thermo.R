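#' Active/inactive state occupancy ratio
#'
#' The ratio of the stationary occupancies of the two major states, with the
#' model in canonical (descending-E) order: state 1 is the high-E active
#' conformation, state 2 the inactive one. For a sequential chain this equals
#' `k21 / k12` exactly.
#'
#' @param model A [kinetic_model()] with at least 2 states.
#' @param pi_se Optional per-state occupancy standard errors (e.g. from
#'   [h2mm_bootstrap()]) for uncertainty propagation.
#' @return List: `ratio`, `se` (NA without `pi_se`).
#' @export
active_inactive_ratio <- function(model, pi_se = NULL) {
  stopifnot(model$K >= 2)
  r <- model$pi[1] / model$pi[2]
  se <- NA_real_
  if (!is.null(pi_se)) {
    se <- r * sqrt((pi_se[1] / model$pi[1])^2 + (pi_se[2] / model$pi[2])^2)
  }
  list(ratio = r, se = se)
}

#' Arrhenius free-energy profile of a kinetic model
#'
#' Converts rates and occupancies into a free-energy landscape in units of
#' kBT. Barrier heights follow the Arrhenius relation
#' `dG_ij = ln(A / k_ij)` with pre-exponential factor `A` (default 1e5 s^-1,
#' a conservative choice for large-scale conformational dynamics); state
#' free energies come from occupancy ratios,
#' `G_i - G_ref = ln(pi_ref / pi_i)`.
#'
#' @param model A [kinetic_model()].
#' @param A Pre-exponential factor, s^-1.
#' @param reference Reference state index (free energy 0).
#' @return A `free_energy_profile` list: `state_G` (kBT), `barrier_G` (K x K
#'   matrix, kBT, NA on disallowed transitions), `A`, `reference`, and
#'   `negative_barrier` flag matrix marking any `k_ij >= A`.
#' @export
free_energy_profile <- function(model, A = 1e5, reference = 1) {
  stopifnot(A > 0)
  mask <- model$connectivity
  if (any(model$Q[mask] <= 0)) stop("all allowed rates must be positive")
  state_G <- log(model$pi[reference] / model$pi)
  barrier <- matrix(NA_real_, model$K, model$K)
  barrier[mask] <- log(A / model$Q[mask])
  neg <- !is.na(barrier) & barrier < 0
  if (any(neg)) {
    warning("rate exceeds the pre-exponential factor; negative barrier flagged")
  }
  out <- list(state_G = state_G, barrier_G = barrier, A = A,
              reference = reference, negative_barrier = neg)
  class(out) <- "free_energy_profile"
  out
}

#' Rebuild rates from a free-energy profile
#'
#' Inverse of [free_energy_profile()]: `k_ij = A exp(-dG_ij)`. Round-trips
#' the input model's rates exactly.
#'
#' @param profile A `free_energy_profile`.
#' @return Rate matrix (s^-1).
#' @export
rates_from_profile <- function(profile) {
  Q <- matrix(0, nrow(profile$barrier_G), ncol(profile$barrier_G))
  ok <- !is.na(profile$barrier_G)
  Q[ok] <- profile$A * exp(-profile$barrier_G[ok])
  diag(Q) <- -rowSums(Q)
  Q
}

#' Binomial distribution of labeled protomers per complex
#'
#' For an oligomer assembled from a mix of labeled and unlabeled protomers,
#' the number of labeled protomers per complex is binomial:
#' `P(k) = choose(n, k) p^k (1-p)^(n-k)` with
#' `p = labeled / (labeled + unlabeled)`. At the working 1:100 mixing ratio
#' and `n = 6`, a hexamer carries exactly one label with probability 5.7%.
#'
#' @param n Protomers per complex (default 6, a hexamer).
#' @param labeled_conc,unlabeled_conc Concentrations (any common unit) of
#'   labeled and unlabeled protomers; not both zero.
#' @return A `labeling_mix` list: `n`, `p`, `P` (vector over k = 0..n),
#'   `P_one` and `P_multi` conveniences.
#' @export
labeling_distribution <- function(n = 6, labeled_conc, unlabeled_conc) {
  stopifnot(labeled_conc >= 0, unlabeled_conc >= 0,
            labeled_conc + unlabeled_conc > 0)
  p <- labeled_conc / (labeled_conc + unlabeled_conc)
  P <- stats::dbinom(0:n, n, p)
  names(P) <- paste0("k", 0:n)
  out <- list(n = n, p = p, P = P, P_one = unname(P[2]),
              P_multi = sum(P[-(1:2)]))
  class(out) <- "labeling_mix"
  out
}

#' Fit the Hill equation to saturation-kinetics data
#'
#' Nonlinear least squares of `v = Vmax S^n / (S^n + K05^n)` with positivity
#' constraints, started from data quantiles. Covariances come from the fit's
#' variance matrix.
#'
#' @param S Substrate concentrations.
#' @param v Measured rates.
#' @param fix_n Optional fixed Hill coefficient (e.g. 1 for a hyperbolic
#'   fit).
#' @return A `hill_fit` list: `Vmax`, `K05`, `n`, standard errors,
#'   `covariance`, `fit` (nls object), `converged`, `residuals`.
#' @export
fit_hill <- function(S, v, fix_n = NULL) {
  stopifnot(length(S) == length(v), length(S) >= 4)
  start <- list(Vmax = max(v) * 1.05,
                K05 = stats::approx(v, S, xout = max(v) / 2, ties = mean)$y)
  if (is.na(start$K05)) start$K05 <- stats::median(S)
  fml <- if (is.null(fix_n)) {
    start$n <- 1.5
    v ~ Vmax * S^n / (S^n + K05^n)
  } else {
    n <- fix_n
    v ~ Vmax * S^fix_n / (S^fix_n + K05^fix_n)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(S = S, v = v), start = start,
                      lower = rep(1e-12, length(start)),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(Vmax = NA, K05 = NA, n = fix_n, converged = FALSE,
                          residuals = v - mean(v)), class = "hill_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  out <- list(Vmax = unname(cf["Vmax"]), K05 = unname(cf["K05"]),
              n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
              se = se, covariance = tryCatch(vcov(fit), error = function(e) NULL),
              fit = fit, converged = TRUE, residuals = resid(fit))
  class(out) <- "hill_fit"
  out
}

#' Fit a one-site binding isotherm
#'
#' Fits `y(c) = r0 + amplitude * c / (c + Kd)` — the hyperbolic dose-response
#' of, e.g., the active/inactive population ratio against co-chaperone
#' concentration — by constrained nonlinear least squares.
#'
#' @param conc Ligand concentrations.
#' @param ratio Measured response (e.g. population ratio).
#' @return A `binding_fit` list: `r0`, `amplitude`, `Kd`, standard errors,
#'   `covariance`, `fit`, `converged`.
#' @export
fit_binding_isotherm <- function(conc, ratio) {
  stopifnot(length(conc) == length(ratio), length(conc) >= 4)
  # Kd start from the half-rise concentration; baseline from the smallest-c
  # response, amplitude from an assumed ~80% saturation at the largest c
  half <- stats::approx(ratio, conc,
                        xout = min(ratio) + (max(ratio) - min(ratio)) / 2,
                        ties = mean)$y
  if (is.na(half) || half <= 0) half <- stats::median(conc[conc > 0])
  start <- list(r0 = ratio[which.min(conc)],
                amplitude = (max(ratio) - min(ratio)) * 1.25,
                Kd = half)
  fit <- tryCatch(
    minpack.lm::nlsLM(ratio ~ r0 + amplitude * conc / (conc + Kd),
                      data = data.frame(conc = conc, ratio = ratio),
                      start = start, lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(Kd = NA, converged = FALSE), class = "binding_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  out <- list(r0 = unname(cf["r0"]), amplitude = unname(cf["amplitude"]),
              Kd = unname(cf["Kd"]), se = se,
              covariance = tryCatch(vcov(fit), error = function(e) NULL),
              fit = fit, converged = TRUE)
  class(out) <- "binding_fit"
  out
}
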