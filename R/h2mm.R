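#' Extract per-burst donor-excitation photon records for kinetic inference
#'
#' Photon-by-photon inference uses only photons detected after donor
#' excitation, each reduced to its color (donor or acceptor channel) and its
#' arrival time. This helper pulls those records out of a stream for a set of
#' detected bursts.
#'
#' @param stream A [photon_stream()].
#' @param bursts A `burst_table` from [detect_bursts()] (possibly corrected
#'   and filtered).
#' @return A `photon_bursts` list: `color` (0 donor / 1 acceptor), `dt`
#'   (interphoton interval in clock ticks, `NA` at each burst start), `t`
#'   (ticks), `burst` (1-based burst index), `clock_period`, `n_bursts`.
#' @export
burst_photons <- function(stream, bursts) {
  stopifnot(inherits(stream, "photon_stream"))
  idx_list <- lapply(seq_len(nrow(bursts)), function(b) {
    i <- bursts$start_idx[b]:bursts$end_idx[b]
    i[stream$excitation[i] == 0L]
  })
  keep <- lengths(idx_list) > 0
  idx_list <- idx_list[keep]
  idx <- unlist(idx_list)
  burst <- rep(seq_along(idx_list), lengths(idx_list))
  t <- stream$timestamp[idx]
  dt <- c(NA, diff(t))
  dt[c(1, which(diff(burst) != 0) + 1)] <- NA
  out <- list(color = stream$detector[idx], dt = dt, t = t, burst = burst,
              clock_period = attr(stream, "clock_period"),
              n_bursts = length(idx_list))
  class(out) <- "photon_bursts"
  out
}

#' Build photon bursts directly from simulation ground truth
#'
#' Bypasses burst detection: collects the donor-excitation photons of every
#' simulated double-labeled burst, keyed by the generator's burst labels.
#' Useful for validation analyses that need uncontaminated bursts.
#'
#' @param sim Result of [simulate_photon_stream()].
#' @param min_photons Minimum donor-excitation photons per burst.
#' @return A `photon_bursts` list (see [burst_photons()]).
#' @export
burst_photons_from_truth <- function(sim, min_photons = 20) {
  st <- sim$stream
  tr <- sim$truth
  dbl <- tr$bursts$burst_id[tr$bursts$species == "double"]
  sel <- !is.na(tr$burst_id) & tr$burst_id %in% dbl & st$excitation == 0L
  id <- tr$burst_id[sel]
  t <- st$timestamp[sel]
  col <- st$detector[sel]
  counts <- table(id)
  good <- as.integer(names(counts)[counts >= min_photons])
  keep <- id %in% good
  id <- id[keep]; t <- t[keep]; col <- col[keep]
  burst <- match(id, unique(id))
  dt <- c(NA, diff(t))
  dt[c(1, which(diff(burst) != 0) + 1)] <- NA
  out <- list(color = col, dt = dt, t = t, burst = burst,
              clock_period = attr(st, "clock_period"),
              n_bursts = length(unique(burst)),
              truth_state = tr$state[sel][keep])
  class(out) <- "photon_bursts"
  out
}

#' @export
print.photon_bursts <- function(x, ...) {
  cat(sprintf("<photon_bursts> %d photons in %d bursts (donor excitation)\n",
              length(x$color), x$n_bursts))
  invisible(x)
}

.bp_prep <- function(model, bp) {
  uq <- sort(unique(bp$dt[!is.na(bp$dt)]))
  gap_idx <- ifelse(is.na(bp$dt), 0L, match(bp$dt, uq))
  P <- ctmc_propagators(model$Q, uq * bp$clock_period)
  list(gap_idx = as.integer(gap_idx), P = as.numeric(P), uq = uq)
}

#' Photon-by-photon log-likelihood of a kinetic model
#'
#' Forward recursion over the colored photon sequence of every burst under
#' the hidden continuous-time Markov chain: between consecutive photons the
#' hidden state evolves by the propagator `exp(Q * dt)`; each photon is
#' acceptor-colored with the current state's FRET efficiency. Bursts are
#' independent (each restarts at the stationary distribution) and their
#' log-likelihoods add. The recursion is normalized per photon, so bursts of
#' arbitrary length are numerically safe.
#'
#' @param model A [kinetic_model()].
#' @param bp A `photon_bursts` object.
#' @return Total log-likelihood (scalar).
#' @export
photon_likelihood <- function(model, bp) {
  stopifnot(inherits(model, "kinetic_model"), inherits(bp, "photon_bursts"))
  pr <- .bp_prep(model, bp)
  h2mm_loglik_cpp(as.integer(bp$color), pr$gap_idx, pr$P,
                  model$E, model$pi, model$K)
}

.chain_mask <- function(K) {
  m <- matrix(FALSE, K, K)
  for (i in seq_len(K - 1)) { m[i, i + 1] <- TRUE; m[i + 1, i] <- TRUE }
  m
}

.full_mask <- function(K) {
  m <- matrix(TRUE, K, K); diag(m) <- FALSE; m
}

.build_model <- function(theta, K, mask) {
  E <- stats::plogis(theta[seq_len(K)])
  Q <- matrix(0, K, K)
  Q[which(mask)] <- exp(theta[-seq_len(K)])
  diag(Q) <- -rowSums(Q)
  kinetic_model(E, Q, connectivity = mask)
}

#' Fit a K-state kinetic model to photon bursts by maximum likelihood
#'
#' Maximizes [photon_likelihood()] over the per-state efficiencies and the
#' allowed transition rates by quasi-Newton ascent on an unconstrained
#' parameterization (logit efficiencies, log rates), with multiple random
#' restarts and best-of selection. States of the returned model are in
#' canonical order (descending efficiency). For `K = 1` the maximum is closed
#' form: the efficiency equals the overall acceptor fraction.
#'
#' @param bp A `photon_bursts` object.
#' @param K Number of states.
#' @param connectivity `"sequential"` (chain, the default, as found for the
#'   M domain), `"full"`, or a logical mask matrix.
#' @param init Optional list with `E` and `rates` (vector over allowed
#'   transitions, row-major) to seed the first start.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum optimizer iterations per restart.
#' @param n_restarts Number of random restarts (first start is deterministic,
#'   from burst-efficiency quantiles).
#' @param seed Integer seed controlling restart jitter.
#' @return An `h2mm_fit` list: `model`, `loglik`, `loglik_trace` (best-so-far
#'   log-likelihood over objective evaluations, non-decreasing), `n_iter`,
#'   `converged`, `K`, `n_photons`, `n_bursts`, `restart_logliks`.
#' @export
fit_h2mm <- function(bp, K, connectivity = "sequential", init = NULL,
                     tol = 1e-6, max_iter = 1000, n_restarts = 5, seed = 1) {
  stopifnot(inherits(bp, "photon_bursts"), K >= 1, bp$n_bursts >= 1)
  n_ph <- length(bp$color)
  if (K == 1) {
    E <- mean(bp$color)
    ll <- sum(bp$color == 1) * log(E) + sum(bp$color == 0) * log(1 - E)
    if (!is.finite(ll)) ll <- 0  # degenerate all-one-color stream
    model <- kinetic_model(E, matrix(0, 1, 1))
    out <- list(model = model, loglik = ll, loglik_trace = ll, n_iter = 0L,
                converged = TRUE, K = 1L, n_photons = n_ph,
                n_bursts = bp$n_bursts, restart_logliks = ll)
    class(out) <- "h2mm_fit"
    return(out)
  }
  mask <- if (is.matrix(connectivity)) {
    storage.mode(connectivity) <- "logical"; connectivity
  } else switch(connectivity,
                sequential = .chain_mask(K),
                full = .full_mask(K),
                stop("unknown connectivity: ", connectivity))
  n_rates <- sum(mask)

  # deterministic initial guess: E from burst-efficiency quantiles
  # (descending), rates at 1/(10 x mean interphoton time)
  bE <- tapply(bp$color, bp$burst, mean)
  E0 <- unname(quantile(bE, probs = rev(seq_len(K)) / (K + 1), names = FALSE))
  E0 <- pmin(pmax(E0, 0.02), 0.98)
  if (any(duplicated(round(E0, 3)))) E0 <- E0 + seq(0, 0.02, length.out = K)
  mean_dt <- mean(bp$dt, na.rm = TRUE) * bp$clock_period
  r0 <- 1 / (10 * mean_dt)
  starts <- list(list(E = sort(E0, decreasing = TRUE), rates = rep(r0, n_rates)))
  if (!is.null(init)) starts <- c(list(init), starts)
  extra <- withr::with_seed(seed, lapply(seq_len(max(0, n_restarts - length(starts))),
    function(i) {
      list(E = pmin(pmax(sort(E0 + rnorm(K, 0, 0.08), decreasing = TRUE), 0.01), 0.99),
           rates = r0 * exp(rnorm(n_rates, 0, 0.7)))
    }))
  starts <- c(starts, extra)

  # gap indexing is model-independent: hoist it out of the objective
  uq <- sort(unique(bp$dt[!is.na(bp$dt)]))
  gap_idx <- as.integer(ifelse(is.na(bp$dt), 0L, match(bp$dt, uq)))
  uq_sec <- uq * bp$clock_period
  colors <- as.integer(bp$color)
  mask_idx <- which(mask)

  best <- NULL
  restart_ll <- numeric(0)
  for (st in starts) {
    theta0 <- c(stats::qlogis(st$E), log(st$rates))
    trace_env <- new.env()
    trace_env$tr <- numeric(0)
    negll <- function(theta) {
      E <- stats::plogis(theta[seq_len(K)])
      Q <- matrix(0, K, K)
      Q[mask_idx] <- exp(theta[-seq_len(K)])
      diag(Q) <- -rowSums(Q)
      pi0 <- tryCatch(stationary_distribution(Q), error = function(e) NULL)
      if (is.null(pi0)) return(1e12)
      P <- ctmc_propagators(Q, uq_sec)
      ll <- h2mm_loglik_cpp(colors, gap_idx, as.numeric(P), E, pi0, K)
      if (!is.finite(ll)) return(1e12)
      trace_env$tr <- c(trace_env$tr, ll)
      -ll
    }
    opt <- optim(theta0, negll, method = "L-BFGS-B",
                 lower = c(rep(stats::qlogis(1e-4), K), rep(log(1e-2), n_rates)),
                 upper = c(rep(stats::qlogis(1 - 1e-4), K), rep(log(1e7), n_rates)),
                 control = list(maxit = max_iter,
                                factr = tol / .Machine$double.eps))
    ll <- -opt$value
    restart_ll <- c(restart_ll, ll)
    if (is.null(best) || ll > best$loglik) {
      best <- list(loglik = ll, par = opt$par,
                   trace = cummax(trace_env$tr),
                   n_iter = opt$counts[["function"]],
                   converged = opt$convergence == 0)
    }
  }
  model <- canonical_order(.build_model(best$par, K, mask))
  out <- list(model = model, loglik = best$loglik,
              loglik_trace = best$trace, n_iter = best$n_iter,
              converged = best$converged, K = as.integer(K),
              n_photons = n_ph, n_bursts = bp$n_bursts,
              restart_logliks = restart_ll)
  class(out) <- "h2mm_fit"
  if (!best$converged) {
    warning("optimizer did not report convergence within max_iter; result flagged")
  }
  out
}

#' @export
print.h2mm_fit <- function(x, ...) {
  cat(sprintf("<h2mm_fit> K = %d, loglik = %.2f (%d photons, %d bursts)%s\n",
              x$K, x$loglik, x$n_photons, x$n_bursts,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$model)
  invisible(x)
}

#' Bootstrap uncertainties for a fitted kinetic model
#'
#' Resamples bursts with replacement and refits from the point estimate,
#' giving standard errors for the efficiencies, the allowed rates, and the
#' stationary occupancies.
#'
#' @param fit An `h2mm_fit`.
#' @param bp The `photon_bursts` the model was fitted to.
#' @param n_boot Number of bootstrap resamples (default 20).
#' @param seed Integer seed.
#' @return List with `E_se`, `rate_se` (matrix, NA off the connectivity),
#'   `pi_se`, and the raw bootstrap draws.
#' @export
h2mm_bootstrap <- function(fit, bp, n_boot = 20, seed = 1) {
  mask <- fit$model$connectivity
  draws_E <- matrix(NA_real_, n_boot, fit$K)
  draws_r <- matrix(NA_real_, n_boot, sum(mask))
  draws_p <- matrix(NA_real_, n_boot, fit$K)
  ids <- withr::with_seed(seed, replicate(n_boot,
    sample.int(bp$n_bursts, bp$n_bursts, replace = TRUE), simplify = FALSE))
  init <- list(E = fit$model$E, rates = fit$model$Q[which(mask)])
  for (i in seq_len(n_boot)) {
    bpi <- .bp_subset(bp, ids[[i]])
    f <- fit_h2mm(bpi, fit$K, connectivity = mask, init = init,
                  n_restarts = 1, seed = seed + i)
    draws_E[i, ] <- f$model$E
    draws_r[i, ] <- f$model$Q[which(f$model$connectivity)]
    draws_p[i, ] <- f$model$pi
  }
  rate_se <- matrix(NA_real_, fit$K, fit$K)
  rate_se[which(mask)] <- apply(draws_r, 2, sd)
  list(E_se = apply(draws_E, 2, sd), rate_se = rate_se,
       pi_se = apply(draws_p, 2, sd),
       draws = list(E = draws_E, rates = draws_r, pi = draws_p))
}

.bp_subset <- function(bp, burst_ids) {
  pieces <- lapply(burst_ids, function(b) which(bp$burst == b))
  idx <- unlist(pieces)
  burst <- rep(seq_along(pieces), lengths(pieces))
  dt <- bp$dt[idx]
  dt[c(1, which(diff(burst) != 0) + 1)] <- NA
  out <- list(color = bp$color[idx], dt = dt, t = bp$t[idx], burst = burst,
              clock_period = bp$clock_period, n_bursts = length(pieces))
  class(out) <- "photon_bursts"
  out
}

#' Compare state counts by parsimony and recoloring
#'
#' Fits each candidate `K` and reports the log-likelihood, a Bayesian
#' information criterion (`-2 logL + p log n_photons`), and the recoloring
#' histogram discrepancy (reduced chi-square, see [recoloring_check()]). The
#' recommended state count is the smallest `K` whose recoloring discrepancy
#' passes the threshold — the validation the field trusts — falling back to
#' the BIC minimum if none passes.
#'
#' @param bp A `photon_bursts` object.
#' @param K_range Candidate state counts (default 1:4).
#' @param threshold Reduced chi-square acceptance threshold (default 2).
#' @param ... Passed to [fit_h2mm()].
#' @param seed Integer seed (restarts and recoloring).
#' @return List with `table` (K, loglik, n_par, bic, recolor_chi2red) and
#'   `recommended_K`; fitted models attached as `fits`.
#' @export
select_state_number <- function(bp, K_range = 1:4, threshold = 2, seed = 1, ...) {
  fits <- lapply(K_range, function(K) fit_h2mm(bp, K, seed = seed, ...))
  n_ph <- length(bp$color)
  rows <- lapply(seq_along(K_range), function(i) {
    f <- fits[[i]]
    p <- f$K + sum(f$model$connectivity)
    rc <- recoloring_check(f$model, bp, seed = seed)
    data.frame(K = f$K, loglik = f$loglik, n_par = p,
               bic = -2 * f$loglik + p * log(n_ph),
               recolor_chi2red = rc$chi2_reduced)
  })
  tab <- do.call(rbind, rows)
  pass <- which(tab$recolor_chi2red < threshold)
  recommended <- if (length(pass)) tab$K[min(pass)] else tab$K[which.min(tab$bic)]
  list(table = tab, recommended_K = recommended, fits = fits)
}

#' Most-likely hidden state path per burst
#'
#' Viterbi decoding under the same interphoton propagators and per-state
#' emission probabilities as [photon_likelihood()].
#'
#' @param model A [kinetic_model()].
#' @param bp A `photon_bursts` object.
#' @return Integer vector of 1-based state assignments, aligned with
#'   `bp$color`.
#' @export
viterbi_paths <- function(model, bp) {
  pr <- .bp_prep(model, bp)
  h2mm_viterbi_cpp(as.integer(bp$color), pr$gap_idx, pr$P,
                   model$E, model$pi, model$K)
}

#' Recolor photon arrival times from a kinetic model
#'
#' The recoloring validation: for each burst, a fresh hidden state path is
#' simulated from the model over the burst's real photon arrival times, and
#' each photon's color is redrawn from its state's emission probability. If
#' the model describes the data, the recolored burst-efficiency histogram
#' reproduces the measured one, including its dynamic broadening.
#'
#' @param model A [kinetic_model()].
#' @param bp A `photon_bursts` object (real arrival times).
#' @param seed Integer seed.
#' @param n_rep Number of independent recolorings.
#' @return Matrix of per-burst recolored efficiencies, `n_bursts x n_rep`.
#' @export
recolor <- function(model, bp, seed = 1, n_rep = 1) {
  splits <- split(seq_along(bp$color), bp$burst)
  withr::with_seed(seed, {
    out <- matrix(NA_real_, length(splits), n_rep)
    for (r in seq_len(n_rep)) {
      for (b in seq_along(splits)) {
        idx <- splits[[b]]
        tt <- (bp$t[idx] - bp$t[idx[1]]) * bp$clock_period
        dur <- max(tt[length(tt)], bp$clock_period)
        path <- simulate_state_path(model, dur * (1 + 1e-9))
        st <- path$state[findInterval(tt, path$t0)]
        cols <- rbinom(length(idx), 1, model$E[st])
        out[b, r] <- mean(cols)
      }
    }
    out
  })
}

#' Chi-square discrepancy between data and recolored histograms
#'
#' Bins the measured per-burst efficiencies and compares them to the expected
#' bin proportions from `n_rep` recolorings, via a Pearson chi-square with
#' sparse bins pooled (expected count >= 5). The reduced chi-square is the
#' discrepancy statistic; a fitted model that describes the data gives values
#' near 1.
#'
#' @param model A [kinetic_model()].
#' @param bp A `photon_bursts` object.
#' @param n_bins Histogram bins over \[0, 1\].
#' @param n_rep Recolorings averaged into the expectation.
#' @param seed Integer seed.
#' @param threshold Pass threshold on the reduced chi-square.
#' @return List: `chi2`, `dof`, `chi2_reduced`, `p_value`, `pass`.
#' @export
recoloring_check <- function(model, bp, n_bins = 25, n_rep = 10, seed = 1,
                             threshold = 2) {
  bE <- tapply(bp$color, bp$burst, mean)
  rc <- as.vector(recolor(model, bp, seed = seed, n_rep = n_rep))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(x) tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                                   n_bins), nbins = n_bins)
  obs <- bin(bE)
  expec <- bin(rc) / n_rep
  # pool sparse bins left to right
  o <- numeric(0); e <- numeric(0); co <- 0; ce <- 0
  for (i in seq_len(n_bins)) {
    co <- co + obs[i]; ce <- ce + expec[i]
    if (ce >= 5) { o <- c(o, co); e <- c(e, ce); co <- 0; ce <- 0 }
  }
  if (ce > 0 && length(e)) { e[length(e)] <- e[length(e)] + ce; o[length(o)] <- o[length(o)] + co }
  # match totals so only shape is tested
  e <- e * sum(o) / sum(e)
  chi2 <- sum((o - e)^2 / e)
  dof <- max(length(e) - 1, 1)
  list(chi2 = chi2, dof = dof, chi2_reduced = chi2 / dof,
       p_value = pchisq(chi2, dof, lower.tail = FALSE),
       pass = (chi2 / dof) < threshold)
}

#' Dwell-time analysis of decoded state paths
#'
#' Splits each burst's Viterbi path into dwell segments (boundaries at the
#' midpoint between adjacent photons assigned to different states). Edge
#' dwells are censored by the burst window; exit rates are therefore
#' estimated with the censoring-aware exponential estimator
#' (observed exits / total time at risk), alongside a naive exponential fit
#' to the complete (interior-terminated) dwells.
#'
#' @param paths Integer state path from [viterbi_paths()].
#' @param bp The matching `photon_bursts`.
#' @param min_dwells Minimum observed exits required to report a rate.
#' @return List per state: `dwells` (durations, s), `censored` flags,
#'   `n_exits`, `exposure` (s), `exit_rate` (s^-1), `mean_dwell` (s),
#'   `rate_naive`. States with too few exits report `NA` rates with a notice.
#' @export
dwell_time_analysis <- function(paths, bp, min_dwells = 10) {
  K <- max(paths)
  segs <- .dwell_segments(paths, bp)
  out <- lapply(seq_len(K), function(s) {
    d <- segs[segs$state == s, , drop = FALSE]
    n_exits <- sum(!d$right_censored)
    exposure <- sum(d$duration)
    if (n_exits < min_dwells) {
      message("state ", s, ": only ", n_exits,
              " complete dwells; rate estimate skipped")
      rate <- NA_real_
    } else {
      rate <- n_exits / exposure
    }
    complete <- d$duration[!d$right_censored & !d$left_censored]
    list(dwells = d$duration, censored = d$right_censored | d$left_censored,
         n_exits = n_exits, exposure = exposure, exit_rate = rate,
         mean_dwell = 1 / rate,
         rate_naive = if (length(complete) >= min_dwells) 1 / mean(complete) else NA_real_)
  })
  names(out) <- paste0("state", seq_len(K))
  out
}

.dwell_segments <- function(paths, bp) {
  res <- vector("list", bp$n_bursts)
  splits <- split(seq_along(paths), bp$burst)
  for (b in seq_along(splits)) {
    idx <- splits[[b]]
    st <- paths[idx]
    tt <- bp$t[idx] * bp$clock_period
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    nseg <- length(r$values)
    # boundaries at midpoints between adjacent opposite-state photons
    b_lo <- c(tt[1], (tt[starts[-1]] + tt[ends[-nseg]]) / 2)
    b_hi <- c(b_lo[-1], tt[length(tt)])
    res[[b]] <- data.frame(state = r$values,
                           duration = b_hi - b_lo,
                           n_photons = r$lengths,
                           first = tt[starts], last = tt[ends],
                           left_censored = seq_len(nseg) == 1,
                           right_censored = seq_len(nseg) == nseg,
                           burst = b)
  }
  do.call(rbind, res)
}

#' Efficiency histogram of per-dwell segments
#'
#' Each Viterbi dwell with at least `min_photons` photons contributes one
#' efficiency value (its acceptor fraction). Because a segment sits within a
#' single state, this histogram resolves the state efficiencies that the
#' per-burst histogram blurs by time averaging.
#'
#' @param paths State path from [viterbi_paths()].
#' @param bp The matching `photon_bursts`.
#' @param min_photons Minimum photons per contributing segment (default 10).
#' @param n_bins Histogram bins.
#' @return An `e_histogram` (see [fret_histogram()]); segment efficiencies in
#'   attribute `E`.
#' @export
segmentation_histogram <- function(paths, bp, min_photons = 10, n_bins = 40) {
  seg_id <- cumsum(c(1, diff(paths) != 0 | diff(bp$burst) != 0))
  segE <- tapply(bp$color, seg_id, mean)
  segN <- tapply(bp$color, seg_id, length)
  E <- segE[segN >= min_photons]
  h <- fret_histogram(as.numeric(E), n_bins = n_bins)
  attr(h, "E") <- as.numeric(E)
  h
}

#' Donor-acceptor intensity cross-correlation of burst photons
#'
#' Bins each burst's donor-excitation photons by color and accumulates the
#' normalized donor x acceptor cross-correlation over lags, pooled across
#' bursts (symmetrized in lag sign). Anticorrelated FRET dynamics produce a
#' dip at short lags that relaxes to 1 with the exchange relaxation time; a
#' single-exponential fit `G(tau) = a + b exp(-tau / tau_R)` returns that
#' time. For a two-state system `tau_R = 1 / (k12 + k21)`.
#'
#' @param bp A `photon_bursts` object.
#' @param bin_width Correlation bin width (s), default 10 us.
#' @param max_lag Largest lag (s); lags beyond the longest burst are
#'   truncated with a notice.
#' @return List: `lag` (s), `G`, `n_pairs`, `relaxation_time` (s; NA if the
#'   exponential fit fails or the curve is flat), `fit` (the nls object or
#'   NULL), `amplitude`.
#' @export
donor_acceptor_crosscorrelation <- function(bp, bin_width = 1e-5,
                                            max_lag = 5e-4) {
  splits <- split(seq_along(bp$color), bp$burst)
  durs <- vapply(splits, function(i) diff(range(bp$t[i])) * bp$clock_period,
                 numeric(1))
  if (max_lag > max(durs)) {
    message("max_lag exceeds the longest burst; truncating to ",
            signif(max(durs), 3), " s")
    max_lag <- max(durs)
  }
  M <- max(1L, floor(max_lag / bin_width))
  num <- numeric(M); den <- numeric(M)
  for (i in splits) {
    tt <- (bp$t[i] - bp$t[i[1]]) * bp$clock_period
    nb <- floor(tt[length(tt)] / bin_width) + 1
    if (nb < 4) next
    bins <- pmin(floor(tt / bin_width) + 1, nb)
    col <- bp$color[i]
    d <- tabulate(bins[col == 0L], nbins = nb)
    a <- tabulate(bins[col == 1L], nbins = nb)
    md <- mean(d); ma <- mean(a)
    if (md == 0 || ma == 0) next
    mm <- min(M, nb - 1)
    for (m in seq_len(mm)) {
      sl <- seq_len(nb - m)
      num[m] <- num[m] + sum(d[sl] * a[sl + m]) + sum(a[sl] * d[sl + m])
      den[m] <- den[m] + 2 * (nb - m) * md * ma
    }
  }
  ok <- den > 0
  lag <- (seq_len(M) * bin_width)[ok]
  G <- (num / den)[ok]
  amp <- NA_real_; tau <- NA_real_; fit <- NULL
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ a + b * exp(-lag / tau),
                      start = list(a = mean(tail(G, 5)),
                                   b = G[1] - mean(tail(G, 5)),
                                   tau = max_lag / 5),
                      lower = c(0, -Inf, bin_width / 10),
                      upper = c(Inf, Inf, max_lag * 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    amp <- unname(cf["b"]); tau <- unname(cf["tau"])
    # a flat curve has no identifiable relaxation time
    if (abs(amp) < 2 * sd(G) / sqrt(length(G))) tau <- NA_real_
  }
  list(lag = lag, G = G, n_pairs = num, relaxation_time = tau,
       amplitude = amp, fit = fit)
}
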