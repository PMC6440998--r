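#' Detect single-molecule bursts by smoothed interphoton times
#'
#' Implements the sliding-window burst search used for diffusing molecules:
#' interphoton times are smoothed with a centered running average of `window`
#' photons; a maximal run of smoothed intervals below the `cutoff` defines a
#' candidate burst, whose edges are then expanded outward over any raw
#' interval still below the cutoff (making edge assignment deterministic).
#' Bursts with fewer than `min_photons` photons — counted over both detection
#' channels and both excitation slots — are discarded. No background or
#' crosstalk correction is applied at this stage.
#'
#' @param stream A [photon_stream()].
#' @param window Running-average window in photons (default 15).
#' @param cutoff Interphoton-time threshold in seconds (default 10 us).
#' @param min_photons Minimum photons per burst (default 30).
#' @return A `burst_table` data frame: `start_idx`, `end_idx` (photon indices
#'   into the stream), `n_photons`, `n_DD`, `n_DA`, `n_AA`, `duration` (s).
#' @export
detect_bursts <- function(stream, window = 15, cutoff = 1e-5, min_photons = 30) {
  stopifnot(inherits(stream, "photon_stream"), nrow(stream) > 0)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (window < 1) stop("window must be at least 1 photon")
  n <- nrow(stream)
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      n_photons = integer(0), n_DD = integer(0),
                      n_DA = integer(0), n_AA = integer(0),
                      duration = numeric(0))
  class(empty) <- c("burst_table", "data.frame")
  if (n < 2) return(empty)
  clock <- attr(stream, "clock_period")
  dt <- diff(stream$timestamp) * clock
  sm <- as.numeric(stats::filter(dt, rep(1 / window, window), sides = 2))
  # shrink the window near the ends instead of dropping them
  half <- (window - 1) %/% 2
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(length(dt), i + half)
    sm[i] <- mean(dt[lo:hi])
  }
  fast <- sm < cutoff
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  # run over intervals [a, b] covers photons a .. b+1; expand over raw dt < cutoff
  a <- starts[keep]; b <- ends[keep]
  for (j in seq_along(a)) {
    while (a[j] > 1 && dt[a[j] - 1] < cutoff) a[j] <- a[j] - 1
    while (b[j] < length(dt) && dt[b[j] + 1] < cutoff) b[j] <- b[j] + 1
  }
  # merge any runs that expansion made overlap or touch
  ord <- order(a)
  a <- a[ord]; b <- b[ord]
  ma <- a[1]; mb <- b[1]; outa <- integer(0); outb <- integer(0)
  for (j in seq_along(a)[-1]) {
    if (a[j] <= mb + 1) mb <- max(mb, b[j]) else {
      outa <- c(outa, ma); outb <- c(outb, mb); ma <- a[j]; mb <- b[j]
    }
  }
  outa <- c(outa, ma); outb <- c(outb, mb)
  start_idx <- outa
  end_idx <- outb + 1L
  n_ph <- end_idx - start_idx + 1L
  sel <- n_ph >= min_photons
  start_idx <- start_idx[sel]; end_idx <- end_idx[sel]; n_ph <- n_ph[sel]
  if (!length(start_idx)) return(empty)
  cls <- .photon_class(stream)
  csum <- function(x) c(0, cumsum(x))
  cDD <- csum(cls == "DD"); cDA <- csum(cls == "DA"); cAA <- csum(cls == "AA")
  out <- data.frame(
    start_idx = start_idx, end_idx = end_idx, n_photons = n_ph,
    n_DD = as.integer(cDD[end_idx + 1] - cDD[start_idx]),
    n_DA = as.integer(cDA[end_idx + 1] - cDA[start_idx]),
    n_AA = as.integer(cAA[end_idx + 1] - cAA[start_idx]),
    duration = (stream$timestamp[end_idx] - stream$timestamp[start_idx]) * clock
  )
  class(out) <- c("burst_table", "data.frame")
  out
}

.photon_class <- function(stream) {
  cls <- rep("other", nrow(stream))
  cls[stream$excitation == 0L & stream$detector == 0L] <- "DD"
  cls[stream$excitation == 0L & stream$detector == 1L] <- "DA"
  cls[stream$excitation == 1L & stream$detector == 1L] <- "AA"
  cls
}

#' Raw FRET efficiency and stoichiometry per burst
#'
#' `E_raw = n_DA / (n_DD + n_DA)` uses photons detected after donor
#' excitation only; `S_raw = (n_DD + n_DA) / (n_DD + n_DA + n_AA)` uses
#' photons from both excitations. Bursts with an undefined denominator are
#' flagged (`valid = FALSE`) rather than dropped; raw values are not clipped.
#'
#' @param bursts A `burst_table` from [detect_bursts()] (or any data frame
#'   with `n_DD`, `n_DA`, `n_AA` columns).
#' @return The table with columns `E_raw`, `S_raw`, `valid` added.
#' @export
compute_raw_es <- function(bursts) {
  nde <- bursts$n_DD + bursts$n_DA
  tot <- nde + bursts$n_AA
  bursts$E_raw <- ifelse(nde > 0, bursts$n_DA / nde, NA_real_)
  bursts$S_raw <- ifelse(tot > 0, nde / tot, NA_real_)
  bursts$valid <- nde > 0 & tot > 0
  bursts
}

#' Estimate leakage and direct-excitation factors from single-dye populations
#'
#' From the raw E/S populations: donor-only molecules (high stoichiometry)
#' have no acceptor, so their apparent FRET efficiency measures the fraction
#' of donor photons leaking into the acceptor channel; acceptor-only
#' molecules (low stoichiometry) produce donor-slot photons only through
#' direct excitation, so their stoichiometry measures that level. The
#' returned `direct_excitation` is expressed per donor-excitation event,
#' i.e. rescaled by the PIE pulse ratio.
#'
#' @param bursts Burst table with `E_raw`, `S_raw` (see [compute_raw_es()]).
#' @param donor_only_s_min Stoichiometry above which a burst is treated as
#'   donor-only (default 0.9).
#' @param acceptor_only_s_max Stoichiometry below which a burst is treated as
#'   acceptor-only (default 0.2).
#' @param pie_ratio Donor:acceptor pulse ratio used in the measurement.
#' @return A `correction_factors` list: `leakage`, `direct_excitation`, and
#'   `diagnostics` (population sizes and S windows used).
#' @export
estimate_corrections <- function(bursts, donor_only_s_min = 0.9,
                                 acceptor_only_s_max = 0.2,
                                 pie_ratio = c(3L, 1L)) {
  ok <- !is.na(bursts$S_raw)
  don <- ok & bursts$S_raw >= donor_only_s_min & !is.na(bursts$E_raw)
  acc <- ok & bursts$S_raw <= acceptor_only_s_max
  if (!any(don)) stop("no donor-only population found above S = ", donor_only_s_min)
  if (!any(acc)) stop("no acceptor-only population found below S = ", acceptor_only_s_max)
  # pool photons rather than average per-burst ratios (small-count robustness)
  leakage <- sum(bursts$n_DA[don]) / sum(bursts$n_DA[don] + bursts$n_DD[don])
  s_acc <- sum(bursts$n_DA[acc] + bursts$n_DD[acc]) /
    sum(bursts$n_DA[acc] + bursts$n_DD[acc] + bursts$n_AA[acc])
  d_coef <- s_acc / (1 - s_acc)                    # DA counts per AA count
  slot_ratio <- pie_ratio[1] / pie_ratio[2]
  out <- list(leakage = leakage,
              direct_excitation = d_coef / slot_ratio,
              diagnostics = list(n_donor_only = sum(don),
                                 n_acceptor_only = sum(acc),
                                 donor_only_s_min = donor_only_s_min,
                                 acceptor_only_s_max = acceptor_only_s_max,
                                 pie_ratio = pie_ratio))
  class(out) <- "correction_factors"
  out
}

#' Correct burst counts and select double-labeled molecules
#'
#' Applies the leakage and direct-excitation corrections to the donor-slot
#' acceptor counts: leaked photons are moved back to the donor channel
#' (`n_DD / (1 - leakage)`) and the direct-excitation contribution
#' (proportional to `n_AA` scaled by the pulse ratio) is subtracted from
#' `n_DA`. Corrected E/S may fall slightly outside \[0, 1\] and are reported
#' as-is with an `out_of_range` flag. Bursts whose corrected stoichiometry
#' falls outside `s_window` are removed.
#'
#' @param bursts Burst table with raw counts and `E_raw`/`S_raw`.
#' @param factors A `correction_factors` object (or list with `leakage` and
#'   `direct_excitation`).
#' @param s_window Stoichiometry window retaining double-labeled molecules
#'   (default `c(0.3, 0.8)`).
#' @param pie_ratio Donor:acceptor pulse ratio.
#' @return Filtered burst table with `E_corr`, `S_corr`, `out_of_range`;
#'   attribute `n_removed` records how many bursts fell outside the window.
#' @export
apply_corrections_and_filter <- function(bursts, factors,
                                         s_window = c(0.3, 0.8),
                                         pie_ratio = c(3L, 1L)) {
  l <- factors$leakage
  d_coef <- factors$direct_excitation * pie_ratio[1] / pie_ratio[2]
  nDD <- bursts$n_DD / (1 - l)
  nDA <- bursts$n_DA - (l / (1 - l)) * bursts$n_DD - d_coef * bursts$n_AA
  nde <- nDD + nDA
  tot <- nde + bursts$n_AA
  bursts$E_corr <- ifelse(nde > 0, nDA / nde, NA_real_)
  bursts$S_corr <- ifelse(tot > 0, nde / tot, NA_real_)
  bursts$out_of_range <- !is.na(bursts$E_corr) &
    (bursts$E_corr < 0 | bursts$E_corr > 1)
  keep <- !is.na(bursts$S_corr) &
    bursts$S_corr >= s_window[1] & bursts$S_corr <= s_window[2]
  if (!any(keep)) warning("no bursts survive the stoichiometry window")
  out <- bursts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- c("burst_table", "data.frame")
  out
}

#' FRET efficiency histogram over bursts
#'
#' @param E Vector of per-burst FRET efficiencies (raw or corrected); values
#'   outside the bin range are clamped into the outer bins so that counts sum
#'   to the number of bursts.
#' @param n_bins Number of equal-width bins (default 40).
#' @param range Histogram range (default `c(0, 1)`).
#' @return An `e_histogram` list: `breaks`, `mids`, `counts`, `density`,
#'   `n_bursts`.
#' @export
fret_histogram <- function(E, n_bins = 40, range = c(0, 1)) {
  E <- E[!is.na(E)]
  if (!length(E)) stop("no valid efficiencies to histogram")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  Ec <- pmin(pmax(E, range[1]), range[2])
  idx <- pmin(findInterval(Ec, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- list(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
              counts = counts,
              density = counts / sum(counts) / diff(breaks)[1],
              n_bursts = length(E))
  class(out) <- "e_histogram"
  out
}

#' Locate modes of an efficiency histogram
#'
#' Simple peak finder: local maxima of the (optionally lightly smoothed)
#' counts, ranked by height.
#'
#' @param h An `e_histogram`.
#' @param n_peaks Number of peaks to return.
#' @param smooth Moving-average half-width in bins (0 = none).
#' @return Data frame `position`, `height`, ordered by height.
#' @export
histogram_peaks <- function(h, n_peaks = 2, smooth = 1) {
  y <- h$counts
  if (smooth > 0) {
    w <- 2 * smooth + 1
    y <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    y[is.na(y)] <- h$counts[is.na(y)]
  }
  n <- length(y)
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    y[i] == max(y[lo:hi]) && y[i] > 0
  }, logical(1))
  # collapse plateaus
  idx <- which(is_peak)
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 1)]
  ord <- idx[order(y[idx], decreasing = TRUE)]
  ord <- head(ord, n_peaks)
  data.frame(position = h$mids[ord], height = y[ord])
}

#' Shot-noise (static molecule) reference histogram
#'
#' For each burst, redraws the donor-slot acceptor count binomially at a
#' fixed efficiency with that burst's donor-excitation photon number. The
#' resulting histogram is the width expected from photon-counting statistics
#' alone; dynamic exchange broadens the measured histogram beyond it.
#'
#' @param bursts Burst table with `n_DD`, `n_DA`.
#' @param E_mean The fixed efficiency of the hypothetical static molecule.
#' @param n_bins,range Passed to [fret_histogram()].
#' @param seed Integer seed for the binomial draws.
#' @return An `e_histogram`; the drawn per-burst efficiencies are attached as
#'   attribute `E`.
#' @export
shot_noise_reference <- function(bursts, E_mean, n_bins = 40,
                                 range = c(0, 1), seed = 1) {
  N <- bursts$n_DD + bursts$n_DA
  N <- N[N > 0]
  E <- withr::with_seed(seed, rbinom(length(N), N, E_mean) / N)
  h <- fret_histogram(E, n_bins = n_bins, range = range)
  attr(h, "E") <- E
  h
}
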