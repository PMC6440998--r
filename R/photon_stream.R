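#' Photon stream container
#'
#' A photon stream holds the time-tagged photon record of one measurement:
#' integer arrival times in units of the laser repetition period (clock
#' ticks), the detection channel, and the excitation slot assigned by pulsed
#' interleaved excitation. Stored as a data frame with attributes, mirroring
#' the columnar layout of photon archive formats.
#'
#' @param timestamp Integer-valued clock ticks, monotone non-decreasing.
#' @param detector Integer, 0 = donor channel, 1 = acceptor channel.
#' @param excitation Integer, 0 = donor-laser slot, 1 = acceptor-laser slot.
#' @param clock_period Seconds per clock tick (default 25 ns, a 40 MHz clock).
#' @return A `photon_stream` data frame.
#' @export
photon_stream <- function(timestamp, detector, excitation,
                          clock_period = 2.5e-8) {
  stopifnot(length(detector) == length(timestamp),
            length(excitation) == length(timestamp))
  if (is.unsorted(timestamp)) stop("timestamps must be monotone non-decreasing")
  if (!all(detector %in% c(0L, 1L))) stop("detector must be 0 (donor) or 1 (acceptor)")
  if (!all(excitation %in% c(0L, 1L))) stop("excitation must be 0 (donor slot) or 1 (acceptor slot)")
  out <- data.frame(timestamp = as.numeric(timestamp),
                    detector = as.integer(detector),
                    excitation = as.integer(excitation))
  attr(out, "clock_period") <- clock_period
  class(out) <- c("photon_stream", "data.frame")
  out
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("<photon_stream> %d photons, clock period %.3g s, span %.4g s\n",
              nrow(x), attr(x, "clock_period"),
              diff(range(x$timestamp)) * attr(x, "clock_period")))
  invisible(x)
}

#' Read / write photon streams as columnar CSV
#'
#' Timestamps, detector and excitation codes go into a plain CSV; the clock
#' period is kept in a JSON sidecar (`<path>.meta.json`) so that the file pair
#' round-trips losslessly.
#'
#' @param stream A `photon_stream`.
#' @param path CSV file path.
#' @return `read_photon_stream` returns a `photon_stream`;
#'   `write_photon_stream` returns `path` invisibly.
#' @export
write_photon_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  jsonlite::write_json(list(clock_period = attr(stream, "clock_period")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  photon_stream(d$timestamp, d$detector, d$excitation,
                clock_period = meta$clock_period)
}
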