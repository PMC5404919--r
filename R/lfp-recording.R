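#' Single-channel LFP recording
#'
#' Container for a uniformly sampled extracellular field-potential trace.
#' Voltages are in microvolts and time is in seconds from
#' `start_time_s`.
#'
#' @param samples Numeric vector of voltages (µV). Must be finite.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param start_time_s Time of the first sample in seconds (default 0).
#'
#' @return An object of class `lfp_recording` with fields `samples`,
#'   `sampling_rate_hz` and `start_time_s`.
#' @export
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 200 * seq(0, 1, by = 1e-4)), 10000)
#' lfp_duration(rec)
lfp_recording <- function(samples, sampling_rate_hz, start_time_s = 0) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("samples: must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("samples: non-finite values present", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz: must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      start_time_s = as.numeric(start_time_s)
    ),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> %d samples @ %g Hz (%.3f s), start %.3f s\n",
    length(x$samples), x$sampling_rate_hz, lfp_duration(x), x$start_time_s
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec An [lfp_recording()].
#' @return Duration in seconds (`n / sampling_rate`).
#' @export
lfp_duration <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  length(rec$samples) / rec$sampling_rate_hz
}

#' Sample-aligned time axis of a recording
#'
#' @param rec An [lfp_recording()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
lfp_times <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  rec$start_time_s + (seq_along(rec$samples) - 1) / rec$sampling_rate_hz
}
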