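#' Multi-frequency oscillometry stimulus protocol
#'
#' The stimulus is a concatenation of single-frequency sinusoidal pressure
#' segments superimposed on the set intra-abdominal pressure (IAP). The
#' default schedule applies 4, 4, 8, 6 and 10 whole cycles at 0.5, 1, 2, 3
#' and 5 Hz with a peak-to-peak amplitude of 3 hPa, giving a 20-s sequence
#' sampled at 200 Hz. Cycle counts must stay within 4 to 10 so each
#' frequency contributes enough oscillations while the overall pause stays
#' short.
#'
#' @param frequencies Stimulus frequencies, Hz; strictly positive, distinct.
#' @param cycles Whole sinusoidal cycles applied per frequency; each in
#'   `[4, 10]`.
#' @param peak_to_peak Oscillation amplitude, hPa (peak-to-peak).
#' @param mean_pressure Set IAP the oscillation rides on, hPa.
#' @param sample_rate Output sampling rate, Hz; must exceed twice the
#'   highest stimulus frequency.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(mean_pressure = 12)
#' @export
stimulus_protocol <- function(frequencies = c(0.5, 1, 2, 3, 5),
                              cycles = c(4, 4, 8, 6, 10),
                              peak_to_peak = 3,
                              mean_pressure = 12,
                              sample_rate = 200) {
  check_number(frequencies, "frequencies")
  check_number(cycles, "cycles")
  check_number(peak_to_peak, "peak_to_peak")
  check_number(mean_pressure, "mean_pressure")
  check_number(sample_rate, "sample_rate")
  if (length(cycles) != length(frequencies)) {
    stop_oscillab("config", "`cycles` must have one entry per frequency.")
  }
  if (any(frequencies <= 0) || anyDuplicated(frequencies)) {
    stop_oscillab("config", "frequencies must be strictly positive and distinct.")
  }
  if (any(cycles < 4 | cycles > 10) || any(cycles != round(cycles))) {
    stop_oscillab("config", "cycle counts must be whole numbers within [4, 10].")
  }
  if (peak_to_peak < 0) stop_oscillab("config", "`peak_to_peak` must be >= 0.")
  if (sample_rate <= 2 * max(frequencies)) {
    stop_oscillab("config",
                  sprintf("sample_rate = %g Hz is at or below Nyquist for a %g Hz stimulus.",
                          sample_rate, max(frequencies)))
  }
  structure(list(frequencies = frequencies,
                 cycles = as.integer(cycles),
                 peak_to_peak = peak_to_peak,
                 mean_pressure = mean_pressure,
                 sample_rate = sample_rate),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s Hz (%s cycles), %.3g hPa p-p about %.3g hPa, %g Hz sampling, %.3g s\n",
              paste(x$frequencies, collapse = "/"), paste(x$cycles, collapse = "/"),
              x$peak_to_peak, x$mean_pressure, x$sample_rate, protocol_duration(x)))
  invisible(x)
}

#' Total stimulus duration of a protocol
#'
#' @param protocol A [stimulus_protocol()].
#' @return Duration in seconds, `sum(cycles / frequencies)`.
#' @export
protocol_duration <- function(protocol) {
  sum(protocol$cycles / protocol$frequencies)
}

# Segment bookkeeping: start time, duration and sample extent of each
# single-frequency segment at the protocol's sampling rate.
protocol_segments <- function(protocol) {
  dur <- protocol$cycles / protocol$frequencies
  start <- cumsum(c(0, utils::head(dur, -1)))
  n <- round(dur * protocol$sample_rate)
  tibble(frequency = protocol$frequencies,
         cycles = protocol$cycles,
         start_s = start,
         duration_s = dur,
         i_start = as.integer(round(start * protocol$sample_rate)) + 1L,
         n_samples = as.integer(n))
}

# Analytic pressure setpoint at arbitrary times (vectorised); each segment
# starts at zero phase. Times past the schedule hold the mean pressure.
stimulus_pressure_at <- function(protocol, t) {
  seg <- protocol_segments(protocol)
  p <- rep(protocol$mean_pressure, length(t))
  amp <- protocol$peak_to_peak / 2
  for (i in seq_len(nrow(seg))) {
    in_seg <- t >= seg$start_s[i] & t < seg$start_s[i] + seg$duration_s[i]
    if (any(in_seg)) {
      p[in_seg] <- p[in_seg] + amp * sin(2 * pi * seg$frequency[i] * (t[in_seg] - seg$start_s[i]))
    }
  }
  p
}

#' Build the pressure setpoint waveform for a stimulus protocol
#'
#' Concatenates single-frequency sinusoidal segments, each containing its
#' exact whole number of cycles and starting at zero phase, with amplitude
#' `peak_to_peak / 2` about the mean set pressure.
#'
#' @inheritParams protocol_duration
#' @return A tibble with columns `time` (s, from sequence start) and
#'   `pressure` (hPa), sampled at `protocol$sample_rate`.
#' @examples
#' w <- build_stimulus(stimulus_protocol(mean_pressure = 12))
#' range(w$pressure)
#' @export
build_stimulus <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  n <- round(protocol_duration(protocol) * protocol$sample_rate)
  t <- (seq_len(n) - 1) / protocol$sample_rate
  tibble(time = t, pressure = stimulus_pressure_at(protocol, t))
}

#' Construct an oscillometry recording
#'
#' A recording holds uniformly sampled insufflation pressure (hPa) and
#' trocar gas flow (L/s, positive into the abdomen), with the sampling rate
#' and the mean set IAP carried as attributes.
#'
#' @param time Sample times, s; must be uniform to within 1e-9 s jitter.
#' @param pressure Insufflation pressure, hPa.
#' @param flow Trocar flow, L/s.
#' @param sample_rate Sampling rate, Hz.
#' @param mean_pressure Set IAP, hPa.
#' @return A tibble of class `oscillometry_recording` with columns `time`,
#'   `pressure`, `flow`.
#' @export
new_recording <- function(time, pressure, flow, sample_rate, mean_pressure) {
  if (!(length(time) == length(pressure) && length(time) == length(flow))) {
    stop_oscillab("input", "time, pressure and flow must have equal length.")
  }
  check_number(sample_rate, "sample_rate")
  if (length(time) > 1) {
    jitter <- max(abs(diff(time) - 1 / sample_rate))
    if (jitter > 1e-9) {
      stop_oscillab("format",
                    sprintf("non-uniform sampling: max timestamp jitter %.3g s exceeds 1e-9 s.", jitter))
    }
  }
  out <- tibble(time = as.double(time), pressure = as.double(pressure), flow = as.double(flow))
  attr(out, "sample_rate") <- sample_rate
  attr(out, "mean_pressure") <- mean_pressure
  class(out) <- c("oscillometry_recording", class(out))
  out
}

#' @export
print.oscillometry_recording <- function(x, ...) {
  cat(sprintf("<oscillometry_recording> %d samples @ %g Hz, mean IAP %.3g hPa\n",
              nrow(x), attr(x, "sample_rate"), attr(x, "mean_pressure")))
  NextMethod()
}

rec_sample_rate <- function(rec) {
  sr <- attr(rec, "sample_rate")
  if (is.null(sr)) stop_oscillab("input", "recording lacks a sample_rate attribute.")
  sr
}

#' Split a recording into per-frequency segments
#'
#' Uses the known stimulus schedule to cut the recording into one slice per
#' stimulus frequency. The first cycle of each segment carries the
#' transition transient; its samples are dropped from the returned slice
#' (spectral estimation must not see it), while `duration_s` reports the
#' full scheduled segment length.
#'
#' @param rec An [new_recording()] object covering at least the protocol
#'   duration.
#' @param protocol The [stimulus_protocol()] that produced the recording.
#' @return A tibble with one row per stimulus frequency: `frequency` (Hz),
#'   `duration_s` (full segment length, s), `n_total`, `n_kept` (samples
#'   before/after transient removal) and `slice` (list column of
#'   `oscillometry_recording` objects with the first cycle removed).
#' @export
segment_recording <- function(rec, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  fs <- rec_sample_rate(rec)
  if (abs(fs - protocol$sample_rate) > 1e-9) {
    stop_oscillab("alignment",
                  sprintf("recording sampled at %g Hz but protocol expects %g Hz.", fs, protocol$sample_rate))
  }
  seg <- protocol_segments(protocol)
  n_needed <- seg$i_start[nrow(seg)] + seg$n_samples[nrow(seg)] - 1L
  if (nrow(rec) < n_needed) {
    stop_oscillab("alignment",
                  sprintf("recording has %d samples but the schedule needs %d (%.3g s).",
                          nrow(rec), n_needed, protocol_duration(protocol)))
  }
  mp <- attr(rec, "mean_pressure")
  slices <- purrr::pmap(seg, function(frequency, cycles, start_s, duration_s, i_start, n_samples) {
    idx <- seq.int(i_start, i_start + n_samples - 1L)
    n_transient <- as.integer(round(fs / frequency))  # first cycle
    keep <- idx[-seq_len(min(n_transient, length(idx)))]
    new_recording(rec$time[keep], rec$pressure[keep], rec$flow[keep],
                  sample_rate = fs, mean_pressure = mp)
  })
  tibble(frequency = seg$frequency,
         duration_s = seg$duration_s,
         n_total = seg$n_samples,
         n_kept = purrr::map_int(slices, nrow),
         slice = slices)
}
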