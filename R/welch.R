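#' Welch cross-spectral impedance estimate at one stimulus frequency
#'
#' Estimates the abdominal input impedance \eqn{Z = P(f)/Q(f)} from a
#' single-frequency slice of a recording by Welch periodogram averaging:
#' Hamming-tapered windows of exactly two stimulus periods
#' (`round(2 * sample_rate / f)` samples) with 50% overlap, per-window mean
#' removal, auto- and cross-spectra averaged across windows, and the H1
#' estimator (cross-spectrum of flow onto pressure over the flow
#' auto-spectrum) read at the window's bin 2 — the bin the two-period
#' window places the stimulus on. The magnitude-squared coherence
#' \eqn{|S_{qp}|^2 / (S_{pp} S_{qq})} quantifies how linearly flow follows
#' pressure; it is clipped to `[0, 1]`.
#'
#' With only two analysis windows (the shortest segments) the coherence
#' estimate averages very little; such estimates carry
#' `low_averaging = TRUE`.
#'
#' @param slice An `oscillometry_recording` covering one stimulus
#'   frequency, transient already removed (see [segment_recording()]).
#' @param f Stimulus frequency, Hz.
#' @return A one-row tibble: `frequency`, `impedance` (complex, hPa·s/L),
#'   `resistance`, `reactance`, `coherence`, `n_windows`, `low_averaging`.
#' @examples
#' fs <- 200; t <- seq(0, 6 - 1/fs, by = 1/fs)
#' rec <- new_recording(t, 12 + 1.5 * sin(2*pi*t), 0.3 * sin(2*pi*t), fs, 12)
#' estimate_impedance(rec, 1)
#' @export
estimate_impedance <- function(slice, f) {
  check_number(f, "f")
  fs <- rec_sample_rate(slice)
  L <- as.integer(round(2 * fs / f))
  hop <- L %/% 2L
  n <- nrow(slice)
  n_win <- if (n < L) 0L else (n - L) %/% hop + 1L
  if (n_win < 2L) {
    stop_oscillab("insufficient_data",
                  sprintf("slice at %g Hz supports %d analysis window(s); need at least 2 windows of %.3g s.",
                          f, n_win, L / fs))
  }
  w <- hamming_window(L)
  bin <- 3L  # DFT bin index 2 (0-based): two cycles per window
  spp <- sqq <- 0
  sqp <- 0 + 0i
  for (k in seq_len(n_win)) {
    idx <- seq.int((k - 1L) * hop + 1L, length.out = L)
    pw <- slice$pressure[idx]; qw <- slice$flow[idx]
    pw <- (pw - mean(pw)) * w
    qw <- (qw - mean(qw)) * w
    P <- fft(pw)[bin]
    Q <- fft(qw)[bin]
    spp <- spp + Mod(P)^2
    sqq <- sqq + Mod(Q)^2
    sqp <- sqp + P * Conj(Q)
  }
  # degenerate if the flow bin carries essentially no power
  if (sqq <= 1e-24 || (spp > 0 && sqq / spp < 1e-18)) {
    stop_oscillab("degenerate",
                  sprintf("no flow power at %g Hz; cannot form an impedance estimate.", f))
  }
  z <- sqp / sqq
  coh <- Mod(sqp)^2 / (spp * sqq)
  coh <- min(max(coh, 0), 1)
  tibble(frequency = f,
         impedance = z,
         resistance = Re(z),
         reactance = Im(z),
         coherence = coh,
         n_windows = n_win,
         low_averaging = n_win <= 2L)
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Impedance spectrum of a full oscillometry recording
#'
#' Applies [segment_recording()] and then [estimate_impedance()] at each
#' stimulus frequency, yielding the five-point (by default) abdominal
#' impedance curve with per-point coherence.
#'
#' @inheritParams segment_recording
#' @return A tibble of class `impedance_spectrum`, one row per stimulus
#'   frequency, with the columns of [estimate_impedance()]. The protocol's
#'   mean pressure and sample rate are carried as attributes.
#' @export
impedance_spectrum <- function(rec, protocol) {
  segs <- segment_recording(rec, protocol)
  rows <- purrr::map2(segs$slice, segs$frequency, function(s, f) {
    tryCatch(estimate_impedance(s, f),
             oscillab_error = function(e) {
               stop_oscillab("degenerate",
                             sprintf("at %g Hz: %s", f, conditionMessage(e)),
                             parent = e)
             })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_pressure") <- attr(rec, "mean_pressure")
  attr(out, "sample_rate") <- rec_sample_rate(rec)
  class(out) <- c("impedance_spectrum", class(out))
  out
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("<impedance_spectrum> %d frequencies, mean IAP %.3g hPa\n",
              nrow(x), attr(x, "mean_pressure") %||% NA_real_))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
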