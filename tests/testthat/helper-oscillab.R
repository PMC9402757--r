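# Shared fixtures, built in code.

default_protocol <- function(mean_pressure = 12) {
  stimulus_protocol(mean_pressure = mean_pressure)
}

# A single-frequency recording with analytic pressure/flow channels.
make_sine_recording <- function(f, dur_s, p_amp = 1.5, q_amp = 0.3,
                                q_phase = 0, fs = 200, mean_pressure = 12) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  new_recording(t,
                mean_pressure + p_amp * sin(2 * pi * f * t),
                q_amp * sin(2 * pi * f * t + q_phase),
                sample_rate = fs, mean_pressure = mean_pressure)
}

# Independent single-bin DFT ratio oracle: direct complex projection onto
# the stimulus frequency over an exact whole number of cycles. Shares no
# code with the Welch estimator.
dft_ratio_oracle <- function(rec, f) {
  fs <- attr(rec, "sample_rate")
  n_cycle <- round(fs / f)
  n <- (nrow(rec) %/% n_cycle) * n_cycle
  k <- n / n_cycle                      # whole cycles in the truncated slice
  ph <- exp(-2i * pi * k * (0:(n - 1)) / n)
  p <- rec$pressure[1:n] - mean(rec$pressure[1:n])
  q <- rec$flow[1:n] - mean(rec$flow[1:n])
  sum(p * ph) / sum(q * ph)
}

# Per-subject model evaluation over a cohort parameter table.
static_compliance_by_row <- function(tab, p) {
  vapply(seq_len(nrow(tab)), function(i) {
    static_compliance(pv_params(tab$p0[i], tab$iav_max[i], tab$lam[i]), p)
  }, numeric(1))
}

predict_iav_by_row <- function(tab, p) {
  vapply(seq_len(nrow(tab)), function(i) {
    predict_iav(pv_params(tab$p0[i], tab$iav_max[i], tab$lam[i]), p)
  }, numeric(1))
}

# Simulate a linear RLC abdomen recording (the stated noisy-study model).
simulate_linear_rlc <- function(seed, noise = 0.02, mean_pressure = 12,
                                r = 5, l = 0.2, c = 0.1) {
  model <- abdomen_model(c_lin = c, r_tissue_circuit = r, l_gas = l,
                         noise_sd_frac = noise)
  simulate_recording(model, default_protocol(mean_pressure), seed = seed)
}
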