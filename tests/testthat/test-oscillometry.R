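test_that("the default stimulus honours the protocol contract", {
  proto <- default_protocol()
  expect_equal(protocol_duration(proto), 20)
  w <- build_stimulus(proto)
  expect_equal(nrow(w), 4000L)
  # peak-to-peak is exactly 3 hPa within every segment
  seg <- segment_recording(
    new_recording(w$time, w$pressure, rep(0.1, nrow(w)) + sin(w$time),
                  sample_rate = 200, mean_pressure = 12), proto)
  bounds <- cumsum(c(0, proto$cycles / proto$frequencies))
  for (i in seq_along(proto$frequencies)) {
    inseg <- w$pressure[w$time >= bounds[i] & w$time < bounds[i + 1]]
    expect_equal(max(inseg) - min(inseg), 3, tolerance = 1e-9)
  }
  # each segment starts at zero phase, i.e. at the mean pressure
  starts <- round(bounds[-length(bounds)] * 200) + 1
  expect_equal(w$pressure[starts], rep(12, 5))
})

test_that("zero amplitude gives a constant setpoint", {
  proto <- stimulus_protocol(peak_to_peak = 0, mean_pressure = 10)
  w <- build_stimulus(proto)
  expect_equal(unique(w$pressure), 10)
})

test_that("protocol validation rejects bad configurations", {
  expect_error(stimulus_protocol(sample_rate = 8), class = "oscillab_error_config")
  expect_error(stimulus_protocol(cycles = c(4, 4, 8, 6, 12)), class = "oscillab_error_config")
  expect_error(stimulus_protocol(cycles = c(4, 4, 8, 6, 3)), class = "oscillab_error_config")
  expect_error(stimulus_protocol(frequencies = c(0.5, 0.5, 2, 3, 5)), class = "oscillab_error_config")
})

test_that("segment_recording cuts the known schedule and drops the transient cycle", {
  proto <- default_protocol()
  w <- build_stimulus(proto)
  rec <- new_recording(w$time, w$pressure, 0.1 * sin(w$time), 200, 12)
  seg <- segment_recording(rec, proto)
  expect_equal(seg$frequency, c(0.5, 1, 2, 3, 5))
  expect_equal(seg$duration_s, c(8, 4, 4, 2, 2))
  # the 0.5 Hz segment keeps 3 of its 4 cycles
  expect_equal(seg$n_kept[1], 3 * 400L)
  expect_equal(seg$n_total[1], 4 * 400L)
  # truncated recording cannot be aligned
  short <- new_recording(w$time[1:3000], w$pressure[1:3000], rep(0, 3000), 200, 12)
  expect_error(segment_recording(short, proto), class = "oscillab_error_alignment")
})

test_that("estimate_impedance recovers pure resistance and pure compliance", {
  rec_r <- make_sine_recording(1, 6, p_amp = 1.5, q_amp = 0.3)
  z <- estimate_impedance(rec_r, 1)
  expect_equal(z$resistance, 5, tolerance = 1e-6)
  expect_equal(z$reactance, 0, tolerance = 1e-6)
  expect_equal(z$coherence, 1, tolerance = 1e-6)
  # flow leads pressure by 90 degrees: a pure compliance of 0.1 L/hPa
  rec_c <- make_sine_recording(1, 6, p_amp = 1.5, q_amp = 1.5 * 2 * pi * 0.1,
                               q_phase = pi / 2)
  zc <- estimate_impedance(rec_c, 1)
  expect_equal(Re(zc$impedance), 0, tolerance = 1e-4)
  expect_equal(Im(zc$impedance), -1.5915, tolerance = 1e-3)
})

test_that("estimate_impedance stays within 2% under 2% channel noise", {
  z_true <- complex(real = 5, imaginary = 0)
  for (seed in 1:20) {
    set.seed(seed)
    rec <- make_sine_recording(1, 6, p_amp = 1.5, q_amp = 0.3)
    rec$pressure <- rec$pressure + rnorm(nrow(rec), 0, 0.02 * 1.5)
    rec$flow <- rec$flow + rnorm(nrow(rec), 0, 0.02 * 0.3)
    z <- estimate_impedance(rec, 1)
    expect_lt(Mod(z$impedance - z_true) / Mod(z_true), 0.02)
    expect_gt(z$coherence, 0.96)
  }
})

test_that("estimate_impedance guards window count and degenerate flow", {
  short <- make_sine_recording(0.5, 3)     # < 2 windows of 4 s
  expect_error(estimate_impedance(short, 0.5), class = "oscillab_error_insufficient_data")
  dead <- make_sine_recording(1, 6, q_amp = 0)
  expect_error(estimate_impedance(dead, 1), class = "oscillab_error_degenerate")
})

test_that("the Welch estimator agrees with the single-bin DFT oracle", {
  set.seed(99)
  for (i in 1:15) {
    f <- sample(c(0.5, 1, 2, 3, 5), 1)
    p_amp <- runif(1, 0.5, 2)
    q_amp <- runif(1, 0.1, 1)
    ph <- runif(1, -pi, pi)
    rec <- make_sine_recording(f, max(6 / f, 2), p_amp = p_amp, q_amp = q_amp,
                               q_phase = ph)
    z <- estimate_impedance(rec, f)$impedance
    z0 <- dft_ratio_oracle(rec, f)
    expect_lt(abs(Mod(z) / Mod(z0) - 1), 0.005)
    expect_lt(abs(Arg(z) - Arg(z0)) * 180 / pi, 0.5)
  }
})

test_that("coherence is 1 for noiseless linear responses and decreases with noise", {
  proto <- default_protocol()
  model <- abdomen_model(c_lin = 0.1, noise_sd_frac = 0)
  rec0 <- simulate_recording(model, proto)
  spec0 <- impedance_spectrum(rec0, proto)
  expect_true(all(spec0$coherence > 1 - 1e-6))
  noise_levels <- c(0.02, 0.1, 0.3)
  meanc <- vapply(noise_levels, function(ns) {
    m <- abdomen_model(c_lin = 0.1, noise_sd_frac = ns)
    rec <- simulate_recording(m, proto, seed = 5)
    mean(impedance_spectrum(rec, proto)$coherence)
  }, numeric(1))
  expect_true(all(diff(meanc) < 0))
})

test_that("impedance_spectrum matches the closed-form RLC curve within 1%", {
  proto <- default_protocol()
  model <- abdomen_model(c_lin = 0.1, r_tissue_circuit = 5, l_gas = 0.2,
                         noise_sd_frac = 0)
  spec <- impedance_spectrum(simulate_recording(model, proto), proto)
  z_true <- complex(real = 5,
                    imaginary = 2 * pi * spec$frequency * 0.2 -
                      1 / (2 * pi * spec$frequency * 0.1))
  expect_true(all(Mod(spec$impedance - z_true) / Mod(z_true) < 0.01))
})

test_that("a dead flow channel is reported as degenerate at every frequency", {
  proto <- default_protocol()
  w <- build_stimulus(proto)
  rec <- new_recording(w$time, w$pressure, rep(0, nrow(w)), 200, 12)
  expect_error(impedance_spectrum(rec, proto), class = "oscillab_error_degenerate")
})

test_that("impedance is scale equivariant", {
  rec <- make_sine_recording(1, 6, p_amp = 1.5, q_amp = 0.3, q_phase = 0.3)
  z <- estimate_impedance(rec, 1)$impedance
  both <- rec; both$pressure <- 12 + 2 * (both$pressure - 12); both$flow <- 2 * both$flow
  expect_equal(estimate_impedance(both, 1)$impedance, z, tolerance = 1e-9)
  qonly <- rec; qonly$flow <- 2 * qonly$flow
  expect_equal(estimate_impedance(qonly, 1)$impedance, z / 2, tolerance = 1e-9)
})

test_that("fit_rlc is an exact-recovery map on noiseless spectra", {
  f <- c(0.5, 1, 2, 3, 5)
  set.seed(17)
  for (i in 1:100) {
    # physiological regime: the lowest frequency must see a net-negative
    # reactance or the compliance is unidentifiable from this band
    r <- runif(1, 2, 10); l <- runif(1, 0.05, 0.3); cc <- runif(1, 0.02, 0.3)
    z <- complex(real = r, imaginary = 2 * pi * f * l - 1 / (2 * pi * f * cc))
    fit <- fit_rlc(tibble::tibble(frequency = f, impedance = z, coherence = 1))
    expect_lt(abs(fit$r / r - 1), 1e-3)
    expect_lt(abs(fit$l / l - 1), 1e-3)
    expect_lt(abs(fit$c / cc - 1), 1e-3)
    expect_lt(fit$rmse, 1e-6)
  }
})

test_that("fit_rlc survives 2% multiplicative noise with small median error", {
  f <- c(0.5, 1, 2, 3, 5)
  z0 <- complex(real = 5, imaginary = 2 * pi * f * 0.2 - 1 / (2 * pi * f * 0.1))
  set.seed(202)
  err <- replicate(100, {
    z <- z0 * (1 + rnorm(5, 0, 0.02))
    fit <- fit_rlc(tibble::tibble(frequency = f, impedance = z, coherence = 1))
    c(abs(fit$r / 5 - 1), abs(fit$l / 0.2 - 1), abs(fit$c / 0.1 - 1))
  })
  expect_true(all(apply(err, 1, median) < 0.05))
})

test_that("fit_rlc enforces minimum data and flags non-compliant spectra", {
  f <- c(0.5, 1)
  z <- complex(real = c(5, 5), imaginary = c(-2, -1))
  expect_error(fit_rlc(tibble::tibble(frequency = f, impedance = z)),
               class = "oscillab_error_insufficient_data")
  # all-positive reactance: no compliant behaviour to identify
  f5 <- c(0.5, 1, 2, 3, 5)
  zp <- complex(real = 5, imaginary = 2 * pi * f5 * 0.2)
  fitp <- fit_rlc(tibble::tibble(frequency = f5, impedance = zp, coherence = 1))
  expect_true(fitp$low_confidence)
})

test_that("fit_rlc excludes low-coherence points before fitting", {
  f <- c(0.5, 1, 2, 3, 5)
  z <- complex(real = 5, imaginary = 2 * pi * f * 0.2 - 1 / (2 * pi * f * 0.1))
  z[2] <- z[2] + 40     # corrupted point, flagged by its coherence
  spec <- tibble::tibble(frequency = f, impedance = z,
                         coherence = c(1, 0.5, 1, 1, 1))
  fit <- fit_rlc(spec)
  expect_equal(fit$excluded, 1)
  expect_equal(fit$c, 0.1, tolerance = 1e-3)
  # with QC off the corrupted point drags the fit
  fit_raw <- fit_rlc(spec, coherence_min = NULL)
  expect_gt(fit_raw$rmse, 1)
})

test_that("dynamic_compliance projects the fitted capacitance", {
  f <- c(0.5, 1, 2, 3, 5)
  z <- complex(real = 5, imaginary = 2 * pi * f * 0.2 - 1 / (2 * pi * f * 0.1))
  fit <- fit_rlc(tibble::tibble(frequency = f, impedance = z, coherence = 1))
  expect_equal(dynamic_compliance(fit), fit$c)
  expect_equal(dynamic_compliance(fit), 0.1, tolerance = 1e-3)
})
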