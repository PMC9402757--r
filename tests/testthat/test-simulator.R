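test_that("a purely elastic abdomen reproduces the closed-form flow amplitude", {
  proto <- stimulus_protocol(frequencies = c(0.5, 1), cycles = c(4, 4),
                             peak_to_peak = 3, mean_pressure = 12)
  model <- abdomen_model(c_lin = 0.1, r_tissue_circuit = 0, l_gas = 0,
                         noise_sd_frac = 0)
  rec <- simulate_recording(model, proto)
  seg <- segment_recording(rec, proto)
  # q = C * dp/dt -> amplitude C * 2*pi*f * A with A = 1.5 hPa
  expect_equal(max(abs(seg$slice[[2]]$flow)), 0.1 * 2 * pi * 1 * 1.5,
               tolerance = 1e-6)
})

test_that("zero stimulus leaves no oscillatory flow", {
  proto <- stimulus_protocol(peak_to_peak = 0, mean_pressure = 12)
  model <- abdomen_model(pv = pv_params(2, 3.84, 0.12), noise_sd_frac = 0)
  rec <- simulate_recording(model, proto)
  expect_lt(max(abs(rec$flow)), 1e-6)
})

test_that("identical seeds give bit-identical recordings", {
  proto <- default_protocol()
  model <- abdomen_model(c_lin = 0.1)
  r1 <- simulate_recording(model, proto, seed = 9)
  r2 <- simulate_recording(model, proto, seed = 9)
  expect_identical(r1$pressure, r2$pressure)
  expect_identical(r1$flow, r2$flow)
  r3 <- simulate_recording(model, proto, seed = 10)
  expect_false(identical(r1$flow, r3$flow))
})

test_that("the full pipeline recovers the model parameters in the linear limit", {
  proto <- default_protocol()
  pv <- pv_params(2, 3.84, 0.12)
  model <- abdomen_model(pv = pv, r_tissue_circuit = 5, l_gas = 0.2,
                         noise_sd_frac = 0)
  fit <- fit_rlc(impedance_spectrum(simulate_recording(model, proto), proto))
  expect_equal(fit$r, 5, tolerance = 0.02)
  expect_equal(fit$l, 0.2, tolerance = 0.05)
  expect_equal(fit$c, static_compliance(pv, 12), tolerance = 0.05)
})

test_that("integrated flow balances the stored volume", {
  proto <- default_protocol()
  model <- abdomen_model(pv = pv_params(2, 3.84, 0.12), viscoelastic = TRUE,
                         noise_sd_frac = 0)
  rec <- simulate_recording(model, proto, return_state = TRUE)
  st <- attr(rec, "state")
  h <- st$time[2] - st$time[1]
  vol_from_flow <- st$volume[1] + c(0, cumsum((st$flow[-1] + st$flow[-nrow(st)]) / 2 * h))
  expect_lt(max(abs(vol_from_flow - st$volume)), 1e-6)
})

test_that("halving the integration step barely changes the output", {
  proto <- stimulus_protocol(frequencies = c(1, 2), cycles = c(4, 8),
                             mean_pressure = 12)
  model <- abdomen_model(pv = pv_params(2, 3.84, 0.12), viscoelastic = TRUE,
                         noise_sd_frac = 0)
  r1 <- simulate_recording(model, proto, internal_rate = 1000)
  r2 <- simulate_recording(model, proto, internal_rate = 2000)
  scale <- max(abs(r1$flow))
  expect_lt(max(abs(r1$flow - r2$flow)) / scale, 1e-6)
  expect_lt(max(abs(r1$pressure - r2$pressure)), 1e-9)
})

test_that("unstable configurations raise a simulation error", {
  proto <- default_protocol(mean_pressure = 12)
  model <- abdomen_model(pv = pv_params(11.9, 0.5, 1.9), r_tissue_circuit = 1e-6,
                         l_gas = 1e-6, noise_sd_frac = 0)
  expect_error(simulate_recording(model, proto), class = "oscillab_error_simulation")
  low <- abdomen_model(pv = pv_params(13, 3.84, 0.12), noise_sd_frac = 0)
  expect_error(simulate_recording(low, proto), class = "oscillab_error_simulation")
})

test_that("ventilator interference degrades coherence at the nearest frequency", {
  proto <- default_protocol()
  model <- abdomen_model(c_lin = 0.1, noise_sd_frac = 0.02)
  rec <- simulate_recording(model, proto, seed = 3)
  clean <- impedance_spectrum(rec, proto)
  noisy <- impedance_spectrum(
    inject_artifact(rec, "ventilator_interference",
                    params = list(frequency = 0.25, amplitude = 1)), proto)
  expect_lt(noisy$coherence[noisy$frequency == 0.5],
            clean$coherence[clean$frequency == 0.5])
  # zero-amplitude interference is the identity
  same <- inject_artifact(rec, "ventilator_interference", params = list(amplitude = 0))
  expect_identical(same$pressure, rec$pressure)
})

test_that("tube occlusion yields a degenerate or low-coherence estimate", {
  proto <- default_protocol()
  model <- abdomen_model(c_lin = 0.1, noise_sd_frac = 0.02)
  rec <- simulate_recording(model, proto, seed = 4)
  # occlude the whole 1 Hz segment (8 s to 12 s in the schedule)
  occ <- inject_artifact(rec, "tube_occlusion",
                         params = list(start_s = 8, duration_s = 4))
  seg <- segment_recording(occ, proto)
  got <- tryCatch(estimate_impedance(seg$slice[[2]], 1)$coherence,
                  oscillab_error = function(e) 0)
  expect_lt(got, 0.9)
  expect_error(inject_artifact(rec, "dropout"), class = "oscillab_error_input")
})

test_that("simulate_study produces the full crossed design deterministically", {
  design <- study_design(n_subjects = 2, pressures = c(5, 10, 15, 20), seed = 21)
  ds1 <- simulate_study(design)
  expect_equal(nrow(ds1$recordings), 8L)
  expect_equal(nrow(ds1$volumes), 8L)
  expect_equal(nrow(ds1$subjects), 2L)
  # volumes strictly increasing within each subject
  ok <- ds1$volumes |>
    dplyr::summarise(mono = !is.unsorted(volume, strictly = TRUE), .by = subject)
  expect_true(all(ok$mono))
  # parameters inside the sampling ranges
  expect_true(all(ds1$subjects$p0 >= 1.1 & ds1$subjects$p0 <= 2.5))
  expect_true(all(ds1$subjects$iav_max >= 2.79 & ds1$subjects$iav_max <= 4.61))
  expect_true(all(ds1$subjects$lam >= 0.10 & ds1$subjects$lam <= 0.15))
  ds2 <- simulate_study(design)
  expect_identical(ds1$volumes, ds2$volumes)
  expect_identical(ds1$recordings$recording[[3]]$flow,
                   ds2$recordings$recording[[3]]$flow)
})

test_that("dynamic compliance decreases monotonically along a staircase", {
  design <- study_design(n_subjects = 1, seed = 8)
  ds <- simulate_study(design)
  res <- analyze_study(ds)
  cd <- res$rlc$c_dyn[order(res$rlc$pressure)]
  expect_true(all(diff(cd) < 0))
})

test_that("the make-up flow stub offsets flow without touching impedance", {
  proto <- stimulus_protocol(frequencies = c(1, 2), cycles = c(4, 8))
  m0 <- abdomen_model(c_lin = 0.1, noise_sd_frac = 0)
  md <- abdomen_model(c_lin = 0.1, noise_sd_frac = 0, drift_Lps = 0.05)
  r0 <- simulate_recording(m0, proto)
  rd <- simulate_recording(md, proto)
  expect_equal(rd$flow - r0$flow, rep(0.05, nrow(r0)))
  z0 <- impedance_spectrum(r0, proto)$impedance
  zd <- impedance_spectrum(rd, proto)$impedance
  expect_equal(zd, z0, tolerance = 1e-9)
})

test_that("study_design validates its inputs", {
  expect_error(study_design(n_subjects = 0), class = "oscillab_error_config")
  expect_error(study_design(pressures = c(10, 5)), class = "oscillab_error_config")
  expect_error(study_design(ranges = list(p0 = c(2, 1), iav_max = c(3, 4), lam = c(0.1, 0.2))),
               class = "oscillab_error_config")
})
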