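#' Lumped-parameter virtual abdomen
#'
#' A forward model of the insufflated abdomen seen from the trocar: a
#' series resistance `r_tissue_circuit` (tissue deformation losses plus the
#' insufflation circuit), a gas inertance `l_gas`, a nonlinear elastic
#' compartment whose recoil pressure is the inverse of the exponential
#' pressure-volume curve (or a constant compliance `c_lin` for a linearised
#' abdomen), and optionally a Kelvin viscoelastic element (spring `c_ve`
#' parallel to dashpot `r_ve`) in series. The Kelvin element makes the
#' apparent compliance frequency dependent, so dynamic compliance recovered
#' by oscillometry falls below the static compliance — the behaviour seen
#' in real tissue.
#'
#' @param pv A [pv_params()] object (nonlinear elastic recoil). Exactly one
#'   of `pv` and `c_lin` must be given.
#' @param c_lin Constant compliance, L/hPa, for a linearised abdomen.
#' @param r_tissue_circuit Series resistance, hPa·s/L. Default 5.
#' @param l_gas Gas inertance, hPa·s²/L. Default 0.2.
#' @param viscoelastic `FALSE`/`NULL` for none, `TRUE` for the default
#'   Kelvin element (`c_ve` = 2 x the local static compliance at the set
#'   IAP, `r_ve` = 3 hPa·s/L), or a list with elements `c_ve` (L/hPa) and
#'   `r_ve` (hPa·s/L).
#' @param noise_sd_frac Additive Gaussian sensor noise, standard deviation
#'   as a fraction of each channel's oscillation amplitude. Default 0.02.
#' @param drift_Lps Constant make-up flow, L/s, standing in for CO2
#'   absorption/leak: the insufflator replaces lost gas, so the flow
#'   channel carries this offset. A deliberate stub, off (0) by default;
#'   no absorption kinetics are modelled.
#' @return An object of class `abdomen_model`.
#' @examples
#' abdomen_model(pv = pv_params(2, 3.84, 0.12))
#' @export
abdomen_model <- function(pv = NULL, c_lin = NULL,
                          r_tissue_circuit = 5, l_gas = 0.2,
                          viscoelastic = FALSE, noise_sd_frac = 0.02,
                          drift_Lps = 0) {
  if (is.null(pv) == is.null(c_lin)) {
    stop_oscillab("config", "give exactly one of `pv` and `c_lin`.")
  }
  if (!is.null(pv)) pv <- as_pv_params(pv)
  if (!is.null(c_lin)) {
    check_number(c_lin, "c_lin")
    if (c_lin <= 0) stop_oscillab("config", "`c_lin` must be > 0.")
  }
  check_number(r_tissue_circuit, "r_tissue_circuit")
  check_number(l_gas, "l_gas")
  check_number(noise_sd_frac, "noise_sd_frac")
  if (r_tissue_circuit < 0 || l_gas < 0) {
    stop_oscillab("config", "`r_tissue_circuit` and `l_gas` must be >= 0.")
  }
  if (noise_sd_frac < 0) stop_oscillab("config", "`noise_sd_frac` must be >= 0.")
  if (is.list(viscoelastic)) {
    if (!all(c("c_ve", "r_ve") %in% names(viscoelastic)) ||
        viscoelastic$c_ve <= 0 || viscoelastic$r_ve <= 0) {
      stop_oscillab("config", "`viscoelastic` needs positive `c_ve` and `r_ve`.")
    }
  } else if (!isTRUE(viscoelastic) && !isFALSE(viscoelastic) && !is.null(viscoelastic)) {
    stop_oscillab("config", "`viscoelastic` must be FALSE, TRUE or a list(c_ve=, r_ve=).")
  }
  check_number(drift_Lps, "drift_Lps")
  structure(list(pv = pv, c_lin = c_lin,
                 r_tissue_circuit = r_tissue_circuit, l_gas = l_gas,
                 viscoelastic = viscoelastic %||% FALSE,
                 noise_sd_frac = noise_sd_frac,
                 drift_Lps = drift_Lps),
            class = "abdomen_model")
}

#' @export
print.abdomen_model <- function(x, ...) {
  el <- if (!is.null(x$pv)) {
    sprintf("exponential PV (p0 %.3g, iav_max %.3g, lam %.3g)", x$pv$p0, x$pv$iav_max, x$pv$lam)
  } else sprintf("linear C = %.3g L/hPa", x$c_lin)
  ve <- if (isFALSE(x$viscoelastic)) "off" else if (isTRUE(x$viscoelastic)) "default Kelvin" else
    sprintf("Kelvin c_ve %.3g, r_ve %.3g", x$viscoelastic$c_ve, x$viscoelastic$r_ve)
  cat(sprintf("<abdomen_model> %s; R = %.3g, L = %.3g; viscoelastic %s; noise %.3g\n",
              el, x$r_tissue_circuit, x$l_gas, ve, x$noise_sd_frac))
  invisible(x)
}

# Resolve the Kelvin element at a given working pressure.
resolve_viscoelastic <- function(model, mean_pressure) {
  v <- model$viscoelastic
  if (isFALSE(v)) return(NULL)
  if (is.list(v)) return(v)
  c_loc <- if (!is.null(model$pv)) static_compliance(model$pv, mean_pressure) else model$c_lin
  list(c_ve = 2 * c_loc, r_ve = 3)
}

# Analytic time derivative of the stimulus setpoint.
stimulus_dpressure_at <- function(protocol, t) {
  seg <- protocol_segments(protocol)
  dp <- rep(0, length(t))
  amp <- protocol$peak_to_peak / 2
  for (i in seq_len(nrow(seg))) {
    in_seg <- t >= seg$start_s[i] & t < seg$start_s[i] + seg$duration_s[i]
    if (any(in_seg)) {
      wi <- 2 * pi * seg$frequency[i]
      dp[in_seg] <- amp * wi * cos(wi * (t[in_seg] - seg$start_s[i]))
    }
  }
  dp
}

#' Simulate an endoscopic oscillometry recording
#'
#' Integrates the virtual abdomen under an ideally applied pressure
#' setpoint \eqn{p_{app}(t)} (the stimulus about the set IAP):
#' \deqn{p_{app} = R q + L \dot q + p_{el}(V) + p_{ve}, \qquad q = \dot V,}
#' with \eqn{p_{el}} the elastic recoil (inverse pressure-volume curve) and
#' the Kelvin element obeying
#' \eqn{\dot p_{ve} = q/c_{ve} - p_{ve}/(r_{ve} c_{ve})} when enabled.
#' Fixed-step 4th-order Runge-Kutta at `internal_rate` (default 1 kHz,
#' mirroring the insufflator's control rate), decimated to the protocol's
#' sampling rate. A 2-s settling run at constant mean pressure precedes the
#' stimulus and is discarded. Additive Gaussian sensor noise (sd =
#' `noise_sd_frac` x each channel's oscillation amplitude) is applied after
#' integration. The same seed always yields the identical recording.
#'
#' When both `r_tissue_circuit` and `l_gas` are zero (a purely elastic
#' abdomen) the applied pressure acts directly on the elastic element and
#' flow follows analytically; the viscoelastic element then has no
#' well-posed state equation and is rejected.
#'
#' @param model An [abdomen_model()].
#' @param protocol A [stimulus_protocol()] (its `mean_pressure` is the set
#'   IAP).
#' @param seed Integer seed for the sensor noise; `NULL` leaves the RNG
#'   state alone.
#' @param internal_rate Internal integration rate, Hz; must be a multiple
#'   of the protocol sample rate. Default 1000.
#' @param settle_s Settling run length, s. Default 2.
#' @param return_state If `TRUE`, attach the noiseless internal-rate state
#'   trajectory (time, volume, flow, p_ve, pressure) as attribute
#'   `"state"`.
#' @return An `oscillometry_recording` (see [new_recording()]).
#' @export
simulate_recording <- function(model, protocol, seed = NULL,
                               internal_rate = 1000, settle_s = 2,
                               return_state = FALSE) {
  stopifnot(inherits(model, "abdomen_model"), inherits(protocol, "stimulus_protocol"))
  fs <- protocol$sample_rate
  if (abs(internal_rate / fs - round(internal_rate / fs)) > 1e-12 || internal_rate < fs) {
    stop_oscillab("config", "`internal_rate` must be an integer multiple of the protocol sample rate.")
  }
  mp <- protocol$mean_pressure
  ve <- resolve_viscoelastic(model, mp)
  r <- model$r_tissue_circuit; l <- model$l_gas
  pure_elastic <- (r == 0 && l == 0)
  if (pure_elastic && !is.null(ve)) {
    stop_oscillab("simulation",
                  "viscoelastic element requires r_tissue_circuit or l_gas > 0 (no state equation otherwise).")
  }

  # local elastic recoil p_el(V) and its inverse, without per-call validation
  if (!is.null(model$pv)) {
    p0 <- model$pv$p0; ivm <- model$pv$iav_max; lam <- model$pv$lam
    if (mp <= p0) {
      stop_oscillab("simulation",
                    sprintf("mean_pressure %.3g hPa is at or below the model baseline p0 = %.3g hPa.", mp, p0))
    }
    pel <- function(V) p0 - log(1 - V / ivm) / lam
    v_of_p <- function(p) ivm - ivm * exp(-lam * (p - p0))
    c_of_p <- function(p) lam * ivm * exp(-lam * (p - p0))
    v_cap <- ivm
  } else {
    cl <- model$c_lin
    pel <- function(V) V / cl
    v_of_p <- function(p) cl * p
    c_of_p <- function(p) rep(cl, length(p))
    v_cap <- Inf
  }

  h <- 1 / internal_rate
  dur <- protocol_duration(protocol)
  n_settle <- round(settle_s * internal_rate)
  n_stim <- round(dur * internal_rate)
  n_tot <- n_settle + n_stim
  t_int <- (seq_len(n_tot + 1L) - 1L) * h - settle_s   # t = 0 is stimulus start

  # scalar setpoint lookup kept free of data-frame machinery: the integrator
  # evaluates it four times per step
  seg_dur <- protocol$cycles / protocol$frequencies
  seg_start <- cumsum(c(0, seg_dur))                   # length n_seg + 1
  seg_f <- protocol$frequencies
  n_seg <- length(seg_f)
  amp <- protocol$peak_to_peak / 2
  p_app_scalar <- function(t) {
    if (t < 0 || t >= seg_start[n_seg + 1L]) return(mp)
    i <- findInterval(t, seg_start)
    mp + amp * sin(2 * pi * seg_f[i] * (t - seg_start[i]))
  }
  p_app_at <- function(t) {
    out <- rep(mp, length(t))
    pos <- t >= 0
    if (any(pos)) out[pos] <- stimulus_pressure_at(protocol, t[pos])
    out
  }

  if (pure_elastic) {
    # flow is the chain rule: q = C(p) dp/dt, both factors analytic
    p_tr <- p_app_at(t_int)
    dp_tr <- ifelse(t_int >= 0, stimulus_dpressure_at(protocol, pmax(t_int, 0)), 0)
    v_tr <- v_of_p(p_tr)
    q_tr <- c_of_p(p_tr) * dp_tr
    pve_tr <- rep(0, length(t_int))
  } else {
    # state: V, q (if l > 0), p_ve (if Kelvin enabled)
    has_l <- l > 0
    has_ve <- !is.null(ve)
    if (has_ve) { cve <- ve$c_ve; rve <- ve$r_ve }
    deriv <- function(t, V, q, pve) {
      if (V >= v_cap || V < 0 || !is.finite(V)) return(NULL)
      pa <- p_app_scalar(t)
      if (has_l) {
        dq <- (pa - r * q - pel(V) - pve) / l
      } else {
        q <- (pa - pel(V) - pve) / r
        dq <- 0
      }
      dpve <- if (has_ve) q / cve - pve / (rve * cve) else 0
      c(q, dq, dpve, q)  # dV, dq, dpve, algebraic q (for l == 0 output)
    }
    V <- v_of_p(mp); q <- 0; pve <- 0
    v_tr <- q_tr <- pve_tr <- numeric(n_tot + 1L)
    v_tr[1] <- V; q_tr[1] <- q; pve_tr[1] <- pve
    for (k in seq_len(n_tot)) {
      t0 <- t_int[k]
      k1 <- deriv(t0, V, q, pve)
      if (is.null(k1)) sim_diverged(model, t0)
      k2 <- deriv(t0 + h / 2, V + h / 2 * k1[1], q + h / 2 * k1[2], pve + h / 2 * k1[3])
      if (is.null(k2)) sim_diverged(model, t0)
      k3 <- deriv(t0 + h / 2, V + h / 2 * k2[1], q + h / 2 * k2[2], pve + h / 2 * k2[3])
      if (is.null(k3)) sim_diverged(model, t0)
      k4 <- deriv(t0 + h, V + h * k3[1], q + h * k3[2], pve + h * k3[3])
      if (is.null(k4)) sim_diverged(model, t0)
      V <- V + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      q <- q + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      pve <- pve + h / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
      if (!is.finite(V) || !is.finite(q) || abs(q) > 1e4) sim_diverged(model, t0)
      v_tr[k + 1L] <- V
      q_tr[k + 1L] <- if (has_l) q else deriv(t_int[k + 1L], V, q, pve)[4]
      pve_tr[k + 1L] <- pve
    }
    p_tr <- p_app_at(t_int)
  }

  # decimate the stimulus portion to the output rate
  dec <- internal_rate / fs
  n_out <- round(dur * fs)
  idx <- n_settle + 1L + (seq_len(n_out) - 1L) * dec
  t_out <- (seq_len(n_out) - 1L) / fs
  p_out <- p_tr[idx]
  q_out <- q_tr[idx] + model$drift_Lps

  if (model$noise_sd_frac > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    a_p <- (max(p_out) - min(p_out)) / 2
    a_q <- (max(q_out) - min(q_out)) / 2
    p_out <- p_out + rnorm(n_out, 0, model$noise_sd_frac * a_p)
    q_out <- q_out + rnorm(n_out, 0, model$noise_sd_frac * a_q)
  }

  rec <- new_recording(t_out, p_out, q_out, sample_rate = fs, mean_pressure = mp)
  if (return_state) {
    attr(rec, "state") <- tibble(time = t_int, volume = v_tr, flow = q_tr,
                                 p_ve = pve_tr, pressure = p_tr)
  }
  rec
}

sim_diverged <- function(model, t) {
  stop_oscillab("simulation",
                sprintf(paste0("integration diverged at t = %.3f s; check r_tissue_circuit = %.3g, ",
                               "l_gas = %.3g and the elastic parameters for a stiff configuration."),
                        t, model$r_tissue_circuit, model$l_gas))
}

#' Inject a measurement artifact into a recording
#'
#' Reproduces the two failure modes that force recordings to be excluded in
#' practice: mechanical-ventilation interference (a low-frequency pressure
#' sinusoid leaking into the oscillometry band) and occlusion of the
#' insufflation tube (flow clamped to zero over an interval). Both degrade
#' the magnitude-squared coherence, which is what the quality-control
#' threshold catches.
#'
#' @param rec An `oscillometry_recording`.
#' @param kind `"ventilator_interference"` or `"tube_occlusion"`.
#' @param params For interference: `frequency` (Hz, default 0.25),
#'   `amplitude` (hPa, default 1), `phase` (rad, default 0). For occlusion:
#'   `start_s` (default 0) and `duration_s` (default to end of recording).
#' @param seed Unused by the deterministic artifacts; accepted for
#'   interface uniformity.
#' @return The modified recording.
#' @export
inject_artifact <- function(rec, kind, params = list(), seed = NULL) {
  stopifnot(inherits(rec, "oscillometry_recording"))
  if (kind == "ventilator_interference") {
    p <- modifyList(list(frequency = 0.25, amplitude = 1, phase = 0), params)
    rec$pressure <- rec$pressure +
      p$amplitude * sin(2 * pi * p$frequency * rec$time + p$phase)
  } else if (kind == "tube_occlusion") {
    p <- modifyList(list(start_s = 0, duration_s = Inf), params)
    hit <- rec$time >= p$start_s & rec$time < p$start_s + p$duration_s
    rec$flow[hit] <- 0
  } else {
    stop_oscillab("input", sprintf("unknown artifact kind '%s'.", kind))
  }
  rec
}
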