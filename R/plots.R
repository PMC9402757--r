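#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs theme_minimal
NULL

#' Plot an impedance spectrum
#'
#' Resistance (real part) and reactance (imaginary part) against stimulus
#' frequency, optionally overlaid with a fitted RLC curve.
#'
#' @param object An [impedance_spectrum()].
#' @param rlc Optional [fit_rlc()] result drawn as a dashed model curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.impedance_spectrum <- function(object, rlc = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("frequency", "resistance", "reactance")],
                              c("resistance", "reactance"),
                              names_to = "component", values_to = "value")
  p <- ggplot(long, aes(x = .data$frequency, y = .data$value, shape = .data$component)) +
    geom_point(size = 2.5) +
    labs(x = "Frequency (Hz)", y = expression(Z[ab] ~ "(hPa·s/L)"),
         shape = NULL) +
    theme_minimal()
  if (!is.null(rlc)) {
    fgrid <- seq(min(object$frequency), max(object$frequency), length.out = 200)
    zm <- rlc_impedance(fgrid, rlc$r, rlc$l, rlc$c)
    model <- tibble(frequency = rep(fgrid, 2),
                    component = rep(c("resistance", "reactance"), each = length(fgrid)),
                    value = c(Re(zm), Im(zm)))
    p <- p + geom_line(data = model, aes(group = .data$component),
                       linetype = "dashed", show.legend = FALSE)
  }
  p
}

#' Plot a pressure-volume fit
#'
#' Measured staircase points with the fitted exponential curve.
#'
#' @param object A `pv_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_fit <- function(object, ...) {
  d <- object$model$m$getEnv()
  pts <- tibble(pressure = d$pressure, volume = d$volume)
  grid <- tibble(pressure = seq(min(pts$pressure), max(pts$pressure), length.out = 200))
  grid$volume <- suppressWarnings(predict_iav(object$params, grid$pressure))
  ggplot(pts, aes(x = .data$pressure, y = .data$volume)) +
    geom_point(shape = 1, size = 2.5) +
    geom_line(data = grid) +
    labs(x = "IAP (hPa)", y = "IAV (L)") +
    theme_minimal()
}

#' Plot a compliance calibration
#'
#' Scatter of paired static against dynamic compliance with the fitted
#' quadratic conversion curve.
#'
#' @param object A `quad_calibration` fitted with [fit_quadratic()].
#' @param pairs The pairs the calibration was fitted to (needed when the
#'   calibration carries no model, e.g. [reference_calibration()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quad_calibration <- function(object, pairs = NULL, ...) {
  if (is.null(pairs) && !is.null(object$model)) {
    pairs <- object$model$model
    names(pairs)[1:2] <- c("c_stat", "c_dyn")
  }
  if (is.null(pairs)) stop_oscillab("input", "supply `pairs` to plot a coefficients-only calibration.")
  grid <- tibble(c_dyn = seq(min(pairs$c_dyn), max(pairs$c_dyn), length.out = 200))
  grid$c_stat <- predict_static_from_dynamic(object, grid$c_dyn)
  ggplot(pairs, aes(x = .data$c_dyn, y = .data$c_stat)) +
    geom_point(shape = 0, size = 2) +
    geom_line(data = grid) +
    labs(x = expression(C["ab,dyn"] ~ "(L/hPa)"),
         y = expression(C["ab,stat"] ~ "(L/hPa)")) +
    theme_minimal()
}

#' Plot a recording
#'
#' Pressure and flow traces against time.
#'
#' @param object An `oscillometry_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oscillometry_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("pressure", "flow"),
                              names_to = "channel", values_to = "value")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(pressure = "Pressure (hPa)", flow = "Flow (L/s)"))) +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal()
}
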