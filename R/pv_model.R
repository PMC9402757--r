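#' Parameters of the exponential pressure-volume model
#'
#' The intra-abdominal pressure-volume relationship during CO2 insufflation
#' is described by an exponential rise to an asymptote,
#' \deqn{IAV(p) = IAV_{max} - IAV_{max} \, e^{-\lambda (p - p_0)},}
#' with a baseline pressure \eqn{p_0} (hPa), the maximum intra-abdominal
#' volume \eqn{IAV_{max}} (L) reached at infinitely high pressure, and an
#' expansion rate \eqn{\lambda} (1/hPa). Static abdominal compliance is its
#' pressure derivative.
#'
#' @param p0 Baseline pressure, hPa. May lie below the lowest measured
#'   pressure; must be finite.
#' @param iav_max Asymptotic maximum intra-abdominal volume, L. Must be > 0.
#' @param lam Expansion rate, 1/hPa. Must be > 0.
#' @return An object of class `pv_params`: a named list with elements
#'   `p0`, `iav_max`, `lam`.
#' @examples
#' pv_params(p0 = 2, iav_max = 3.84, lam = 0.12)
#' @export
pv_params <- function(p0, iav_max, lam) {
  check_number(p0, "p0")
  check_number(iav_max, "iav_max")
  check_number(lam, "lam")
  if (length(p0) != 1L || length(iav_max) != 1L || length(lam) != 1L) {
    stop_oscillab("input", "pv_params fields must be scalars.")
  }
  if (iav_max <= 0) stop_oscillab("input", "`iav_max` must be > 0.")
  if (lam <= 0) stop_oscillab("input", "`lam` must be > 0.")
  structure(list(p0 = p0, iav_max = iav_max, lam = lam), class = "pv_params")
}

#' @export
print.pv_params <- function(x, ...) {
  cat(sprintf("<pv_params> p0 = %.3g hPa, iav_max = %.3g L, lam = %.3g /hPa\n",
              x$p0, x$iav_max, x$lam))
  invisible(x)
}

# Coerce a pv_params, pv_fit, one-row data frame or named list/vector.
as_pv_params <- function(x) {
  if (inherits(x, "pv_params")) return(x)
  if (inherits(x, "pv_fit")) return(x$params)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_oscillab("input", "expected exactly one parameter row.")
    x <- as.list(x)
  }
  if (is.numeric(x) && !is.null(names(x))) x <- as.list(x)
  if (is.list(x) && all(c("p0", "iav_max", "lam") %in% names(x))) {
    return(pv_params(x$p0, x$iav_max, x$lam))
  }
  stop_oscillab("input", "cannot interpret `params`; need p0, iav_max and lam.")
}

#' Predict intra-abdominal volume at a given insufflation pressure
#'
#' Evaluates the exponential pressure-volume model. Pressures below `p0`
#' return negative volumes (model extrapolation) accompanied by a warning of
#' class `oscillab_warning_extrapolation`; they are deliberately not clamped
#' so the algebra stays invertible for the simulator's elastic recoil term.
#'
#' @param params Model parameters: a [pv_params()] object, a fitted
#'   [fit_pv_model()] result, or anything coercible (named list, one-row
#'   data frame).
#' @param p Insufflation pressure(s), hPa.
#' @return Intra-abdominal volume(s), L.
#' @examples
#' predict_iav(pv_params(2, 3.84, 0.12), p = 12)
#' @export
predict_iav <- function(params, p) {
  params <- as_pv_params(params)
  check_number(p, "p")
  v <- params$iav_max - params$iav_max * exp(-params$lam * (p - params$p0))
  if (any(p < params$p0)) {
    warn_oscillab("extrapolation",
                  sprintf("%d pressure value(s) below p0 = %.3g hPa; returning negative extrapolated volume.",
                          sum(p < params$p0), params$p0))
  }
  v
}

#' Invert the pressure-volume model
#'
#' Returns the insufflation pressure at which the model attains a given
#' volume: \eqn{p = p_0 - \ln(1 - v/IAV_{max})/\lambda}. Used by the virtual
#' abdomen as the elastic recoil pressure of the gas compartment.
#'
#' @inheritParams predict_iav
#' @param v Intra-abdominal volume(s), L; must satisfy `0 <= v < iav_max`.
#' @return Pressure(s), hPa. Round-trips with [predict_iav()] to 1e-9
#'   relative precision.
#' @export
inverse_pv <- function(params, v) {
  params <- as_pv_params(params)
  check_number(v, "v")
  if (any(v < 0)) stop_oscillab("domain", "`v` must be >= 0.")
  if (any(v >= params$iav_max)) {
    stop_oscillab("domain",
                  sprintf("`v` must be < iav_max = %.4g L (asymptote is unreachable).", params$iav_max))
  }
  params$p0 - log(1 - v / params$iav_max) / params$lam
}

#' Static abdominal compliance from the pressure-volume model
#'
#' The pressure derivative of the exponential model,
#' \deqn{C_{ab,stat}(p) = \lambda \, IAV_{max} \, e^{-\lambda (p - p_0)},}
#' in L/hPa. Strictly positive and strictly decreasing in pressure: the
#' abdomen is easiest to expand at low insufflation pressure.
#'
#' @inheritParams predict_iav
#' @return Static compliance value(s), L/hPa.
#' @examples
#' static_compliance(pv_params(2, 3.84, 0.12), p = c(5, 12, 20))
#' @export
static_compliance <- function(params, p) {
  params <- as_pv_params(params)
  check_number(p, "p")
  params$lam * params$iav_max * exp(-params$lam * (p - params$p0))
}

#' Fit the exponential pressure-volume model by nonlinear least squares
#'
#' Fits \eqn{(p_0, IAV_{max}, \lambda)} to a static insufflation staircase
#' (pressure in hPa, volume in L) by Levenberg-Marquardt least squares on
#' the volume residuals. The start is data-driven and deterministic:
#' `p0` at the lowest pressure minus 1 hPa, `iav_max` at 1.1 times the
#' largest volume, and `lam` from log-linearising the two extreme samples.
#' Box bounds keep the exponential well conditioned.
#'
#' @param data Data frame with columns `pressure` (hPa) and `volume` (L)
#'   (the column names `pressure_hPa` / `volume_L` of the on-disk format are
#'   also accepted). Pressures must be distinct; at least 4 samples.
#' @param init Optional starting parameters (anything [pv_params()]-coercible).
#' @param bounds Optional list with `lower` and `upper` named numeric
#'   vectors over `p0`, `iav_max`, `lam`, overriding the defaults.
#' @return An object of class `pv_fit`: list with `params` ([pv_params()]),
#'   `rmse` (L), `n_points`, `converged`, and the fitted `model`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' pv <- pv_params(2, 3.84, 0.12)
#' d <- tibble::tibble(pressure = c(5, 8, 10, 12, 14, 16, 18, 20),
#'                     volume = predict_iav(pv, c(5, 8, 10, 12, 14, 16, 18, 20)))
#' fit_pv_model(d)
#' @export
fit_pv_model <- function(data, init = NULL, bounds = NULL) {
  data <- normalise_pv_columns(data)
  p <- data$pressure
  v <- data$volume
  if (nrow(data) < 4L || length(unique(p)) < 4L) {
    stop_oscillab("insufficient_data",
                  "need at least 4 samples at distinct pressures (3 parameters + 1).")
  }
  check_number(p, "pressure")
  check_number(v, "volume")
  if (any(v < 0)) stop_oscillab("input", "volumes must be >= 0.")
  if (is.unsorted(p, strictly = TRUE)) {
    ord <- order(p)
    p <- p[ord]; v <- v[ord]
    if (any(diff(p) == 0)) stop_oscillab("input", "pressures must be distinct.")
  }

  vmax <- max(v)
  start <- if (!is.null(init)) {
    ip <- as_pv_params(init)
    c(p0 = ip$p0, iav_max = ip$iav_max, lam = ip$lam)
  } else {
    iav0 <- 1.1 * vmax
    p00 <- min(p) - 1
    # log-linearise the two extreme samples: 1 - v/iav_max = exp(-lam (p - p0))
    n <- length(p)
    lam0 <- -(log(1 - v[n] / iav0) - log(1 - v[1] / iav0)) / (p[n] - p[1])
    if (!is.finite(lam0) || lam0 <= 0) lam0 <- 0.1
    c(p0 = p00, iav_max = iav0, lam = min(max(lam0, 1e-3), 2))
  }
  lower <- c(p0 = -20, iav_max = vmax * (1 + 1e-9), lam = 1e-4)
  upper <- c(p0 = min(p) - 1e-9, iav_max = 10 * vmax, lam = 2)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  start <- pmin(pmax(start, lower), upper)

  fit <- minpack.lm::nlsLM(
    volume ~ iav_max - iav_max * exp(-lam * (pressure - p0)),
    data = data.frame(pressure = p, volume = v),
    start = as.list(start), lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  est <- coef(fit)
  resid <- v - (est[["iav_max"]] - est[["iav_max"]] * exp(-est[["lam"]] * (p - est[["p0"]])))
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) {
    warn_oscillab("nonconvergence", "pressure-volume fit did not converge; result flagged.")
  }
  structure(
    list(params = pv_params(est[["p0"]], est[["iav_max"]], est[["lam"]]),
         rmse = sqrt(mean(resid^2)),
         n_points = length(p),
         converged = converged,
         model = fit),
    class = "pv_fit")
}

normalise_pv_columns <- function(data) {
  if (!is.data.frame(data)) stop_oscillab("input", "`data` must be a data frame.")
  nm <- names(data)
  if ("pressure_hPa" %in% nm && !"pressure" %in% nm) data$pressure <- data$pressure_hPa
  if ("volume_L" %in% nm && !"volume" %in% nm) data$volume <- data$volume_L
  if (!all(c("pressure", "volume") %in% names(data))) {
    stop_oscillab("format", "`data` needs columns `pressure` (hPa) and `volume` (L).")
  }
  as_tibble(data)
}

#' @export
print.pv_fit <- function(x, ...) {
  cat(sprintf("<pv_fit> %d points, rmse = %.4g L%s\n", x$n_points, x$rmse,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

#' @rdname fit_pv_model
#' @param x,object A `pv_fit` object.
#' @param ... Unused.
#' @export
tidy.pv_fit <- function(x, ...) {
  tibble(term = c("p0", "iav_max", "lam"),
         estimate = c(x$params$p0, x$params$iav_max, x$params$lam),
         unit = c("hPa", "L", "1/hPa"))
}

#' @rdname fit_pv_model
#' @export
glance.pv_fit <- function(x, ...) {
  tibble(rmse = x$rmse, n_points = x$n_points, converged = x$converged)
}

#' Summarise a cohort of pressure-volume fits
#'
#' Computes the median and interquartile range of each model parameter and
#' of the fit RMSE across subjects, in the layout of a per-cohort summary
#' row. The median of an even number of subjects is the mean of the two
#' central order statistics; IQR endpoints use linear interpolation of
#' order statistics (R's quantile type 7).
#'
#' @param fits A list of `pv_fit` objects, or a data frame with columns
#'   `p0`, `iav_max`, `lam` and optionally `rmse`.
#' @param digits Named reporting precision: parameters to 2 decimals and
#'   rmse to 3 by default. Set to `NULL` to disable rounding.
#' @return A tibble with one row per quantity (`p0`, `iav_max`, `lam`,
#'   `rmse`) and columns `median`, `q1`, `q3`.
#' @examples
#' summarize_cohort(reference_cohort())
#' @export
summarize_cohort <- function(fits, digits = c(p0 = 2, iav_max = 2, lam = 2, rmse = 3)) {
  tab <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else if (is.list(fits) && length(fits) > 0 && all(purrr::map_lgl(fits, inherits, "pv_fit"))) {
    purrr::map_dfr(fits, function(f) {
      tibble(p0 = f$params$p0, iav_max = f$params$iav_max, lam = f$params$lam, rmse = f$rmse)
    })
  } else {
    stop_oscillab("input", "`fits` must be a non-empty list of pv_fit objects or a data frame.")
  }
  if (nrow(tab) == 0L) stop_oscillab("input", "cannot summarise an empty cohort.")
  quantities <- intersect(c("p0", "iav_max", "lam", "rmse"), names(tab))
  if (length(quantities) == 0L) stop_oscillab("input", "no summarisable columns found.")
  out <- purrr::map_dfr(quantities, function(q) {
    x <- tab[[q]]
    qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    tibble(quantity = q, median = median(x), q1 = qs[1], q3 = qs[2])
  })
  if (!is.null(digits)) {
    dg <- digits[out$quantity]
    dg[is.na(dg)] <- 3
    out <- dplyr::mutate(out,
      median = round(.data$median, dg),
      q1 = round(.data$q1, dg),
      q3 = round(.data$q3, dg))
  }
  out
}

#' Reference porcine cohort parameters
#'
#' Published pressure-volume model parameters for a cohort of ten
#' approximately 20-kg pigs undergoing stepwise CO2 insufflation from 5 to
#' 20 hPa, with the root-mean-square error of each subject's curve fit.
#' These serve as the default sampling ranges for [simulate_study()] and as
#' a reference input for cohort-level checks.
#'
#' @return A tibble with columns `subject`, `p0` (hPa), `iav_max` (L),
#'   `lam` (1/hPa), `rmse` (L).
#' @examples
#' reference_cohort()
#' @export
reference_cohort <- function() {
  tibble(
    subject = 1:10,
    p0      = c(1.1, 2.0, 2.4, 2.5, 2.1, 2.4, 2.3, 2.0, 1.5, 1.9),
    iav_max = c(4.52, 4.61, 3.89, 3.60, 3.99, 2.79, 3.21, 3.91, 3.78, 3.09),
    lam     = c(0.14, 0.11, 0.11, 0.13, 0.10, 0.12, 0.13, 0.10, 0.14, 0.15),
    rmse    = c(0.034, 0.021, 0.034, 0.023, 0.024, 0.007, 0.035, 0.013, 0.018, 0.021)
  )
}
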