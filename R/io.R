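#' Read and write oscillometry recordings
#'
#' Recordings are stored as delimited text with the exact header
#' `time_s,pressure_hPa,flow_Lps` (one sample per row, decimal point,
#' UTF-8) plus a JSON sidecar `<path>.json` carrying `sample_rate_Hz` and
#' `mean_pressure_hPa`. Values are written with full double precision so a
#' write/read round trip reproduces the channels to better than 1e-9.
#'
#' @param rec An `oscillometry_recording`.
#' @param path CSV file path; the sidecar lives at `paste0(path, ".json")`.
#' @return `read_recording()` returns an `oscillometry_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "oscillometry_recording"))
  df <- tibble(time_s = rec$time, pressure_hPa = rec$pressure, flow_Lps = rec$flow)
  readr::write_csv(df, path)
  meta <- list(sample_rate_Hz = rec_sample_rate(rec),
               mean_pressure_hPa = attr(rec, "mean_pressure"),
               n_samples = nrow(rec))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param sample_rate,mean_pressure Override the sidecar metadata (used
#'   when no sidecar exists).
#' @export
read_recording <- function(path, sample_rate = NULL, mean_pressure = NULL) {
  if (!file.exists(path)) stop_oscillab("input", sprintf("no such file: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("time_s", "pressure_hPa", "flow_Lps")
  if (!identical(names(raw)[seq_along(required)], required)) {
    stop_oscillab("format",
                  sprintf("expected header `%s`, found `%s` (unit suffixes are mandatory).",
                          paste(required, collapse = ","), paste(names(raw), collapse = ",")))
  }
  cols <- lapply(required, function(nm) {
    x <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(x) & !is.na(raw[[nm]]))
    if (length(bad) > 0 || anyNA(raw[[nm]])) {
      row <- c(bad, which(is.na(raw[[nm]])))[1]
      stop_oscillab("format",
                    sprintf("non-numeric value in column `%s` at data row %d.", nm, row))
    }
    x
  })
  names(cols) <- required
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    sample_rate <- sample_rate %||% meta$sample_rate_Hz
    mean_pressure <- mean_pressure %||% meta$mean_pressure_hPa
  }
  if (is.null(sample_rate)) {
    dt <- diff(cols$time_s)
    sample_rate <- 1 / stats::median(dt)
  }
  jitter <- if (length(cols$time_s) > 1) max(abs(diff(cols$time_s) - 1 / sample_rate)) else 0
  if (jitter > 1e-9) {
    row <- which.max(abs(diff(cols$time_s) - 1 / sample_rate)) + 1L
    stop_oscillab("format",
                  sprintf("non-uniform sampling at data row %d (jitter %.3g s against %g Hz).",
                          row, jitter, sample_rate))
  }
  new_recording(cols$time_s, cols$pressure_hPa, cols$flow_Lps,
                sample_rate = sample_rate,
                mean_pressure = mean_pressure %||% mean(cols$pressure_hPa))
}

# Provenance block embedded in every JSON artifact.
output_metadata <- function(seed = NULL, config = NULL) {
  list(package = "oscillab",
       version = as.character(utils::packageVersion("oscillab")),
       seed = seed,
       config_hash = if (!is.null(config)) {
         rlang::hash(config)
       } else NULL)
}

#' Write analysis artifacts as JSON
#'
#' Serialisers for impedance spectra, RLC fits, pressure-volume fits and
#' calibrations. Keys carry explicit unit suffixes; every document embeds
#' the package version and, when given, the seed and a configuration hash,
#' so the artifact can be regenerated exactly.
#'
#' @param x The object to write.
#' @param path Output file.
#' @param seed,config Optional provenance recorded in the document.
#' @return `path`, invisibly.
#' @export
write_spectrum_json <- function(x, path, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "impedance_spectrum"))
  doc <- list(
    meta = output_metadata(seed, config),
    mean_pressure_hPa = attr(x, "mean_pressure"),
    points = purrr::pmap(x[c("frequency", "resistance", "reactance", "coherence", "n_windows")],
      function(frequency, resistance, reactance, coherence, n_windows) {
        list(frequency_Hz = frequency, resistance_hPasL = resistance,
             reactance_hPasL = reactance, coherence = coherence, n_windows = n_windows)
      }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
read_spectrum_json <- function(path) {
  doc <- jsonlite::read_json(path)
  pts <- purrr::map_dfr(doc$points, function(p) {
    tibble(frequency = p$frequency_Hz,
           resistance = p$resistance_hPasL,
           reactance = p$reactance_hPasL,
           coherence = p$coherence,
           n_windows = p$n_windows)
  })
  pts$impedance <- complex(real = pts$resistance, imaginary = pts$reactance)
  attr(pts, "mean_pressure") <- doc$mean_pressure_hPa
  class(pts) <- c("impedance_spectrum", class(pts))
  pts
}

#' @rdname write_spectrum_json
#' @export
write_rlc_json <- function(x, path, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "rlc_fit"))
  doc <- list(meta = output_metadata(seed, config),
              r_hPasL = x$r, l_hPas2L = x$l, c_LhPa = x$c,
              rmse_hPasL = x$rmse, n_points = x$n_points,
              converged = x$converged, low_confidence = x$low_confidence,
              excluded_frequencies_Hz = x$excluded)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
write_pv_fit_json <- function(x, path, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "pv_fit"))
  doc <- list(meta = output_metadata(seed, config),
              p0_hPa = x$params$p0, iav_max_L = x$params$iav_max,
              lam_per_hPa = x$params$lam, rmse_L = x$rmse,
              n_points = x$n_points, converged = x$converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
write_calibration_json <- function(x, path, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "quad_calibration"))
  cf <- x$coefficients
  doc <- list(meta = output_metadata(seed, config),
              intercept_LhPa = unname(cf["intercept"]),
              linear = unname(cf["linear"]),
              quadratic_hPaL = unname(cf["quadratic"]),
              n_pairs = x$n_pairs,
              adjusted_r_squared = x$adjusted_r_squared)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write or read a simulated study as a directory tree
#'
#' Lays a [simulate_study()] dataset out as
#' `subject_<i>/step_<p>hPa/recording.csv` per recording, with
#' `volumes.csv` (columns `subject,pressure_hPa,volume_L`), `truth.json`
#' (generating parameters) and `design.json` at the root.
#'
#' @param study A `study_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly; `read_study_volumes()` returns the volumes
#'   tibble with `pressure`/`volume` columns.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    dplyr::transmute(study$volumes, subject = .data$subject,
                     pressure_hPa = .data$pressure, volume_L = .data$volume),
    file.path(dir, "volumes.csv"))
  jsonlite::write_json(
    list(meta = output_metadata(seed = study$design$seed),
         subjects = purrr::pmap(study$subjects, function(subject, p0, iav_max, lam) {
           list(subject = subject, p0_hPa = p0, iav_max_L = iav_max, lam_per_hPa = lam)
         })),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  d <- study$design
  jsonlite::write_json(
    list(n_subjects = d$n_subjects, pressures_hPa = d$pressures,
         seed = d$seed, r_tissue_circuit_hPasL = d$r_tissue_circuit,
         l_gas_hPas2L = d$l_gas, noise_sd_frac = d$noise_sd_frac,
         volume_noise_sd_L = d$volume_noise_sd,
         protocol = list(frequencies_Hz = d$protocol$frequencies,
                         cycles = d$protocol$cycles,
                         peak_to_peak_hPa = d$protocol$peak_to_peak,
                         sample_rate_Hz = d$protocol$sample_rate)),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  purrr::pwalk(study$recordings, function(subject, pressure, seed, recording) {
    sub <- file.path(dir, sprintf("subject_%02d", subject),
                     sprintf("step_%02ghPa", pressure))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    write_recording(recording, file.path(sub, "recording.csv"))
  })
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study_volumes <- function(dir) {
  path <- file.path(dir, "volumes.csv")
  if (!file.exists(path)) stop_oscillab("input", sprintf("no volumes.csv under %s", dir))
  readr::read_csv(path, col_types = "idd", progress = FALSE) |>
    dplyr::rename(pressure = "pressure_hPa", volume = "volume_L")
}
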