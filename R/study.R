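#' Design of a replica insufflation study
#'
#' Describes a cohort study in which each subject undergoes a stepwise
#' insufflation staircase with a static volume measurement and one
#' oscillometry recording at every pressure step. Defaults replicate the
#' reference porcine experiment: 10 subjects, pressure steps 5, 8, 10, 12,
#' 14, 16, 18 and 20 hPa, the default 20-s stimulus, subject parameters
#' sampled uniformly within the extremes of the reference cohort
#' ([reference_cohort()]), a viscoelastic abdomen, 2% sensor noise, and
#' static volume measurement noise of 0.02 L.
#'
#' @param n_subjects Number of subjects. Default 10.
#' @param pressures Insufflation pressure steps, hPa, strictly increasing.
#' @param protocol A [stimulus_protocol()]; its `mean_pressure` is replaced
#'   by each step's pressure.
#' @param ranges Named list of `c(min, max)` sampling ranges for `p0`,
#'   `iav_max` and `lam`.
#' @param r_tissue_circuit,l_gas,viscoelastic,noise_sd_frac Passed to
#'   [abdomen_model()] for every subject.
#' @param volume_noise_sd Gaussian sd of the static volume measurement
#'   noise, L. Within each subject the noise vector is redrawn until the
#'   volume staircase stays strictly increasing, preserving the
#'   monotonicity every real staircase shows.
#' @param seed Master seed; all per-subject and per-step randomness derives
#'   from it (see [simulate_study()]).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 10,
                         pressures = c(5, 8, 10, 12, 14, 16, 18, 20),
                         protocol = stimulus_protocol(),
                         ranges = list(p0 = c(1.1, 2.5),
                                       iav_max = c(2.79, 4.61),
                                       lam = c(0.10, 0.15)),
                         r_tissue_circuit = 5, l_gas = 0.2,
                         viscoelastic = TRUE, noise_sd_frac = 0.02,
                         volume_noise_sd = 0.02,
                         seed = 1L) {
  if (n_subjects < 1) stop_oscillab("config", "`n_subjects` must be >= 1.")
  check_number(pressures, "pressures")
  if (is.unsorted(pressures, strictly = TRUE)) {
    stop_oscillab("config", "`pressures` must be strictly increasing.")
  }
  for (nm in c("p0", "iav_max", "lam")) {
    rg <- ranges[[nm]]
    if (is.null(rg) || length(rg) != 2 || rg[1] > rg[2]) {
      stop_oscillab("config", sprintf("range for `%s` must be c(min, max).", nm))
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), pressures = pressures,
                 protocol = protocol, ranges = ranges,
                 r_tissue_circuit = r_tissue_circuit, l_gas = l_gas,
                 viscoelastic = viscoelastic, noise_sd_frac = noise_sd_frac,
                 volume_noise_sd = volume_noise_sd, seed = as.integer(seed)),
            class = "study_design")
}

# Deterministic child-seed rule: every recording is reproducible in
# isolation from (master, subject, step). Step 0 is reserved for the
# subject's static volume noise. All results stay below 2^31 - 1.
child_seed <- function(master, subject, step) {
  as.integer((as.double(master) * 100003 + subject * 1009 + step * 101) %% 2147483647)
}

#' Simulate a full replica insufflation study
#'
#' Draws each subject's pressure-volume parameters uniformly within the
#' design ranges, computes the static volume staircase from the
#' pressure-volume model (plus measurement noise), and simulates one
#' oscillometry recording per subject and pressure step through
#' [simulate_recording()]. Per-recording seeds derive deterministically
#' from the master seed, so the whole dataset — and any single recording —
#' is reproducible.
#'
#' @param design A [study_design()].
#' @return A list of class `study_dataset` with elements:
#'   \describe{
#'     \item{subjects}{tibble of true parameters: `subject`, `p0`,
#'       `iav_max`, `lam`.}
#'     \item{volumes}{tibble `subject`, `pressure`, `volume` (L).}
#'     \item{recordings}{nested tibble `subject`, `pressure`, `seed`,
#'       `recording` (list column of `oscillometry_recording`).}
#'     \item{design}{the design used.}
#'   }
#' @examples
#' \donttest{
#' ds <- simulate_study(study_design(n_subjects = 2, seed = 7))
#' nrow(ds$recordings)
#' }
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  rg <- design$ranges
  subjects <- tibble(
    subject = seq_len(design$n_subjects),
    p0 = runif(design$n_subjects, rg$p0[1], rg$p0[2]),
    iav_max = runif(design$n_subjects, rg$iav_max[1], rg$iav_max[2]),
    lam = runif(design$n_subjects, rg$lam[1], rg$lam[2]))

  volumes <- purrr::map_dfr(seq_len(design$n_subjects), function(i) {
    pv <- pv_params(subjects$p0[i], subjects$iav_max[i], subjects$lam[i])
    v_true <- predict_iav(pv, design$pressures)
    v <- v_true
    if (design$volume_noise_sd > 0) {
      set.seed(child_seed(design$seed, i, 0L))
      for (try in 1:1000) {
        v <- v_true + rnorm(length(v_true), 0, design$volume_noise_sd)
        if (!is.unsorted(v, strictly = TRUE) && all(v > 0)) break
      }
      if (is.unsorted(v, strictly = TRUE)) v <- v_true  # pathological design; fall back
    }
    tibble(subject = i, pressure = design$pressures, volume = v)
  })

  grid <- tidyr::expand_grid(subject = seq_len(design$n_subjects),
                             step = seq_along(design$pressures))
  recordings <- purrr::pmap_dfr(grid, function(subject, step) {
    pv <- pv_params(subjects$p0[subject], subjects$iav_max[subject], subjects$lam[subject])
    model <- abdomen_model(pv = pv,
                           r_tissue_circuit = design$r_tissue_circuit,
                           l_gas = design$l_gas,
                           viscoelastic = design$viscoelastic,
                           noise_sd_frac = design$noise_sd_frac)
    proto <- design$protocol
    proto$mean_pressure <- design$pressures[step]
    sd_rec <- child_seed(design$seed, subject, step)
    tibble(subject = subject, pressure = design$pressures[step], seed = sd_rec,
           recording = list(simulate_recording(model, proto, seed = sd_rec)))
  })

  structure(list(subjects = subjects, volumes = volumes,
                 recordings = recordings, design = design),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects x %d pressures = %d recordings (master seed %d)\n",
              x$design$n_subjects, length(x$design$pressures),
              nrow(x$recordings), x$design$seed))
  invisible(x)
}

#' Run the full analysis pipeline over a simulated study
#'
#' For every recording: Welch impedance spectrum and RLC inversion, giving
#' dynamic compliance per subject and pressure. For every subject: an
#' exponential pressure-volume fit of the static staircase, giving static
#' compliance at each pressure. The two are paired and the quadratic
#' calibration fitted.
#'
#' @param study A [simulate_study()] result.
#' @param coherence_min Quality-control threshold passed to [fit_rlc()].
#' @param exclude Optional tibble with columns `subject`, `pressure`
#'   identifying recordings to drop before pairing (emulating excluded
#'   measurements).
#' @return A list with `pv_fits` (named list of `pv_fit`), `rlc` (tibble
#'   `subject`, `pressure`, `c_dyn`, `r`, `l`, `rmse`), `pairs` (see
#'   [pair_compliances()]) and `calibration` (see [fit_quadratic()]).
#' @export
analyze_study <- function(study, coherence_min = 0.9, exclude = NULL) {
  stopifnot(inherits(study, "study_dataset"))
  proto <- study$design$protocol
  recs <- study$recordings
  if (!is.null(exclude)) {
    recs <- dplyr::anti_join(recs, exclude, by = c("subject", "pressure"))
  }
  rlc <- purrr::pmap_dfr(recs[c("subject", "pressure", "recording")],
    function(subject, pressure, recording) {
      p <- proto
      p$mean_pressure <- pressure
      spec <- impedance_spectrum(recording, p)
      fit <- fit_rlc(spec, coherence_min = coherence_min)
      tibble(subject = subject, pressure = pressure,
             c_dyn = fit$c, r = fit$r, l = fit$l, rmse = fit$rmse,
             min_coherence = min(spec$coherence))
    })
  pv_fits <- study$volumes |>
    dplyr::group_split(.data$subject) |>
    purrr::map(fit_pv_model)
  names(pv_fits) <- as.character(sort(unique(study$volumes$subject)))
  pairs <- pair_compliances(pv_fits, rlc)
  calibration <- fit_quadratic(pairs)
  list(pv_fits = pv_fits, rlc = rlc, pairs = pairs, calibration = calibration)
}
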