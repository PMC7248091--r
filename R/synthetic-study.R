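# Synthetic study generators: whole simulated experiments (calibration,
# detection-limit ladders, precision runs, clinical comparisons) built on
# the instrument simulator + demodulation chain.
#
# Replicate-to-replicate realism: detector noise alone underestimates the
# spread of repeated measurements on a real bench (capillary
# repositioning, thermal drift). The study generators therefore jitter
# the photothermal amplitude multiplicatively per measurement
# (`replicate_cv`, default 1%) and per day (`day_cv`, default 0.5% in
# multi-day series). The simulator contracts themselves stay exact; the
# jitter lives only here.

#' Default calibration ladder (g/dL)
#'
#' Sixteen whole-blood levels spanning 0.1-17.8 g/dL (fourteen clinical
#' specimens plus two low-concentration plasma dilutions), the standard
#' working range of a whole-blood hemoglobin sensor calibration.
#'
#' @return Numeric vector of 16 concentrations.
#' @export
default_calibration_levels <- function() {
  c(0.1, 0.35, 1.5, 4.8, 5.8, 7.1, 8.0, 9.0, 10.0, 11.0,
    12.0, 13.0, 14.0, 15.0, 16.0, 17.8)
}

# One simulated measurement -> sensor signal (uses the current RNG stream).
sim_signal_once <- function(hb, optical, photothermal, noise, jitter_cv) {
  pt <- photothermal
  if (jitter_cv > 0) {
    pt$phi_max <- pt$phi_max * exp(rnorm(1, 0, jitter_cv))
  }
  stack <- simulate_stack(hb, optical, pt, noise)
  measure_stack(stack)$signal
}

#' Simulate a full calibration study
#'
#' Runs the simulator + demodulation chain for `reps` replicate
#' measurements at each calibration level and returns the replicate-level
#' calibration table ready for [fit_hill()].
#'
#' @param levels Nominal concentrations (g/dL); default
#'   [default_calibration_levels()].
#' @param reps Replicates per level (default 10).
#' @param seed Integer seed for reproducibility.
#' @param optical,photothermal,noise Instrument configuration; noise
#'   must not carry its own seed (the study seed governs).
#' @param replicate_cv Per-measurement multiplicative jitter of the
#'   photothermal amplitude (fractional SD, default 0.01).
#' @return Tibble: `specimen_id`, `nominal_hb`, `replicate`, `signal`.
#' @export
#' @examples
#' \donttest{
#' cal <- simulate_calibration_study(reps = 2, seed = 1)
#' fit_hill(cal)
#' }
simulate_calibration_study <- function(levels = default_calibration_levels(),
                                       reps = 10, seed = NULL,
                                       optical = optical_config(),
                                       photothermal = photothermal_model(),
                                       noise = noise_model(),
                                       replicate_cv = 0.01) {
  if (!is.numeric(levels) || any(levels < 0)) stop_input("`levels` must be >= 0 g/dL")
  check_scalar_number(reps, "reps", lower = 1)
  with_seed(seed, {
    grid <- tidyr::expand_grid(specimen_id = seq_along(levels),
                               replicate = seq_len(reps))
    grid$nominal_hb <- levels[grid$specimen_id]
    grid$signal <- purrr::map_dbl(grid$nominal_hb, sim_signal_once,
                                  optical = optical, photothermal = photothermal,
                                  noise = noise, jitter_cv = replicate_cv)
    grid[, c("specimen_id", "nominal_hb", "replicate", "signal")]
  })
}

#' Simulate a replicate measurement series at one concentration
#'
#' Repeated measurements of the same specimen, optionally across several
#' days (with an additional day-level amplitude jitter), optionally
#' converted to g/dL through a calibration curve.
#'
#' @param hb True concentration (g/dL).
#' @param n Replicates per day.
#' @param days Number of days (1 = intra-assay design).
#' @param seed Integer seed.
#' @param curve Optional [hill_curve()]/[fit_hill()] used to convert
#'   signals to measured [Hb].
#' @inheritParams simulate_calibration_study
#' @param day_cv Day-level multiplicative amplitude jitter (fractional
#'   SD, default 0.005); only applied when `days > 1`.
#' @return Tibble: `day`, `replicate`, `signal`, and `hb_measured` when a
#'   curve is supplied.
#' @export
simulate_measurement_series <- function(hb, n = 5, days = 1, seed = NULL,
                                        curve = NULL,
                                        optical = optical_config(),
                                        photothermal = photothermal_model(),
                                        noise = noise_model(),
                                        replicate_cv = 0.01, day_cv = 0.005) {
  check_scalar_number(hb, "hb", lower = 0)
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(days, "days", lower = 1)
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(days), function(d) {
      pt <- photothermal
      if (days > 1 && day_cv > 0) {
        pt$phi_max <- pt$phi_max * exp(rnorm(1, 0, day_cv))
      }
      tibble(day = d, replicate = seq_len(n),
             signal = purrr::map_dbl(seq_len(n), function(i) {
               sim_signal_once(hb, optical, pt, noise, replicate_cv)
             }))
    })
    if (!is.null(curve)) out$hb_measured <- invert_hill(curve, out$signal)$hb
    out
  })
}

#' Simulate a clinical method-comparison study
#'
#' Draws a virtual cohort with sex-specific [Hb] distributions, runs each
#' specimen through the full simulate -> measure -> invert chain, and
#' returns paired reference/device values ready for [passing_bablok()],
#' [bland_altman()] and [evaluate_anemia()]. The reference analyzer is
#' treated as ground truth; `bias` shifts the specimen presented to the
#' device (a systematic device offset).
#'
#' @param n Number of specimens.
#' @param curve Calibration curve used to invert device signals
#'   ([hill_curve()] or [fit_hill()] result). Required.
#' @param seed Integer seed.
#' @param bias Injected systematic device offset (g/dL, default 0).
#' @param p_male Probability a subject is male (default 0.5).
#' @param hb_mean,hb_sd Named vectors (`male`, `female`) of the cohort
#'   [Hb] distribution (g/dL); defaults give a realistic mix of anemic
#'   and non-anemic adults.
#' @param hb_range Truncation range for drawn concentrations (g/dL).
#' @inheritParams simulate_calibration_study
#' @return Tibble: `id`, `sex`, `reference_hb`, `device_hb`.
#' @export
simulate_clinical_study <- function(n, curve, seed = NULL, bias = 0,
                                    p_male = 0.5,
                                    hb_mean = c(male = 13.5, female = 12.5),
                                    hb_sd = c(male = 2.0, female = 1.8),
                                    hb_range = c(4, 21),
                                    optical = optical_config(),
                                    photothermal = photothermal_model(),
                                    noise = noise_model(),
                                    replicate_cv = 0.01) {
  check_scalar_number(n, "n", lower = 1)
  curve <- as_hill_curve(curve)
  with_seed(seed, {
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
    truth <- vapply(sex, function(s) {
      repeat {
        v <- rnorm(1, hb_mean[[s]], hb_sd[[s]])
        if (v >= hb_range[1] && v <= hb_range[2]) return(v)
      }
    }, numeric(1))
    device <- purrr::map_dbl(truth + bias, function(h) {
      s <- sim_signal_once(max(h, 0), optical, photothermal, noise, replicate_cv)
      invert_hill(curve, s)$hb
    })
    tibble(id = seq_len(n), sex = sex, reference_hb = truth,
           device_hb = device)
  })
}

#' Simulate tabular paired measurements with known truth
#'
#' Quick generator for method-comparison statistics without the imaging
#' chain: reference values uniform over a range, device = reference +
#' `bias` + Gaussian noise.
#'
#' @param n Number of pairs.
#' @param bias True systematic difference (g/dL).
#' @param sd SD of the random device-reference difference (g/dL).
#' @param range Reference [Hb] range (g/dL).
#' @param seed Integer seed.
#' @return Tibble: `id`, `reference_hb`, `device_hb`.
#' @export
simulate_paired_hb <- function(n, bias = 0, sd = 0.5, range = c(5, 20),
                               seed = NULL) {
  check_scalar_number(n, "n", lower = 2)
  with_seed(seed, {
    ref <- stats::runif(n, range[1], range[2])
    tibble(id = seq_len(n), reference_hb = ref,
           device_hb = ref + bias + rnorm(n, 0, sd))
  })
}
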