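# Hill-equation calibration between sensor signal (rad) and [Hb] (g/dL).

#' Construct a Hill calibration curve
#'
#' Four-parameter Hill law `s(Hb) = s0 + s_max * Hb^h / (k_half^h + Hb^h)`.
#' The baseline `s0` absorbs the nonzero blank reading of a real
#' instrument; `s_max` is the span, `k_half` the half-saturation
#' concentration and `h` the Hill coefficient. The predicted signal is
#' strictly increasing on `[0, Inf)` whenever `s_max, k_half, h > 0`.
#'
#' @param s0 Baseline signal (rad, >= 0).
#' @param s_max Signal span (rad, > 0).
#' @param k_half Half-saturation concentration (g/dL, > 0).
#' @param h Hill coefficient (> 0).
#' @param r_squared Optional goodness-of-fit carried along with a fitted
#'   curve.
#' @return An object of class `hill_curve`.
#' @export
hill_curve <- function(s0, s_max, k_half, h, r_squared = NA_real_) {
  check_scalar_number(s0, "s0", lower = 0)
  check_scalar_number(s_max, "s_max", lower = 0, strict_lower = TRUE)
  check_scalar_number(k_half, "k_half", lower = 0, strict_lower = TRUE)
  check_scalar_number(h, "h", lower = 0, strict_lower = TRUE)
  structure(list(s0 = s0, s_max = s_max, k_half = k_half, h = h,
                 r_squared = r_squared),
            class = "hill_curve")
}

as_hill_curve <- function(object) {
  if (inherits(object, "hill_curve")) return(object)
  if (inherits(object, "hill_fit")) return(object$curve)
  stop_input("expected a `hill_curve` or `hill_fit`")
}

#' Predicted sensor signal at a concentration
#'
#' @param object A [hill_curve()] or [fit_hill()] result.
#' @param hb Concentration(s) in g/dL, >= 0.
#' @return Predicted signal(s) in rad.
#' @export
#' @examples
#' cv <- hill_curve(0.05, 1.4, 9, 1.2)
#' predict_signal(cv, 9) - cv$s0 # half the span
predict_signal <- function(object, hb) {
  curve <- as_hill_curve(object)
  if (!is.numeric(hb) || any(!is.finite(hb))) stop_input("`hb` must be finite numeric")
  if (any(hb < 0)) stop_input("`hb` must be >= 0 g/dL")
  h <- curve$h
  curve$s0 + curve$s_max * hb^h / (curve$k_half^h + hb^h)
}

#' Fit a Hill calibration curve to replicate sensor readings
#'
#' Weighted least-squares fit of the four-parameter Hill law to
#' per-specimen replicate means (weights = replicate counts), matching how
#' calibration curves are usually displayed as per-specimen means with
#' confidence intervals. Optimisation is bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()], all parameters constrained positive, tolerances
#' 1e-10, up to 10,000 function evaluations) from a deterministic,
#' scale-free start: `s0` = minimum mean signal, `s_max` = range of mean
#' signals, `k_half` = concentration at half-range by linear
#' interpolation, `h` = 1.
#'
#' @param data Data frame of calibration measurements, one row per
#'   replicate reading.
#' @param nominal Column with the reference-analyzer concentration
#'   (g/dL); default `nominal_hb`.
#' @param signal Column with the sensor reading (rad, >= 0); default
#'   `signal`.
#' @return An object of class `hill_fit`: list with `curve`
#'   ([hill_curve()] including `r_squared` against the replicate means),
#'   `means` (per-level tibble), `fit` (the underlying `nls` object) and
#'   `degenerate` flag. Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_hill <- function(data, nominal = nominal_hb, signal = signal) {
  d <- dplyr::transmute(as_tibble(data),
                        hb = {{ nominal }}, s = {{ signal }})
  if (!is.numeric(d$hb) || !is.numeric(d$s) || any(!is.finite(d$hb)) ||
      any(!is.finite(d$s))) {
    stop_input("calibration table must have finite numeric concentrations and signals")
  }
  if (any(d$s < 0)) stop_input("all signals must be >= 0 rad")
  if (any(d$hb < 0)) stop_input("all concentrations must be >= 0 g/dL")
  means <- d |>
    dplyr::group_by(.data$hb) |>
    dplyr::summarise(mean_signal = mean(.data$s), n = dplyr::n(),
                     sd_signal = sd(.data$s), .groups = "drop") |>
    dplyr::arrange(.data$hb)
  if (nrow(means) < 4L) {
    stop_input("need >= 4 distinct concentrations to fit a 4-parameter Hill curve")
  }
  span <- max(means$mean_signal) - min(means$mean_signal)
  if (span <= 0) stop_input("signals show no response across concentrations")
  s0_init <- min(means$mean_signal)
  half <- s0_init + span / 2
  k_init <- tryCatch(
    approx(means$mean_signal, means$hb, xout = half, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(k_init) || k_init <= 0) k_init <- median(means$hb[means$hb > 0])
  eps <- 1e-12
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mean_signal ~ s0 + s_max * hb^h / (k_half^h + hb^h),
      data = means,
      start = list(s0 = s0_init, s_max = span, k_half = k_init, h = 1),
      lower = c(s0 = 0, s_max = eps, k_half = eps, h = eps),
      weights = means$n,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxfev = 10000, maxiter = 1000)
    ),
    error = function(e) {
      stop_numeric(sprintf(
        "Hill fit failed to converge: %s (start: s0=%.4g, s_max=%.4g, k_half=%.4g, h=1)",
        conditionMessage(e), s0_init, span, k_init))
    })
  p <- coef(fit)
  w <- means$n
  resid <- means$mean_signal -
    (p["s0"] + p["s_max"] * means$hb^p["h"] / (p["k_half"]^p["h"] + means$hb^p["h"]))
  wmean <- sum(w * means$mean_signal) / sum(w)
  r2 <- 1 - sum(w * resid^2) / sum(w * (means$mean_signal - wmean)^2)
  degenerate <- unname(p["s_max"]) < 1e-6 * max(span, 1e-12)
  if (degenerate) {
    warn("fitted signal span s_max is ~0: calibration is degenerate (no response)")
  }
  curve <- hill_curve(unname(p["s0"]), unname(max(p["s_max"], eps)),
                      unname(p["k_half"]), unname(p["h"]), r_squared = r2)
  # monotonicity guard: analytic for positive parameters, asserted numerically
  grid <- predict_signal(curve, seq(0, max(means$hb) * 1.5, length.out = 200))
  stopifnot(all(diff(grid) >= -1e-12))
  structure(list(curve = curve, means = means, fit = fit,
                 degenerate = degenerate),
            class = "hill_fit")
}

#' Invert a Hill calibration curve
#'
#' Closed-form inverse
#' `hb = k_half * ((s - s0) / (s0 + s_max - s))^(1/h)`. Signals at or
#' below the baseline clamp to 0 g/dL (`censored = "floor"`); signals at
#' or above `s0 + ceiling_frac * s_max` clamp to the concentration at
#' that fraction of saturation (`censored = "ceiling"`), since the
#' inverse diverges at full saturation.
#'
#' @param object A [hill_curve()] or [fit_hill()] result.
#' @param signal Sensor reading(s) in rad.
#' @param ceiling_frac Fraction of the span treated as the usable ceiling
#'   (default 0.999).
#' @return Tibble with columns `signal`, `hb` (g/dL) and `censored`
#'   (`"none"`, `"floor"` or `"ceiling"`).
#' @export
#' @examples
#' cv <- hill_curve(0.05, 1.4, 9, 1.2)
#' invert_hill(cv, predict_signal(cv, c(1, 5, 11.2, 17.8)))$hb
invert_hill <- function(object, signal, ceiling_frac = 0.999) {
  curve <- as_hill_curve(object)
  check_scalar_number(ceiling_frac, "ceiling_frac", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (!is.numeric(signal) || any(!is.finite(signal))) {
    stop_input("`signal` must be finite numeric")
  }
  s_ceiling <- curve$s0 + ceiling_frac * curve$s_max
  hb_ceiling <- curve$k_half * (ceiling_frac / (1 - ceiling_frac))^(1 / curve$h)
  s <- pmin(pmax(signal, curve$s0), s_ceiling)
  q <- (s - curve$s0) / (curve$s0 + curve$s_max - s)
  hb <- curve$k_half * q^(1 / curve$h)
  hb[signal >= s_ceiling] <- hb_ceiling
  hb[signal <= curve$s0] <- 0
  tibble(signal = signal, hb = hb,
         censored = dplyr::case_when(signal <= curve$s0 ~ "floor",
                                     signal >= s_ceiling ~ "ceiling",
                                     TRUE ~ "none"))
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf(
    "<hill_curve> s(Hb) = %.4g + %.4g * Hb^%.4g / (%.4g^%.4g + Hb^%.4g)  [rad; Hb g/dL]\n",
    x$s0, x$s_max, x$h, x$k_half, x$h, x$h))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.5f\n", x$r_squared))
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  fitted on %d levels (%d readings)\n",
              nrow(x$means), sum(x$means$n)))
  invisible(x)
}

#' Tidy a Hill calibration fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.hill_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' One-row summary of a Hill calibration fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared` (against replicate means), `sigma`,
#'   `nobs` (number of levels), `n.readings` and `degenerate`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(r.squared = x$curve$r_squared,
         sigma = summary(x$fit)$sigma,
         nobs = nrow(x$means),
         n.readings = sum(x$means$n),
         degenerate = x$degenerate)
}

#' Plot a Hill calibration fit
#'
#' Per-level mean readings (with +/- 1 SD bars where replicates exist)
#' and the fitted saturating curve.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(hb = seq(0, max(object$means$hb), length.out = 250))
  grid$signal <- predict_signal(object$curve, grid$hb)
  ggplot2::ggplot(object$means, ggplot2::aes(.data$hb, .data$mean_signal)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_signal - .data$sd_signal,
                                        ymax = .data$mean_signal + .data$sd_signal),
                           width = 0, colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$signal),
                       colour = "#b2182b") +
    ggplot2::labs(x = "[Hb] (g/dL)", y = "sensor signal (rad)",
                  title = sprintf("Hill calibration (R² = %.4f)",
                                  object$curve$r_squared))
}

#' Write a calibration curve to a versioned JSON file
#'
#' @param object A [hill_curve()] or [fit_hill()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(object, path) {
  curve <- as_hill_curve(object)
  payload <- list(format = "ptashb-calibration", format_version = 1L,
                  parameters = list(s0 = curve$s0, s_max = curve$s_max,
                                    k_half = curve$k_half, h = curve$h),
                  r_squared = curve$r_squared)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path Path to a file written by [write_calibration()].
#' @return A [hill_curve()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("calibration file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "ptashb-calibration") {
    stop_input("not a ptashb calibration file (missing format tag)")
  }
  p <- x$parameters
  hill_curve(p$s0, p$s_max, p$k_half, p$h,
             r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared)
}
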