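# Device-vs-reference method agreement: Passing-Bablok regression,
# Bland-Altman limits of agreement, within-threshold agreement fraction.

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression. All pairwise slopes
#' `S_ij = (y_j - y_i)/(x_j - x_i)` for `i < j` are enumerated, excluding
#' undefined slopes (`x_i = x_j`) and slopes exactly -1; with `K` the
#' number of slopes below -1, the slope estimate is the median of the
#' sorted slopes shifted by `K` ranks (which makes the estimator
#' invariant to swapping the two methods). The 95% CI comes from the
#' rank offsets `M1 = ceiling((N - C)/2)`, `M2 = N - M1 + 1` with
#' `C = z * sqrt(n(n-1)(2n+5)/18)`. The intercept is
#' `median(y - slope * x)`, its CI bounds computed at the slope CI
#' bounds. Pearson r, R² and the RMSE of the raw differences
#' (`device - reference`) are reported alongside as overall
#' correspondence summaries.
#'
#' @param data Data frame of paired measurements (one row per specimen).
#' @param reference Column with the reference method's values (g/dL);
#'   default `reference_hb`.
#' @param device Column with the candidate device's values; default
#'   `device_hb`.
#' @param conf_level Confidence level for the slope/intercept CIs.
#' @return An object of class `pb_fit` supporting [tidy()], [glance()],
#'   [autoplot()]: slope and intercept with CIs, `n`, `r`, `r_squared`,
#'   `rmse`.
#' @export
#' @examples
#' d <- tibble::tibble(reference_hb = c(5, 8, 11, 14, 17),
#'                     device_hb = c(5.1, 8.2, 10.9, 14.3, 16.8))
#' passing_bablok(d)
passing_bablok <- function(data, reference = reference_hb, device = device_hb,
                           conf_level = 0.95) {
  d <- dplyr::transmute(as_tibble(data), x = {{ reference }}, y = {{ device }})
  x <- d$x
  y <- d$y
  n <- length(x)
  if (n < 3L) stop_input("Passing-Bablok regression needs n >= 3 pairs")
  if (!is.numeric(x) || !is.numeric(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop_input("paired values must be finite numeric")
  }
  if (length(unique(x)) == 1L) stop_input("all reference values identical: slopes undefined")
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  slopes <- dy[dx != 0] / dx[dx != 0]
  slopes <- slopes[slopes != -1]
  nn <- length(slopes)
  if (nn == 0L) stop_numeric("no valid pairwise slopes: degenerate input")
  slopes <- sort(slopes)
  k_off <- sum(slopes < -1)
  med_at <- function(idx) {
    # shifted median on the sorted slopes; even/odd rule on the rank
    if (idx < 1 || idx > nn) stop_numeric("slope rank out of range (heavily negative data?)")
    slopes[idx]
  }
  slope <- if (nn %% 2L == 1L) {
    med_at((nn + 1L) %/% 2L + k_off)
  } else {
    (med_at(nn %/% 2L + k_off) + med_at(nn %/% 2L + 1L + k_off)) / 2
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  c_stat <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- ceiling((nn - c_stat) / 2)
  m2 <- nn - m1 + 1L
  ci_ok <- m1 >= 1 && (m2 + k_off) <= nn
  if (!ci_ok) warn("too few pairs for a Passing-Bablok slope CI at this level")
  slope_ci <- if (ci_ok) c(slopes[m1 + k_off], slopes[m2 + k_off]) else c(NA_real_, NA_real_)
  intercept <- median(y - slope * x)
  intercept_ci <- if (ci_ok) {
    c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x))
  } else {
    c(NA_real_, NA_real_)
  }
  r <- cor(x, y)
  structure(
    list(slope = slope, slope_ci = slope_ci,
         intercept = intercept, intercept_ci = intercept_ci,
         n = n, r = r, r_squared = r^2,
         rmse = sqrt(mean((y - x)^2)),
         conf_level = conf_level, n_slopes = nn, k_offset = k_off,
         data = tibble(reference = x, device = y)),
    class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("<Passing-Bablok> n = %d\n", x$n))
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]\n", x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  r = %.4f, R² = %.4f, RMSE = %.4f\n", x$r, x$r_squared, x$rmse))
  invisible(x)
}

#' @export
tidy.pb_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
         conf.high = c(x$intercept_ci[2], x$slope_ci[2]))
}

#' @export
glance.pb_fit <- function(x, ...) {
  tibble(n = x$n, r = x$r, r.squared = x$r_squared, rmse = x$rmse,
         conf.level = x$conf_level)
}

#' Plot a Passing-Bablok fit
#'
#' Scatter of device vs reference values with the regression line (blue)
#' and the identity line (dashed).
#'
#' @param object A `pb_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pb_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$reference, .data$device)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(x = "reference [Hb] (g/dL)", y = "device [Hb] (g/dL)",
                  title = sprintf("Passing-Bablok: slope %.4f, intercept %.4f",
                                  object$slope, object$intercept))
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `device - reference`. Bias = mean difference,
#' SD = sample SD of differences, limits of agreement = bias ± 1.96 SD.
#' The bias CI is `bias ± 1.96 * SD / sqrt(n)` and each LOA CI uses the
#' large-sample approximation `LOA ± 1.96 * SD * sqrt(3/n)`.
#'
#' @inheritParams passing_bablok
#' @return An object of class `ba_fit` supporting [tidy()], [glance()],
#'   [autoplot()]: `bias`, `sd`, `loa` (lower, upper), `bias_ci`,
#'   `loa_lower_ci`, `loa_upper_ci`, `n`.
#' @export
bland_altman <- function(data, reference = reference_hb, device = device_hb) {
  d <- dplyr::transmute(as_tibble(data), x = {{ reference }}, y = {{ device }})
  if (nrow(d) < 2L) stop_input("Bland-Altman analysis needs n >= 2 pairs")
  if (any(!is.finite(d$x)) || any(!is.finite(d$y))) {
    stop_input("paired values must be finite numeric")
  }
  diffs <- d$y - d$x
  n <- length(diffs)
  bias <- mean(diffs)
  s <- sd(diffs)
  loa <- c(bias - 1.96 * s, bias + 1.96 * s)
  half_bias <- 1.96 * s / sqrt(n)
  half_loa <- 1.96 * s * sqrt(3 / n)
  structure(
    list(bias = bias, sd = s, loa = loa,
         bias_ci = c(bias - half_bias, bias + half_bias),
         loa_lower_ci = c(loa[1] - half_loa, loa[1] + half_loa),
         loa_upper_ci = c(loa[2] - half_loa, loa[2] + half_loa),
         n = n,
         data = tibble(mean_hb = (d$x + d$y) / 2, diff = diffs)),
    class = "ba_fit")
}

#' @export
print.ba_fit <- function(x, ...) {
  cat(sprintf("<Bland-Altman> n = %d (device - reference)\n", x$n))
  cat(sprintf("  bias %.4f g/dL [%.4f, %.4f], SD %.4f\n",
              x$bias, x$bias_ci[1], x$bias_ci[2], x$sd))
  cat(sprintf("  LOA  [%.4f, %.4f]\n", x$loa[1], x$loa[2]))
  invisible(x)
}

#' @export
tidy.ba_fit <- function(x, ...) {
  tibble(term = c("bias", "loa_lower", "loa_upper"),
         estimate = c(x$bias, x$loa[1], x$loa[2]),
         conf.low = c(x$bias_ci[1], x$loa_lower_ci[1], x$loa_upper_ci[1]),
         conf.high = c(x$bias_ci[2], x$loa_lower_ci[2], x$loa_upper_ci[2]))
}

#' @export
glance.ba_fit <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd = x$sd,
         loa.lower = x$loa[1], loa.upper = x$loa[2])
}

#' Plot a Bland-Altman analysis
#'
#' Differences against pair means with the bias line (blue) and the
#' 1.96-SD limits of agreement (red, dashed).
#'
#' @param object A `ba_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean_hb, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$bias, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = object$loa, colour = "#b2182b",
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods (g/dL)", y = "device - reference (g/dL)",
                  title = sprintf("Bland-Altman: bias %.4f, LOA [%.4f, %.4f]",
                                  object$bias, object$loa[1], object$loa[2]))
}

#' Fraction of pairs agreeing within a clinical threshold
#'
#' Percentage of specimens with `|device - reference| <= threshold`,
#' reported to 1 decimal place (boundary inclusive).
#'
#' @inheritParams passing_bablok
#' @param threshold Agreement threshold (g/dL); default 1.0.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' d <- tibble::tibble(reference_hb = c(10, 10, 10, 10),
#'                     device_hb = c(10.5, 11, 11.5, 12))
#' within_threshold_fraction(d) # 50.0
within_threshold_fraction <- function(data, reference = reference_hb,
                                      device = device_hb, threshold = 1.0) {
  check_scalar_number(threshold, "threshold", lower = 0)
  d <- dplyr::transmute(as_tibble(data), x = {{ reference }}, y = {{ device }})
  if (nrow(d) < 1L) stop_input("need at least one pair")
  if (any(!is.finite(d$x)) || any(!is.finite(d$y))) {
    stop_input("paired values must be finite numeric")
  }
  round(100 * mean(abs(d$y - d$x) <= threshold), 1)
}
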