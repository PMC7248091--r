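# Fringe-phase lock-in demodulation: frame stack -> scalar sensor signal.
#
# Chain: vertical averaging of each frame into a 1-D scattering profile;
# spatial DFT and phase of the fringe component; temporal unwrapping and
# detrending of the phase trace; magnitude of the trace's Fourier
# component at the modulation frequency (the sensor signal, in rad).

#' Vertically averaged scattering profile of a frame
#'
#' @param frame Numeric matrix (rows = vertical pixels, columns =
#'   horizontal pixels).
#' @return Numeric vector of column means (length = image width).
#' @export
average_profile <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L) {
    stop_input("`frame` must be a non-empty numeric matrix")
  }
  colMeans(frame)
}

#' Locate the fringe bin in a scattering profile
#'
#' Band-restricted argmax of the discrete-Fourier magnitude of the
#' mean-subtracted profile. Ties resolve to the lowest bin.
#'
#' @param profile Numeric intensity profile.
#' @param band Integer vector `c(lo, hi)` of candidate spatial-frequency
#'   bins; must exclude bin 0 (DC) and bins at or above Nyquist. Default
#'   is `c(2, floor(length(profile)/4))`.
#' @return The fringe bin index (cycles per profile width).
#' @export
#' @examples
#' x <- 0:511
#' locate_fringe_bin(cos(2 * pi * 24 * x / 512)) # 24
locate_fringe_bin <- function(profile, band = NULL) {
  w <- length(profile)
  if (w < 8L || !is.numeric(profile) || any(!is.finite(profile))) {
    stop_input("`profile` must be a finite numeric vector of length >= 8")
  }
  nyq <- floor(w / 2)
  if (is.null(band)) band <- c(2L, max(2L, floor(w / 4)))
  if (length(band) != 2L || !all(is_whole(band)) || band[1] < 1 ||
      band[2] < band[1] || band[2] >= nyq) {
    stop_config("`band` must be c(lo, hi) with 1 <= lo <= hi < Nyquist")
  }
  bins <- seq.int(round(band[1]), round(band[2]))
  mag <- Mod(fft(profile - mean(profile)))[bins + 1L]
  if (max(mag) <= w * 1e-12 * max(1, max(abs(profile)))) {
    stop_numeric("no fringe component found in the search band")
  }
  bins[which.max(mag)]
}

#' Fourier phase of a profile's fringe component
#'
#' Argument of the positive-frequency Fourier coefficient at `bin`, with
#' the convention that a profile `c + a*cos(2*pi*f*x/W + phi)` (columns
#' `x = 0, ..., W-1`, `f = bin`) returns `phi` (mod `2*pi`).
#'
#' @param profile Numeric intensity profile.
#' @param bin Fringe bin, `0 < bin < Nyquist`.
#' @return Phase in rad, in `(-pi, pi]`.
#' @export
extract_phase <- function(profile, bin) {
  w <- length(profile)
  if (!is.numeric(profile) || w < 4L || any(!is.finite(profile))) {
    stop_input("`profile` must be a finite numeric vector")
  }
  if (!is_whole(bin) || bin <= 0 || bin >= w / 2) {
    stop_config("`bin` must be an integer in (0, Nyquist)")
  }
  coefficient <- fft(profile - mean(profile))[round(bin) + 1L]
  floor_mag <- w * 1e-12 * max(1, max(abs(profile)))
  if (Mod(coefficient) <= floor_mag) {
    stop_numeric("fringe coefficient magnitude below the numerical floor")
  }
  Arg(coefficient)
}

# Temporal unwrapping: add 2*pi multiples so successive steps have |d| <= pi.
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

# Remove mean and best-fit linear trend from an unwrapped trace.
#
# When an integer number of samples per modulation cycle is available the
# line is fitted to per-cycle means: this removes any constant + ramp
# exactly and is exactly null for a trace that is periodic at the
# modulation frequency, so detrending cannot leak into the lock-in bin.
# Otherwise an ordinary least-squares line over all samples is removed.
detrend_trace <- function(y, frame_rate, mod_freq) {
  n <- length(y)
  t <- (0:(n - 1)) / frame_rate
  per <- frame_rate / mod_freq
  n_cycles <- n / per
  if (!is.null(mod_freq) && is_whole(per) && is_whole(n_cycles) &&
      round(n_cycles) >= 1) {
    per <- round(per)
    n_cycles <- round(n_cycles)
    if (n_cycles == 1L) {
      return(y - mean(y))
    }
    g <- rep(seq_len(n_cycles), each = per)
    my <- tapply(y, g, mean)
    mt <- tapply(t, g, mean)
    beta <- sum((mt - mean(mt)) * (my - mean(my))) / sum((mt - mean(mt))^2)
    alpha <- mean(my) - beta * mean(mt)
  } else {
    fit <- stats::.lm.fit(cbind(1, t), y)
    alpha <- fit$coefficients[1]
    beta <- fit$coefficients[2]
  }
  y - (alpha + beta * t)
}

#' Unwrapped, detrended fringe-phase trace of a stack
#'
#' Extracts the fringe phase of every frame at a fixed bin, unwraps the
#' sequence temporally (successive steps forced to `|d| <= pi`), and
#' removes the mean and best-fit linear trend (thermal drift and the
#' arbitrary phase origin).
#'
#' @param stack A [frame_stack()].
#' @param bin Fringe bin, typically chosen once from the temporal-mean
#'   profile via [locate_fringe_bin()].
#' @return An object of class `phase_trace`: list with `phases` (rad,
#'   detrended), `frame_rate`, `fringe_bin` and `mod_freq`.
#' @export
phase_trace <- function(stack, bin) {
  stopifnot(inherits(stack, "frame_stack"))
  raw <- vapply(seq_along(stack$frames), function(i) {
    tryCatch(extract_phase(average_profile(stack$frames[[i]]), bin),
             ptashb_error = function(e) {
               stop_numeric(sprintf("frame %d: %s", i, conditionMessage(e)))
             })
  }, numeric(1))
  unwrapped <- unwrap_phase(raw)
  detrended <- detrend_trace(unwrapped, stack$frame_rate, stack$mod_freq)
  structure(list(phases = detrended, frame_rate = stack$frame_rate,
                 fringe_bin = round(bin), mod_freq = stack$mod_freq),
            class = "phase_trace")
}

#' Lock-in magnitude of a phase trace at the modulation frequency
#'
#' `2/N` times the DFT magnitude of the trace at the modulation bin, so a
#' pure sinusoid of amplitude `a` at `mod_freq` returns `a` (rad). The
#' modulation frequency should fall exactly on a DFT bin
#' (`mod_freq * N / frame_rate` integer); otherwise the nearest bin is
#' used with a warning.
#'
#' @param trace A [phase_trace()] (or any list with `phases` and
#'   `frame_rate`).
#' @param mod_freq Modulation frequency (Hz), below Nyquist. Defaults to
#'   the trace's recorded modulation frequency.
#' @return Lock-in signal (rad, >= 0).
#' @export
lockin_magnitude <- function(trace, mod_freq = trace$mod_freq) {
  y <- trace$phases
  fs <- trace$frame_rate
  n <- length(y)
  check_scalar_number(mod_freq, "mod_freq", lower = 0, strict_lower = TRUE)
  if (mod_freq >= fs / 2) stop_config("`mod_freq` must be below Nyquist (frame_rate/2)")
  bin <- mod_freq * n / fs
  if (!is_whole(bin)) {
    warn(sprintf("mod_freq %g Hz is not an exact DFT bin (bin %.3f); using nearest",
                 mod_freq, bin))
  }
  2 / n * Mod(fft(y)[round(bin) + 1L])
}

#' Measure the sensor signal of a frame stack
#'
#' End-to-end demodulation: averages all frames into a temporal-mean
#' profile, locates the fringe bin once in `band`, extracts and detrends
#' the per-frame phase trace, and reads out the lock-in magnitude at the
#' modulation frequency.
#'
#' @param stack A [frame_stack()].
#' @param mod_freq Modulation frequency (Hz); defaults to the stack's.
#' @param band Spatial-frequency search band `c(lo, hi)` passed to
#'   [locate_fringe_bin()].
#' @return One-row tibble: `signal` (rad), `mod_freq`, `fringe_bin`, and
#'   `quality` (ratio of the fringe-bin magnitude to the median spectral
#'   magnitude over the band; large is good).
#' @export
#' @examples
#' stk <- simulate_stack(11.2, noise = noise_model(seed = 1))
#' measure_stack(stk)
measure_stack <- function(stack, mod_freq = stack$mod_freq, band = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  profiles <- lapply(stack$frames, average_profile)
  mean_profile <- Reduce(`+`, profiles) / length(profiles)
  bin <- locate_fringe_bin(mean_profile, band)
  w <- length(mean_profile)
  if (is.null(band)) band <- c(2L, max(2L, floor(w / 4)))
  bins <- seq.int(round(band[1]), round(band[2]))
  mag <- Mod(fft(mean_profile - mean(mean_profile)))[bins + 1L]
  quality <- if (median(mag) > 0) max(mag) / median(mag) else Inf
  trace <- phase_trace(stack, bin)
  tibble(signal = lockin_magnitude(trace, mod_freq),
         mod_freq = mod_freq, fringe_bin = bin, quality = quality)
}

#' @export
print.phase_trace <- function(x, ...) {
  cat(sprintf("<phase_trace> %d samples at %.6g Hz, fringe bin %d, rms %.4g rad\n",
              length(x$phases), x$frame_rate, x$fringe_bin,
              sqrt(mean(x$phases^2))))
  invisible(x)
}

#' Plot a fringe-phase trace
#'
#' @param object A [phase_trace()].
#' @param ... Unused.
#' @return A ggplot of detrended phase (rad) against time (s).
#' @export
autoplot.phase_trace <- function(object, ...) {
  d <- tibble(time = (seq_along(object$phases) - 1) / object$frame_rate,
              phase = object$phases)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$phase)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "fringe phase (rad)")
}
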