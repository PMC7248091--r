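# Physics-based simulator of photothermal angular-scattering fringe stacks.
#
# A blood-filled capillary illuminated by a probe beam produces a
# semi-periodic angular fringe pattern on the detector. Modulated
# photothermal illumination heats the blood in proportion to its
# hemoglobin content, shifting the fringe phase. The simulator renders
# that pattern directly: row-constant cosine fringes whose phase
# oscillates with the (thermally low-passed) modulation waveform, with an
# amplitude that saturates with [Hb] according to a Hill response.

#' Optical acquisition configuration
#'
#' Geometry and radiometry of the simulated detector plus the acquisition
#' timing. Defaults are deliberately small (512 x 64 pixels) so that test
#' and simulation-study stacks are cheap; a full-HD sensor is obtained
#' with `optical_config(image_width = 1920, image_height = 1080,
#' fringe_frequency = 90)`.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param fringe_frequency Fringe spatial frequency in cycles per image
#'   width. Must lie in `[2, image_width/4]` so the fringe is resolvable
#'   and well below Nyquist.
#' @param base_phase Static fringe phase offset (rad).
#' @param mean_intensity Mean detector level (counts).
#' @param fringe_visibility Fringe contrast `(Imax - Imin)/(Imax + Imin)`,
#'   in `[0, 1]`.
#' @param frame_rate Acquisition rate (Hz).
#' @param duration Acquisition length (s). `frame_rate * duration` must be
#'   a positive integer (the frame count).
#' @return An object of class `optical_config`.
#' @export
#' @examples
#' opt <- optical_config()
#' opt$frame_rate * opt$duration # 150 frames
optical_config <- function(image_width = 512L, image_height = 64L,
                           fringe_frequency = 24, base_phase = 0.4,
                           mean_intensity = 1000, fringe_visibility = 0.7,
                           frame_rate = 30, duration = 5) {
  check_scalar_number(image_width, "image_width", lower = 8)
  check_scalar_number(image_height, "image_height", lower = 1)
  check_scalar_number(fringe_frequency, "fringe_frequency", lower = 2,
                      upper = image_width / 4)
  check_scalar_number(base_phase, "base_phase")
  check_scalar_number(mean_intensity, "mean_intensity", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(fringe_visibility, "fringe_visibility", lower = 0, upper = 1)
  check_scalar_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n_frames <- frame_rate * duration
  if (!is_whole(n_frames) || round(n_frames) < 1) {
    stop_config("`frame_rate * duration` must be a positive integer frame count")
  }
  structure(
    list(image_width = as.integer(round(image_width)),
         image_height = as.integer(round(image_height)),
         fringe_frequency = fringe_frequency, base_phase = base_phase,
         mean_intensity = mean_intensity, fringe_visibility = fringe_visibility,
         frame_rate = frame_rate, duration = duration),
    class = "optical_config"
  )
}

#' Photothermal response model
#'
#' Ground-truth response of the simulated instrument: the fringe-phase
#' excursion amplitude saturates with \eqn{[Hb]} following a Hill law
#' \eqn{\phi(\mathrm{Hb}) = \phi_{max} Hb^h / (K^h + Hb^h)}, and the
#' photothermal drive is an on/off PWM square wave smoothed by a
#' first-order thermal lag.
#'
#' @param phi_max Saturating phase-shift amplitude (rad). The default
#'   1.5 rad keeps the excursion below \eqn{\pi} so temporal unwrapping is
#'   unambiguous.
#' @param k_half Half-saturation concentration (g/dL).
#' @param hill_h Hill coefficient (dimensionless, > 0).
#' @param mod_freq Photothermal modulation frequency (Hz).
#' @param duty On-fraction of the PWM drive, in (0, 1).
#' @param thermal_tau First-order thermal time constant (s); 0 gives an
#'   ideal square wave.
#' @return An object of class `photothermal_model`.
#' @export
photothermal_model <- function(phi_max = 1.5, k_half = 9, hill_h = 1.2,
                               mod_freq = 1, duty = 0.5, thermal_tau = 0.05) {
  check_scalar_number(phi_max, "phi_max", lower = 0)
  check_scalar_number(k_half, "k_half", lower = 0, strict_lower = TRUE)
  check_scalar_number(hill_h, "hill_h", lower = 0, strict_lower = TRUE)
  check_scalar_number(mod_freq, "mod_freq", lower = 0, strict_lower = TRUE)
  check_scalar_number(duty, "duty", lower = 0, upper = 1, strict_lower = TRUE)
  if (duty >= 1) stop_config("`duty` must be in (0, 1)")
  check_scalar_number(thermal_tau, "thermal_tau", lower = 0)
  structure(
    list(phi_max = phi_max, k_half = k_half, hill_h = hill_h,
         mod_freq = mod_freq, duty = duty, thermal_tau = thermal_tau),
    class = "photothermal_model"
  )
}

#' Detector noise model
#'
#' Additive Gaussian read noise (counts) and optional Poisson shot noise
#' on the clean intensity; simulated values are clipped at zero. A fixed
#' `seed` makes a simulated stack bit-reproducible without disturbing the
#' caller's random stream.
#'
#' @param gaussian_sd Read-noise standard deviation (counts, >= 0).
#' @param shot_noise If `TRUE`, pixel values are Poisson-distributed about
#'   the clean intensity before read noise is added.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 30, shot_noise = FALSE, seed = NULL) {
  check_scalar_number(gaussian_sd, "gaussian_sd", lower = 0)
  if (!is.logical(shot_noise) || length(shot_noise) != 1L || is.na(shot_noise)) {
    stop_config("`shot_noise` must be TRUE or FALSE")
  }
  if (!is.null(seed)) check_scalar_number(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(list(gaussian_sd = gaussian_sd, shot_noise = shot_noise, seed = seed),
            class = "noise_model")
}

#' Hill-type phase-shift amplitude of the photothermal response
#'
#' @param hb Hemoglobin concentration (g/dL), vectorised, >= 0.
#' @param pt A [photothermal_model()].
#' @return Phase-shift amplitude(s) in rad, bounded by `pt$phi_max` and
#'   monotone nondecreasing in `hb`.
#' @export
#' @examples
#' pt <- photothermal_model(phi_max = 2, k_half = 8, hill_h = 2)
#' phase_amplitude(8, pt) # half saturation: 1 rad
phase_amplitude <- function(hb, pt) {
  stopifnot(inherits(pt, "photothermal_model"))
  if (!is.numeric(hb) || any(!is.finite(hb))) stop_input("`hb` must be finite numeric")
  if (any(hb < 0)) stop_input("`hb` must be >= 0 g/dL")
  h <- pt$hill_h
  pt$phi_max * hb^h / (pt$k_half^h + hb^h)
}

#' Thermally low-passed PWM modulation waveform
#'
#' Steady-state periodic response of a first-order thermal system (time
#' constant `thermal_tau`) to a 0/1 PWM square wave at `mod_freq` with the
#' stated duty cycle. Values lie in `[0, 1]`; `thermal_tau = 0` returns
#' the ideal square wave. The steady-state (rather than cold-start)
#' waveform is used so that simulated acquisitions are exactly periodic
#' over an integer number of modulation cycles.
#'
#' @param t Time(s) in seconds, >= 0; vectorised.
#' @param pt A [photothermal_model()].
#' @return Dimensionless drive level(s) in `[0, 1]`.
#' @export
modulation_waveform <- function(t, pt) {
  stopifnot(inherits(pt, "photothermal_model"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_input("`t` must be finite and >= 0")
  }
  period <- 1 / pt$mod_freq
  t_on <- pt$duty * period
  s <- t %% period
  if (pt$thermal_tau <= 0) {
    return(as.numeric(s < t_on))
  }
  tau <- pt$thermal_tau
  a <- exp(-t_on / tau)
  b <- exp(-(period - t_on) / tau)
  y0 <- b * (1 - a) / (1 - a * b)   # level at the start of the on-segment
  y1 <- 1 + (y0 - 1) * a            # level at the end of the on-segment
  on <- s < t_on
  y <- numeric(length(s))
  y[on] <- 1 + (y0 - 1) * exp(-s[on] / tau)
  y[!on] <- y1 * exp(-(s[!on] - t_on) / tau)
  y
}

#' Fundamental amplitude of the realized modulation waveform
#'
#' Amplitude of the Fourier component at `mod_freq` of the modulation
#' waveform as actually sampled by the acquisition (so it includes both
#' the thermal low-pass attenuation and any aliasing of higher harmonics
#' onto the modulation bin). This is the ground-truth conversion factor
#' between the Hill phase amplitude and the lock-in sensor signal for a
#' noiseless stack.
#'
#' @param pt A [photothermal_model()].
#' @param frame_rate Sampling rate (Hz).
#' @param duration Acquisition length (s); `mod_freq * duration` must be a
#'   positive integer number of cycles.
#' @return Dimensionless fundamental amplitude (for an ideal 0/1 square
#'   wave at 50% duty this is `2/pi`).
#' @export
waveform_fundamental <- function(pt, frame_rate = 30, duration = 5) {
  stopifnot(inherits(pt, "photothermal_model"))
  n <- frame_rate * duration
  if (!is_whole(n) || round(n) < 2) stop_config("frame_rate * duration must be an integer >= 2")
  n <- round(n)
  bin <- pt$mod_freq * duration
  if (!is_whole(bin) || round(bin) < 1) {
    stop_config("`mod_freq * duration` must be a positive integer number of cycles")
  }
  w <- modulation_waveform((0:(n - 1)) / frame_rate, pt)
  2 / n * Mod(fft(w)[round(bin) + 1L])
}

#' Simulate a photothermal scattering-fringe image stack
#'
#' Renders the acquisition of a blood sample of concentration `hb`:
#' row-constant cosine fringes whose phase is
#' `base_phase + phase_amplitude(hb) * modulation_waveform(t)`, plus
#' detector noise. Identical inputs (including the noise seed) give a
#' bit-identical stack.
#'
#' @param hb Hemoglobin concentration (g/dL, scalar >= 0).
#' @param optical An [optical_config()].
#' @param photothermal A [photothermal_model()]; its modulation frequency
#'   must complete an integer number of cycles over the acquisition and
#'   lie below the frame-rate Nyquist limit.
#' @param noise A [noise_model()].
#' @return A `frame_stack`: list with `frames` (list of
#'   `image_height x image_width` matrices, counts), `frame_rate`,
#'   `duration` and `mod_freq`.
#' @export
#' @examples
#' stk <- simulate_stack(11.2, noise = noise_model(seed = 7))
#' length(stk$frames)
simulate_stack <- function(hb, optical = optical_config(),
                           photothermal = photothermal_model(),
                           noise = noise_model()) {
  stopifnot(inherits(optical, "optical_config"),
            inherits(photothermal, "photothermal_model"),
            inherits(noise, "noise_model"))
  check_scalar_number(hb, "hb", lower = 0)
  n_cycles <- photothermal$mod_freq * optical$duration
  if (!is_whole(n_cycles) || round(n_cycles) < 1) {
    stop_config("`mod_freq * duration` must be a positive integer number of cycles")
  }
  if (photothermal$mod_freq >= optical$frame_rate / 2) {
    stop_config("`mod_freq` must be below the frame-rate Nyquist limit")
  }
  n <- round(optical$frame_rate * optical$duration)
  t <- (0:(n - 1)) / optical$frame_rate
  amp <- phase_amplitude(hb, photothermal)
  phases <- optical$base_phase + amp * modulation_waveform(t, photothermal)
  w <- optical$image_width
  h <- optical$image_height
  x <- 0:(w - 1)
  carrier <- 2 * pi * optical$fringe_frequency * x / w
  frames <- with_seed(noise$seed, {
    lapply(seq_len(n), function(i) {
      profile <- optical$mean_intensity *
        (1 + optical$fringe_visibility * cos(carrier + phases[i]))
      frame <- matrix(profile, nrow = h, ncol = w, byrow = TRUE)
      if (noise$shot_noise) {
        frame[] <- rpois(length(frame), lambda = frame)
      }
      if (noise$gaussian_sd > 0) {
        frame <- frame + rnorm(length(frame), sd = noise$gaussian_sd)
      }
      frame[frame < 0] <- 0
      frame
    })
  })
  frame_stack(frames, frame_rate = optical$frame_rate,
              duration = optical$duration, mod_freq = photothermal$mod_freq)
}

#' Construct a frame stack
#'
#' Container for a time-ordered sequence of 2-D intensity frames plus the
#' acquisition metadata needed downstream.
#'
#' @param frames List of numeric matrices with identical dimensions and
#'   non-negative values.
#' @param frame_rate Acquisition rate (Hz).
#' @param duration Acquisition length (s); `round(frame_rate * duration)`
#'   must equal `length(frames)`.
#' @param mod_freq Photothermal modulation frequency (Hz).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, duration, mod_freq) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_input("`frames` must be a non-empty list of matrices")
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) stop_input("each frame must be a numeric matrix")
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_input("all frames must share the same dimensions")
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    stop_input("frame intensities must be >= 0")
  }
  check_scalar_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar_number(mod_freq, "mod_freq", lower = 0, strict_lower = TRUE)
  if (round(frame_rate * duration) != length(frames)) {
    stop_input("frame count must equal round(frame_rate * duration)")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 duration = duration, mod_freq = mod_freq),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.6g Hz for %.6g s, mod %.6g Hz\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$duration, x$mod_freq))
  invisible(x)
}
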