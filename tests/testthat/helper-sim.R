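# Small, fast instrument configurations used throughout the unit tests.
# 128 x 8 px frames, 30 Hz for 2 s (60 frames, 2 modulation cycles).

small_optical <- function(...) {
  optical_config(image_width = 128L, image_height = 8L, fringe_frequency = 12,
                 frame_rate = 30, duration = 2, ...)
}

quiet_noise <- function(seed = NULL) noise_model(gaussian_sd = 0, seed = seed)

# A bare phase trace object (already detrended input assumed), for
# feeding lockin_magnitude directly.
make_trace <- function(phases, frame_rate = 30, mod_freq = 1) {
  structure(list(phases = phases, frame_rate = frame_rate,
                 fringe_bin = 12L, mod_freq = mod_freq),
            class = "phase_trace")
}

# Independent brute-force Passing-Bablok oracle: explicit loops, explicit
# rank bookkeeping, no shared code with the implementation.
pb_oracle <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(slopes)
  nn <- length(slopes)
  k <- 0
  for (s in slopes) if (s < -1) k <- k + 1
  if (nn %% 2 == 1) {
    b <- slopes[(nn + 1) / 2 + k]
  } else {
    b <- (slopes[nn / 2 + k] + slopes[nn / 2 + 1 + k]) / 2
  }
  a <- median(y - b * x)
  list(slope = b, intercept = a)
}
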