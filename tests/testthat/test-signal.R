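# Demodulation chain: profiles, fringe location, phase, trace, lock-in.

test_that("average_profile takes column means", {
  frame <- rbind(c(1, 2, 3), c(3, 4, 5))
  expect_equal(average_profile(frame), c(2, 3, 4))
  const <- matrix(rep(c(1, 5, 9), each = 4), nrow = 4)
  expect_equal(average_profile(const), c(1, 5, 9))
  expect_equal(average_profile(matrix(0, 3, 5)), rep(0, 5))
  expect_error(average_profile(matrix(numeric(0), 0, 0)),
               class = "ptashb_input_error")
})

test_that("locate_fringe_bin finds the dominant in-band tone", {
  x <- 0:511
  expect_identical(locate_fringe_bin(cos(2 * pi * 24 * x / 512)), 24L)
  # band restriction: only the in-band tone counts
  two_tone <- cos(2 * pi * 10 * x / 512) + 2 * cos(2 * pi * 40 * x / 512)
  expect_identical(locate_fringe_bin(two_tone, band = c(5, 20)), 10L)
  expect_identical(locate_fringe_bin(two_tone, band = c(30, 60)), 40L)
  # degenerate: pure DC has no fringe
  expect_error(locate_fringe_bin(rep(7, 512)), class = "ptashb_numeric_error")
  expect_error(locate_fringe_bin(cos(x), band = c(0, 10)),
               class = "ptashb_config_error")
})

test_that("extract_phase matches the analytic Fourier phase", {
  x <- 0:511
  expect_equal(extract_phase(cos(2 * pi * 24 * x / 512 + 0.7), 24), 0.7,
               tolerance = 1e-9)
  expect_equal(extract_phase(cos(2 * pi * 24 * x / 512), 24), 0,
               tolerance = 1e-9)
  # Fourier shift theorem: profile delayed by one pixel loses 2*pi*bin/W
  p0 <- cos(2 * pi * 24 * (x - 1) / 512 + 0.7)
  expect_equal(extract_phase(p0, 24), 0.7 - 2 * pi * 24 / 512, tolerance = 1e-9)
  # exactness across bins and phases for single tones at integer bins
  for (bin in c(5L, 12L, 50L)) {
    for (phi in c(-2.5, -0.3, 0.1, 1.9)) {
      got <- extract_phase(3 + 0.5 * cos(2 * pi * bin * x / 512 + phi), bin)
      expect_equal(Arg(exp(1i * (got - phi))), 0, tolerance = 1e-9)
    }
  }
  expect_error(extract_phase(rep(1, 64), 8), class = "ptashb_numeric_error")
})

test_that("phase traces unwrap 2*pi jumps and detrend drift", {
  # wrapped jump: 3.0, 3.2, -3.0 unwraps to 3.0, 3.2, 2*pi - 3.0
  x <- 0:127
  mk <- function(phi) matrix(1000 * (1 + 0.7 * cos(2 * pi * 12 * x / 128 + phi)),
                             nrow = 2, ncol = 128, byrow = TRUE)
  stk <- frame_stack(lapply(c(3.0, 3.2, -3.0), mk),
                     frame_rate = 3, duration = 1, mod_freq = 1)
  tr <- phase_trace(stk, 12)
  raw <- tr$phases - mean(tr$phases) # detrend = mean-removal here (1 cycle)
  expect_equal(diff(raw), diff(c(3.0, 3.2, -3.0 + 2 * pi)), tolerance = 1e-9)

  # constant phase: all-zero trace after detrend
  stk_const <- frame_stack(lapply(rep(0.4, 30), mk),
                           frame_rate = 30, duration = 1, mod_freq = 1)
  expect_equal(phase_trace(stk_const, 12)$phases, rep(0, 30), tolerance = 1e-12)

  # pure linear drift: removed exactly by detrending
  drift <- seq(0, 0.9, length.out = 60)
  stk_drift <- frame_stack(lapply(0.2 + drift, mk),
                           frame_rate = 30, duration = 2, mod_freq = 1)
  expect_equal(phase_trace(stk_drift, 12)$phases, rep(0, 60), tolerance = 1e-9)
})

test_that("lock-in magnitude is normalized to sinusoid amplitude", {
  t <- (0:149) / 30
  expect_equal(lockin_magnitude(make_trace(0.1 * sin(2 * pi * t)), 1), 0.1)
  expect_equal(lockin_magnitude(make_trace(rep(0, 150)), 1), 0)
  # zero-mean +/- a square at mod_freq: fundamental (4/pi)*a, up to the
  # discrete-edge correction 1/(15*sin(pi/30)) vs 2/pi at 30 Hz sampling
  sq <- 0.2 * sign(sin(2 * pi * t + 1e-9))
  expect_equal(lockin_magnitude(make_trace(sq), 1), (4 / pi) * 0.2,
               tolerance = 2e-3)
  expect_error(lockin_magnitude(make_trace(sq), 15), class = "ptashb_config_error")
  expect_warning(lockin_magnitude(make_trace(sq), 1.1), "not an exact DFT bin")
  # 150 frames at 30 Hz: 0.2 Hz resolution puts 1 Hz exactly on bin 5
  expect_true((1 * 150 / 30) %% 1 == 0)
})

test_that("noiseless stacks round-trip phase amplitude x waveform fundamental", {
  opt <- optical_config()
  for (tau in c(0, 0.05)) {
    pt <- photothermal_model(thermal_tau = tau)
    stk <- simulate_stack(11.2, opt, pt, quiet_noise())
    expect_equal(measure_stack(stk)$signal,
                 phase_amplitude(11.2, pt) * waveform_fundamental(pt, 30, 5),
                 tolerance = 1e-6)
  }
  # ideal square drive also matches the continuous-time 2/pi fundamental
  # to within the sampling discretization of the square edge
  pt0 <- photothermal_model(thermal_tau = 0)
  s0 <- measure_stack(simulate_stack(11.2, opt, pt0, quiet_noise()))$signal
  expect_equal(s0, (2 / pi) * phase_amplitude(11.2, pt0), tolerance = 2e-3)
})

test_that("pipeline signal is linear in amplitude and monotone in hb", {
  opt <- small_optical()
  pt1 <- photothermal_model(phi_max = 0.4)
  pt2 <- photothermal_model(phi_max = 0.8)
  s1 <- measure_stack(simulate_stack(30, opt, pt1, quiet_noise()))$signal
  s2 <- measure_stack(simulate_stack(30, opt, pt2, quiet_noise()))$signal
  # hb = 30 drives both models at the same Hill fraction; amplitude doubles
  expect_equal(s2 / s1, 2, tolerance = 1e-6)
  sig <- vapply(seq(0, 30, length.out = 7), function(hb) {
    measure_stack(simulate_stack(hb, opt, photothermal_model(), quiet_noise()))$signal
  }, numeric(1))
  expect_true(all(diff(sig) >= -1e-9))
})

test_that("signal is invariant to intensity scaling and trace offsets/ramps", {
  opt <- small_optical()
  stk <- simulate_stack(11.2, opt, noise = quiet_noise())
  scaled <- frame_stack(lapply(stk$frames, function(f) 3.7 * f),
                        stk$frame_rate, stk$duration, stk$mod_freq)
  expect_equal(measure_stack(scaled)$signal, measure_stack(stk)$signal,
               tolerance = 1e-9)
  # adding a constant and a ramp to the true phase trace changes nothing
  t <- (0:59) / 30
  base <- 0.3 * sin(2 * pi * t)
  phase_trace_from <- function(p) {
    x <- 0:127
    frames <- lapply(p, function(phi) {
      matrix(1000 * (1 + 0.7 * cos(2 * pi * 12 * x / 128 + phi)),
             nrow = 2, ncol = 128, byrow = TRUE)
    })
    stk <- frame_stack(frames, 30, 2, 1)
    measure_stack(stk)$signal
  }
  expect_equal(phase_trace_from(base + 0.8 + 0.05 * t), phase_trace_from(base),
               tolerance = 1e-9)
})

test_that("measuring the same stack twice is deterministic; hb=0 is at the floor", {
  stk <- simulate_stack(11.2, small_optical(),
                        noise = noise_model(gaussian_sd = 20, seed = 2))
  expect_identical(measure_stack(stk), measure_stack(stk))
  blank <- simulate_stack(0, small_optical(), noise = quiet_noise())
  expect_lt(measure_stack(blank)$signal, 1e-9)
})
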