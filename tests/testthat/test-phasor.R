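test_that("DC removal nulls a constant and passes the band", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  out <- remove_dc(rep(1, length(t)), fs)
  expect_lt(max(abs(out[2000:18000])), 1e-3)

  y <- remove_dc(sin(2 * pi * 1 * t), fs)
  expect_equal(amplitude_peaks(y[3000:18000]), 1, tolerance = 0.01)
})

test_that("DC removal attenuates 0.01 Hz by at least 20 dB", {
  fs <- 200
  t <- seq(0, 300, by = 1 / fs)
  y <- remove_dc(sin(2 * pi * 0.01 * t), fs)
  expect_lt(max(abs(y[5000:55000])), 10^(-20 / 20))
})

test_that("DC removal is idempotent in the passband and errors on tiny input", {
  fs <- 1000
  x <- sin(2 * pi * 5 * seq(0, 10, by = 1 / fs))
  once <- remove_dc(x, fs)
  twice <- remove_dc(once, fs)
  core <- 2000:8000
  expect_lt(max(abs(twice[core] - once[core])) / max(abs(once[core])), 1e-3)

  expect_error(remove_dc(rep(1, 5), fs), "short")
  expect_warning(remove_dc(sin(2 * pi * 50 * seq(0, 1, by = 1e-3)), 1000),
                 "reduced")
})

test_that("amplitude from cycle extrema is accurate and invariant", {
  t <- seq(0, 1, by = 1e-4)
  x <- 2 * sin(2 * pi * 10 * t)
  expect_equal(amplitude_peaks(x), 2, tolerance = 0.005)
  # time-shift and sign-flip invariance
  expect_equal(amplitude_peaks(2 * sin(2 * pi * 10 * t + 1.1)),
               amplitude_peaks(x), tolerance = 0.005)
  expect_equal(amplitude_peaks(-x), amplitude_peaks(x))
  # a 5 Vpp source waveform has amplitude 2.5
  expect_equal(amplitude_peaks(2.5 * sin(2 * pi * 10 * t)), 2.5,
               tolerance = 0.005)
  expect_error(amplitude_peaks(rep(0.5, 100)), "no detectable oscillation")
})

test_that("amplitude estimate tolerates mild noise", {
  set.seed(42)
  t <- seq(0, 1, by = 1e-4)
  x <- 2 * sin(2 * pi * 10 * t) + rnorm(length(t), 0, 0.02)
  expect_equal(amplitude_peaks(x), 2, tolerance = 0.02)
})

test_that("Lissajous phase reads the y-intercept correctly", {
  sp0 <- synth_sinusoid_pair(50, 5000, 0.2, 0)
  expect_equal(phase_lissajous(sp0$x, sp0$x), 0)

  sp90 <- synth_sinusoid_pair(50, 5000, 0.2, 90)
  expect_equal(as.numeric(suppressWarnings(phase_lissajous(sp90$x, sp90$y))),
               90, tolerance = 0.5)

  sp30 <- synth_sinusoid_pair(100, 1e4, 0.1, 30)
  expect_equal(phase_lissajous(sp30$x, sp30$y), 30, tolerance = 0.5)
})

test_that("Lissajous clamps to 90 degrees when distortion inflates y0", {
  # y is a 90-degree-shifted copy whose alternate half-cycles are
  # attenuated, so the mean cycle amplitude Y0 dips below the
  # zero-crossing reading y0 and the arcsin argument exceeds 1
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * t)
  y <- cos(2 * pi * t) * (1 - 0.3 * sin(pi * t)^2)
  expect_warning(th <- phase_lissajous(x, y), "clamped")
  expect_equal(as.numeric(th), 90)
  expect_true(attr(th, "clamped"))
})

test_that("cross-correlation phase follows the lag formula", {
  sp <- synth_sinusoid_pair(100, 1e4, 0.1, 0)
  expect_equal(phase_xcorr(sp$x, sp$x, 100, 1e4), 0)

  # a pure 10-sample shift at f = 10, fs = 3600 is exactly 10 degrees
  fs <- 3600
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * (t + 10 / fs))
  expect_equal(phase_xcorr(x, y, 10, fs), 10)

  sp45 <- synth_sinusoid_pair(100, 1e4, 0.1, 45)
  expect_lt(abs(phase_xcorr(sp45$x, sp45$y, 100, 1e4) - 45), 3.6 / 2 + 1e-9)

  expect_error(phase_xcorr(rep(1, 100), rep(1, 100), 10, 1000), "constant")
  expect_error(phase_xcorr(x, y, 10, 70), "< 8")
  expect_warning(phase_xcorr(sin(2 * pi * 10 * (0:99) / 500),
                             sin(2 * pi * 10 * (0:99) / 500), 10, 500),
                 "resolution")
})

test_that("phasor extraction combines magnitude and phase correctly", {
  sp <- synth_sinusoid_pair(100, 1e4, 0.1, 30, amplitudes = c(1, 2))
  for (m in c("lissajous", "xcorr")) {
    p <- waveform_to_phasor(sp$y, sp$x, 100, 1e4, method = m)
    expect_equal(p$magnitude, 2, tolerance = 0.005)
    expect_equal(p$phase_deg, 30, tolerance = 2)
  }
  p0 <- waveform_to_phasor(sp$x, sp$x, 100, 1e4)
  expect_equal(p0$phase_deg, 0, tolerance = 1e-6)
  # both methods agree on a clean pair
  pl <- waveform_to_phasor(sp$y, sp$x, 100, 1e4, "lissajous")
  px <- waveform_to_phasor(sp$y, sp$x, 100, 1e4, "xcorr")
  expect_lt(abs(pl$phase_deg - px$phase_deg), 1)
})

test_that("arcsin quadrant ambiguity is resolved by the correlation sign", {
  sp <- synth_sinusoid_pair(100, 1e4, 0.1, 120)
  # the raw Lissajous estimate folds 120 onto 60 ...
  expect_equal(as.numeric(phase_lissajous(sp$x, sp$y)), 60, tolerance = 0.5)
  # ... and the disambiguated phasor recovers the true quadrant
  p <- waveform_to_phasor(sp$y, sp$x, 100, 1e4, "lissajous")
  expect_equal(p$phase_deg, 120, tolerance = 1)
})

test_that("the two phase estimators agree across random phases", {
  set.seed(5)
  phases <- stats::runif(10, -85, 85)
  f <- 10; fs <- 1000
  for (ph in phases) {
    sp <- synth_sinusoid_pair(f, fs, 0.5, ph)
    pl <- phase_lissajous(sp$x, sp$y)
    px <- phase_xcorr(sp$x, sp$y, f, fs)
    expect_lt(abs(as.numeric(pl) - px), max(1, 360 * f / fs))
  }
})

test_that("phasor arithmetic helpers are consistent", {
  p <- phasor(2, 45, 10)
  z <- phasor_to_complex(p)
  expect_equal(Mod(z), 2)
  expect_equal(Arg(z) * 180 / pi, 45)
  back <- as_phasor(z, 10)
  expect_equal(back$magnitude, p$magnitude)
  expect_equal(back$phase_deg, p$phase_deg)
  expect_equal(as_phasor(complex(real = 0, imaginary = -1), 1)$phase_deg, -90)
})
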