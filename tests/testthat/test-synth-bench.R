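test_that("resistive circuit ground truth is plain divider arithmetic", {
  circ <- circuit_spec(10e3, z_tissue = 1e3, r_ref = 1e3,
                       frequencies = c(1, 10, 100))
  for (cfg in c("A", "B")) {
    sw <- simulate_sweep(circ, cfg)
    expect_equal(Mod(sw$z_sum), rep(11e3, 3))
    expect_equal(Mod(sw$z_12), rep(21e3, 3))
    expect_equal(Arg(sw$z_sum), rep(0, 3))
  }
})

test_that("zero contact impedance collapses Z_12 onto Z_sum", {
  circ <- circuit_spec(0, z_tissue = 1e3, frequencies = c(1, 100))
  sw <- simulate_sweep(circ, "A")
  expect_equal(sw$z_12, sw$z_sum)
})

test_that("Cole-contact sweep truth matches a closed-form oracle at 0.1 Hz", {
  p <- cole_reference_params()
  circ <- circuit_spec(p, frequencies = c(0.1, 1))
  sw <- simulate_sweep(circ, "A")
  zo <- oracle_cole_z(0.1, 35.065e3, 3.701e6, 15.129e-9, 0.8397)
  expect_lt(Mod(sw$z_contact[1] - zo) / Mod(zo), 1e-9)
})

test_that("ground-truth phasors satisfy Kirchhoff's voltage law exactly", {
  p <- cole_reference_params()
  for (cfg in c("A", "B")) {
    sw <- simulate_sweep(circuit_spec(p, frequencies = c(0.1, 10, 1e3)), cfg)
    vg <- complex(real = 2.5, imaginary = 0)
    loop_drop <- sw$i_true * (sw$z_12 + 1000)
    expect_lt(max(Mod(vg - loop_drop)) / 2.5, 1e-12)
  }
})

test_that("sampling-rate policy rejects frequencies it cannot resolve", {
  expect_equal(sweep_fs(0.1), 1000)
  expect_equal(sweep_fs(100), 5000)
  expect_equal(sweep_fs(1e4), 5e5)
  expect_error(sweep_fs(1e5), "incompatible")
})

test_that("sweep waveforms hold at least 10 full cycles", {
  sw <- simulate_sweep(circuit_spec(1e3, frequencies = c(0.5, 50)), "A")
  for (i in seq_len(nrow(sw))) {
    w <- sw$waveform[[i]]
    expect_gte(nrow(w) / (sw$fs[i] / sw$f_hz[i]), 10)
    expect_named(w, c("t", "v_g", "v_r", "v_probe"))
  }
})

test_that("sinusoid pair reproduces the analytic waveform", {
  sp <- synth_sinusoid_pair(100, 1e4, 0.05, phase_deg = 0, amplitudes = c(1, 2))
  expect_equal(sp$y, 2 * sp$x, tolerance = 1e-12)

  sp90 <- synth_sinusoid_pair(100, 1e4, 0.05, phase_deg = 90)
  expect_equal(sp90$y, cos(2 * pi * 100 * sp90$t), tolerance = 1e-12)

  sp30 <- synth_sinusoid_pair(100, 1e4, 0.05, phase_deg = 30, amplitudes = c(1, 2))
  expect_equal(sp30$y[1], 2 * sin(30 * pi / 180))

  expect_error(synth_sinusoid_pair(100, 150, 1, 0), "alias")
})

test_that("synthetic ECG beat count tracks rate times time", {
  rec <- synth_ecg(ecg_synth_spec(duration = 60, heart_rate = 60))
  n_beats <- length(unique(rec$annotations$beat))
  expect_true(abs(n_beats - 60) <= 1)

  rec2 <- synth_ecg(ecg_synth_spec(duration = 30, heart_rate = 100))
  expect_true(abs(length(unique(rec2$annotations$beat)) - 50) <= 1)
})

test_that("corruption suppresses the stated fraction of beats, test channel only", {
  rec <- synth_ecg(ecg_synth_spec(duration = 60, heart_rate = 60,
                                  powerline = c(`60` = 0, `120` = 0),
                                  baseline_wander = list(amplitude = 0,
                                                         frequency = 0.25),
                                  white_noise_sd = 0.005,
                                  corruption = list(wave = "p", fraction = 0.1)))
  n_beats <- length(unique(rec$annotations$beat))
  supp <- dplyr::filter(rec$annotations, suppressed_test)
  expect_equal(nrow(supp), round(0.1 * n_beats))
  expect_true(all(supp$wave == "p"))
  # the suppressed P waves are genuinely absent from the test channel:
  # local test-channel amplitude at those fiducials is far below the P wave
  amp_at <- function(ch, idx) abs(rec$signals[[ch]][idx])
  expect_lt(mean(amp_at("test_mv", supp$index)), 0.5 * 0.15)
})

test_that("powerline component carries the expected tone power", {
  spec <- ecg_synth_spec(
    duration = 30, heart_rate = 60,
    wave_amplitudes = c(p = 0, q = 0, r = 0, s = 0, t = 0),
    powerline = c(`60` = 0.4, `120` = 0),
    baseline_wander = list(amplitude = 0, frequency = 0.25),
    white_noise_sd = 0
  )
  rec <- synth_ecg(spec)
  a_est <- oracle_tone_amplitude(rec$signals$test_mv, rec$signals$t, 60)
  expect_equal(a_est^2 / 2, 0.4^2 / 2, tolerance = 0.02)
})

test_that("ECG fiducials are strictly ordered within each beat", {
  rec <- synth_ecg(ecg_synth_spec(duration = 20, heart_rate = 90))
  ord <- rec$annotations |>
    dplyr::mutate(wave = factor(wave, c("p", "q", "r", "s", "t"))) |>
    dplyr::arrange(beat, wave) |>
    dplyr::group_by(beat) |>
    dplyr::summarise(ok = all(diff(index) > 0))
  expect_true(all(ord$ok))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- synth_ecg(ecg_synth_spec(duration = 5, seed = 7))
  b <- synth_ecg(ecg_synth_spec(duration = 5, seed = 7))
  c <- synth_ecg(ecg_synth_spec(duration = 5, seed = 8))
  expect_identical(a$signals, b$signals)
  expect_false(identical(a$signals$test_mv, c$signals$test_mv))

  pa <- synth_polarization(polarization_synth_spec(duration = 30, seed = 3))
  pb <- synth_polarization(polarization_synth_spec(duration = 30, seed = 3))
  expect_identical(pa, pb)
})

test_that("polarization series matches its specification", {
  const <- synth_polarization(polarization_synth_spec(
    duration = 60, dc_offset = 15.4, drift_rate = 0, noise_sd = 0))
  expect_equal(const$potential_mv, rep(15.4, 600))

  long <- synth_polarization(polarization_synth_spec(duration = 1800))
  expect_equal(nrow(long), 18000)

  # mean of the noise-free component = offset + drift midpoint
  drifting <- synth_polarization(polarization_synth_spec(
    duration = 600, dc_offset = 10, drift_rate = 1.2, noise_sd = 0))
  midpoint <- 10 + 1.2 * (600 - 0.1) / 2 / 60
  expect_equal(mean(drifting$potential_mv), midpoint, tolerance = 1e-10)
})

test_that("i.i.d. polarization noise has the closed-form exchange ratio", {
  # E|X - Y| = 2 sigma / sqrt(pi) for X, Y ~ N(mu, sigma^2) independent
  pol <- synth_polarization(polarization_synth_spec(
    duration = 1800, dc_offset = 0, drift_rate = 0, noise_sd = 100, seed = 11))
  expect_equal(mean(abs(diff(pol$potential_mv))) * 1000,
               2 * 100 / sqrt(pi), tolerance = 0.02)
})
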