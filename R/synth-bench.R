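# Synthetic measurement bench: every input the analysis pipeline consumes
# is generated here with known ground truth, so the full chain is testable
# without any recorded data.

#' Measurement circuit specification
#'
#' Describes the series circuit used by the two sweep configurations: an AC
#' source (5 Vpp by default) drives a current through electrode contact
#' impedances, a shared tissue impedance and a reference resistor. The
#' three electrodes are assumed to have identical contact impedances, the
#' assumption the subtraction algebra `Z_12 = 2 Z_contact + Z_tissue`
#' requires.
#'
#' @param z_contact_model Per-electrode contact impedance: either a
#'   [cole_params] object (frequency dependent) or a single numeric /
#'   complex value (frequency independent).
#' @param z_tissue Tissue impedance between adjacent electrode sites: a
#'   resistive scalar (ohm, default 1000) or a complex vector matched to
#'   `frequencies`.
#' @param r_ref Reference resistance in ohm, `> 0`.
#' @param v_source_pp Source amplitude, volt peak-to-peak (default 5).
#' @param frequencies Sweep frequencies in Hz, strictly positive and
#'   strictly increasing (default [freq_grid()]).
#' @return An object of class `circuit_spec`.
#' @examples
#' circuit_spec(cole_reference_params())
#' @export
circuit_spec <- function(z_contact_model, z_tissue = 1000, r_ref = 1000,
                         v_source_pp = 5, frequencies = freq_grid()) {
  stopifnot(
    r_ref > 0, v_source_pp > 0,
    all(frequencies > 0), all(diff(frequencies) > 0),
    length(z_tissue) %in% c(1, length(frequencies))
  )
  if (!inherits(z_contact_model, "cole_params") &&
      !(is.numeric(z_contact_model) || is.complex(z_contact_model)) ) {
    stop("z_contact_model must be a cole_params object or a numeric/complex scalar")
  }
  structure(
    list(z_contact_model = z_contact_model, z_tissue = z_tissue,
         r_ref = r_ref, v_source_pp = v_source_pp,
         frequencies = frequencies),
    class = "circuit_spec"
  )
}

# contact impedance of one electrode over the circuit's frequencies
circuit_contact_z <- function(circuit, f) {
  if (inherits(circuit$z_contact_model, "cole_params")) {
    cole_impedance(circuit$z_contact_model, f)
  } else {
    rep(as.complex(circuit$z_contact_model), length(f))
  }
}

#' Sampling rate policy for impedance sweeps
#'
#' `fs = max(1 kHz, 50 f)`, capped at 1 MHz. The policy resolves phase at
#' 10 kHz (50 samples per cycle) while keeping 0.1 Hz records tractable.
#' Frequencies whose capped rate would give fewer than 20 samples per
#' cycle are rejected.
#'
#' @param f Frequency in Hz.
#' @return Sampling rate in Hz.
#' @export
sweep_fs <- function(f) {
  fs <- pmin(pmax(1000, 50 * f), 1e6)
  bad <- fs / f < 20
  if (any(bad)) {
    stop("frequency ", paste(f[bad], collapse = ", "),
         " Hz incompatible with the sampling-rate policy (< 20 samples/cycle)")
  }
  fs
}

#' Simulate a two-configuration impedance sweep
#'
#' Generates, per frequency, the sampled source, reference-resistor and
#' probe waveforms of the chosen measurement configuration, with the exact
#' circuit phasors attached as ground truth.
#'
#' In configuration A the source drives electrode 3 and the probe reads
#' electrode 2 through a high-impedance input, so the probe-to-resistor
#' difference spans one contact impedance plus the tissue:
#' `Z_sum = Z_contact + Z_tissue`. In configuration B the source drives
#' electrode 2 directly and `V21 = Vg - Vr` spans both contacts:
#' `Z_12 = 2 Z_contact + Z_tissue`.
#'
#' @param circuit A [circuit_spec].
#' @param config `"A"` or `"B"`.
#' @param n_cycles Number of full cycles per record (>= 10).
#' @param noise_sd Additive Gaussian noise on the sampled waveforms (volt).
#' @param seed Optional integer seed (only used when `noise_sd > 0`).
#' @return A tibble with one row per frequency: `f_hz`, `fs`, `config`,
#'   `waveform` (list column of tibbles `t`, `v_g`, `v_r`, `v_probe`), and
#'   ground-truth complex columns `z_contact`, `z_sum`, `z_12`, `i_true`,
#'   `v_r_true`, `v_probe_true`.
#' @examples
#' sw <- simulate_sweep(circuit_spec(10e3, frequencies = c(1, 10, 100)), "A")
#' sw$z_sum
#' @export
simulate_sweep <- function(circuit, config = c("A", "B"), n_cycles = 10,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(circuit, "circuit_spec"), n_cycles >= 10)
  config <- match.arg(config)
  f <- circuit$frequencies
  fs <- sweep_fs(f)
  zc <- circuit_contact_z(circuit, f)
  zt <- rep(as.complex(circuit$z_tissue), length.out = length(f))
  amp <- circuit$v_source_pp / 2
  vg <- complex(real = amp, imaginary = 0)

  # ground-truth circuit algebra
  z_sum <- zc + zt
  z_12 <- 2 * zc + zt
  # both configurations share the same series loop: source-side contact,
  # tissue, probe/return-side contact, reference resistor
  loop <- 2 * zc + zt + circuit$r_ref
  i_true <- vg / loop
  v_r <- i_true * circuit$r_ref
  v_probe <- if (config == "A") v_r + i_true * z_sum else rep(vg, length(f))

  if (!is.null(seed)) set.seed(seed)
  waveforms <- purrr::map(seq_along(f), function(k) {
    n <- round(n_cycles * fs[k] / f[k])
    t <- (0:(n - 1)) / fs[k]
    w <- 2 * pi * f[k]
    synth <- function(ph) Mod(ph) * sin(w * t + Arg(ph))
    out <- tibble::tibble(
      t = t,
      v_g = synth(vg),
      v_r = synth(v_r[k]),
      v_probe = synth(v_probe[k])
    )
    if (noise_sd > 0) {
      out$v_r <- out$v_r + stats::rnorm(n, 0, noise_sd)
      out$v_probe <- out$v_probe + stats::rnorm(n, 0, noise_sd)
    }
    out
  })

  tibble::tibble(
    f_hz = f, fs = fs, config = config, waveform = waveforms,
    z_contact = zc, z_sum = z_sum, z_12 = z_12,
    i_true = i_true, v_r_true = v_r, v_probe_true = v_probe
  )
}

#' Generate a pair of sinusoids with known phase shift
#'
#' `x(t) = X0 sin(w t)` and `y(t) = Y0 sin(w t + theta)`, optionally with
#' additive Gaussian noise; the reference pair for validating the phase
#' estimators.
#'
#' @param f Frequency in Hz.
#' @param fs Sampling rate in Hz; must exceed `2 f`.
#' @param duration Record length in seconds, at least `3 / f`.
#' @param phase_deg True phase of `y` relative to `x`, degrees.
#' @param amplitudes Length-2 amplitudes `c(X0, Y0)` in volt.
#' @param noise_sd Additive Gaussian noise (volt).
#' @param seed Optional integer seed.
#' @return A tibble with columns `t`, `x`, `y`; the true phase is kept in
#'   attribute `phase_deg`.
#' @examples
#' synth_sinusoid_pair(100, 1e4, 0.05, phase_deg = 30)
#' @export
synth_sinusoid_pair <- function(f, fs, duration, phase_deg,
                                amplitudes = c(1, 1), noise_sd = 0,
                                seed = NULL) {
  if (fs <= 2 * f) stop("fs = ", fs, " <= 2f: the pair would alias")
  stopifnot(duration >= 3 / f, length(amplitudes) == 2)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration * fs)
  t <- (0:(n - 1)) / fs
  w <- 2 * pi * f
  out <- tibble::tibble(
    t = t,
    x = amplitudes[1] * sin(w * t),
    y = amplitudes[2] * sin(w * t + phase_deg * pi / 180)
  )
  if (noise_sd > 0) {
    out$x <- out$x + stats::rnorm(n, 0, noise_sd)
    out$y <- out$y + stats::rnorm(n, 0, noise_sd)
  }
  attr(out, "phase_deg") <- phase_deg
  attr(out, "fs") <- fs
  out
}

#' Synthetic two-channel ECG specification
#'
#' Defines a lead-II-like two-channel recording (test electrode vs Ag/AgCl
#' reference) with sum-of-Gaussians P-Q-R-S-T morphology, 60/120 Hz
#' powerline contamination, baseline wander, channel-specific broadband
#' noise, and an optional corruption rule that suppresses named waves in a
#' stated fraction of beats on the test channel only.
#'
#' @param fs Sampling rate in Hz, `>= 500` (resolves the QRS and the
#'   150 Hz passband edge). Default 1000.
#' @param duration Record length in seconds (default 300, a five-minute
#'   acquisition).
#' @param heart_rate Beats per minute (default 70).
#' @param wave_amplitudes Named per-wave amplitudes in mV
#'   (`p`, `q`, `r`, `s`, `t`).
#' @param powerline Named amplitudes (mV) of the 60 and 120 Hz components.
#' @param baseline_wander List with `amplitude` (mV) and `frequency`
#'   (Hz, below 0.5).
#' @param white_noise_sd Broadband Gaussian noise, mV.
#' @param channel_noise_scale Named per-channel noise multipliers
#'   (`test`, `ref`).
#' @param corruption Either `NULL` or `list(wave =, fraction =)` naming a
#'   wave (e.g. `"p"`) suppressed in that fraction of beats on the test
#'   channel.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @return An object of class `ecg_synth_spec`.
#' @export
ecg_synth_spec <- function(fs = 1000, duration = 300, heart_rate = 70,
                           wave_amplitudes = c(p = 0.15, q = -0.1, r = 1.0,
                                               s = -0.25, t = 0.3),
                           powerline = c(`60` = 0.05, `120` = 0.02),
                           baseline_wander = list(amplitude = 0.1,
                                                  frequency = 0.25),
                           white_noise_sd = 0.01,
                           channel_noise_scale = c(test = 1, ref = 1),
                           corruption = NULL, seed = 1L) {
  stopifnot(
    fs >= 500, duration > 0, heart_rate > 0,
    all(c("p", "q", "r", "s", "t") %in% names(wave_amplitudes)),
    baseline_wander$frequency < 0.5,
    white_noise_sd >= 0
  )
  if (!is.null(corruption)) {
    stopifnot(corruption$wave %in% c("p", "q", "r", "s", "t"),
              corruption$fraction >= 0, corruption$fraction <= 1)
  }
  structure(
    list(fs = fs, duration = duration, heart_rate = heart_rate,
         wave_amplitudes = wave_amplitudes, powerline = powerline,
         baseline_wander = baseline_wander, white_noise_sd = white_noise_sd,
         channel_noise_scale = channel_noise_scale, corruption = corruption,
         seed = as.integer(seed)),
    class = "ecg_synth_spec"
  )
}

# per-wave Gaussian template: center offsets from R (s) and widths (s)
ecg_wave_shape <- function() {
  tibble::tibble(
    wave = c("p", "q", "r", "s", "t"),
    offset = c(-0.20, -0.035, 0, 0.035, 0.28),
    width = c(0.025, 0.010, 0.012, 0.010, 0.055)
  )
}

#' Generate an annotated two-channel synthetic ECG
#'
#' Builds both channels from the same sum-of-Gaussians beat template (so
#' the fiducials are shared), then adds powerline, baseline wander, and
#' channel-specific noise. If a corruption rule is present the named wave
#' is removed from the chosen beats on the test channel only, and the
#' ground-truth annotations record the suppression.
#'
#' @param spec An [ecg_synth_spec].
#' @return An object of class `ecg_recording`: list with `signals`
#'   (tibble `t`, `test_mv`, `ref_mv`), `fs`, `annotations` (tibble
#'   `beat`, `wave`, `index`, `suppressed_test`), and `spec`.
#' @examples
#' rec <- synth_ecg(ecg_synth_spec(duration = 10, heart_rate = 60))
#' nrow(dplyr::filter(rec$annotations, wave == "r"))
#' @export
synth_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_synth_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  fs <- spec$fs
  n <- floor(spec$duration * fs)
  t <- (0:(n - 1)) / fs
  rr <- 60 / spec$heart_rate
  n_beats <- floor(spec$duration * spec$heart_rate / 60)
  r_times <- 0.4 + (seq_len(n_beats) - 1) * rr
  r_times <- r_times[r_times < spec$duration]
  n_beats <- length(r_times)

  shape <- ecg_wave_shape()
  amps <- spec$wave_amplitudes

  suppressed <- rep(FALSE, n_beats)
  supp_wave <- NA_character_
  if (!is.null(spec$corruption) && spec$corruption$fraction > 0) {
    supp_wave <- spec$corruption$wave
    k <- round(spec$corruption$fraction * n_beats)
    suppressed[sample.int(n_beats, min(k, n_beats))] <- TRUE
  }

  template <- function(skip_suppressed) {
    sig <- numeric(n)
    for (b in seq_len(n_beats)) {
      for (w in seq_len(nrow(shape))) {
        wname <- shape$wave[w]
        if (skip_suppressed && suppressed[b] && identical(wname, supp_wave)) next
        ctr <- r_times[b] + shape$offset[w]
        span <- which(t >= ctr - 4 * shape$width[w] & t <= ctr + 4 * shape$width[w])
        if (length(span)) {
          sig[span] <- sig[span] +
            amps[[wname]] * exp(-((t[span] - ctr)^2) / (2 * shape$width[w]^2))
        }
      }
    }
    sig
  }

  common <- numeric(n)
  pl <- spec$powerline
  for (nm in names(pl)) {
    common <- common + pl[[nm]] * sin(2 * pi * as.numeric(nm) * t)
  }
  bw <- spec$baseline_wander
  common <- common + bw$amplitude * sin(2 * pi * bw$frequency * t)

  scl <- spec$channel_noise_scale
  test_mv <- template(TRUE) + common +
    stats::rnorm(n, 0, spec$white_noise_sd * scl[["test"]])
  ref_mv <- template(FALSE) + common +
    stats::rnorm(n, 0, spec$white_noise_sd * scl[["ref"]])

  ann <- tidyr::expand_grid(beat = seq_len(n_beats), wave = shape$wave) |>
    dplyr::left_join(shape, by = "wave") |>
    dplyr::mutate(
      index = round((r_times[.data$beat] + .data$offset) * fs) + 1L,
      suppressed_test = suppressed[.data$beat] & .data$wave == supp_wave
    ) |>
    dplyr::filter(.data$index >= 1, .data$index <= n) |>
    dplyr::select("beat", "wave", "index", "suppressed_test")

  structure(
    list(signals = tibble::tibble(t = t, test_mv = test_mv, ref_mv = ref_mv),
         fs = fs, annotations = ann, spec = spec),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf(
    "<ecg_recording> %d samples @ %g Hz (%.1f s), %d annotated beats\n",
    nrow(x$signals), x$fs, nrow(x$signals) / x$fs,
    length(unique(x$annotations$beat))
  ))
  invisible(x)
}

#' @method autoplot ecg_recording
#' @export
autoplot.ecg_recording <- function(object, from = 0, to = 5, ...) {
  d <- object$signals |>
    dplyr::filter(.data$t >= from, .data$t <= to) |>
    tidyr::pivot_longer(c("test_mv", "ref_mv"),
                        names_to = "channel", values_to = "mv")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
}

#' DC polarization series specification
#'
#' Open-circuit DC potential at an electrode pair, sampled at 10 samples/s
#' for about 30 minutes: a constant offset, slow drift, optional step
#' artifacts, and sample-to-sample Gaussian variability on the scale of
#' tens to hundreds of microvolts per 0.1 s.
#'
#' @param fs Sampling rate in Hz (default 10, the acquisition protocol).
#' @param duration Record length in seconds (default 1800).
#' @param dc_offset DC polarization level in mV (default 15.4, a typical
#'   textile-electrode level).
#' @param drift_rate Slow drift in mV/min.
#' @param step_artifacts Optional list of `c(time, amplitude)` pairs
#'   (seconds, mV) added as steps.
#' @param noise_sd Sample noise SD in microvolt (default 238, which gives
#'   sample-to-sample variability near 270 uV per 0.1 s).
#' @param seed Integer seed.
#' @return An object of class `polarization_synth_spec`.
#' @export
polarization_synth_spec <- function(fs = 10, duration = 1800,
                                    dc_offset = 15.4, drift_rate = 0.02,
                                    step_artifacts = NULL, noise_sd = 238,
                                    seed = 1L) {
  stopifnot(fs > 0, duration > 0, noise_sd >= 0)
  structure(
    list(fs = fs, duration = duration, dc_offset = dc_offset,
         drift_rate = drift_rate, step_artifacts = step_artifacts,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "polarization_synth_spec"
  )
}

#' Generate a DC polarization series
#'
#' @param spec A [polarization_synth_spec].
#' @return A tibble with columns `t` (s) and `potential_mv`, carrying the
#'   sampling rate in attribute `fs`.
#' @examples
#' pol <- synth_polarization(polarization_synth_spec(duration = 60))
#' mean(pol$potential_mv)
#' @export
synth_polarization <- function(spec) {
  stopifnot(inherits(spec, "polarization_synth_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  n <- floor(spec$fs * spec$duration)
  t <- (0:(n - 1)) / spec$fs
  x <- spec$dc_offset + spec$drift_rate * t / 60
  for (stp in spec$step_artifacts) {
    x <- x + ifelse(t >= stp[1], stp[2], 0)
  }
  if (spec$noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, spec$noise_sd / 1000)
  }
  out <- tibble::tibble(t = t, potential_mv = x)
  attr(out, "fs") <- spec$fs
  out
}
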