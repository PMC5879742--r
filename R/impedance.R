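#' Impedance spectra
#'
#' An impedance spectrum is a tibble of complex impedances on a strictly
#' increasing frequency grid, the product of a sweep measurement and the
#' input to Cole fitting and AUC scoring.
#'
#' @param f_hz Frequencies in Hz, strictly increasing.
#' @param z Complex impedances (ohm), finite.
#' @param label Material / electrode identifier.
#' @param provenance Optional free-form method metadata (stored as an
#'   attribute).
#' @return A tibble of class `impedance_spectrum` with columns `f_hz`, `z`,
#'   `z_abs`, `z_phase_deg`, `label`.
#' @export
impedance_spectrum <- function(f_hz, z, label = "", provenance = NULL) {
  stopifnot(length(f_hz) == length(z), all(diff(f_hz) > 0))
  z <- as.complex(z)
  if (!all(is.finite(Mod(z)))) stop("non-finite impedance values")
  out <- tibble::tibble(
    f_hz = as.numeric(f_hz),
    z = z,
    z_abs = Mod(z),
    z_phase_deg = Arg(z) * 180 / pi,
    label = label
  )
  class(out) <- c("impedance_spectrum", class(out))
  attr(out, "provenance") <- provenance
  out
}

#' Default measurement frequency grid
#'
#' Log-spaced sweep grid, 10 points per decade over 0.1 Hz to 10 kHz
#' (51 points), the range used for dry-electrode contact-impedance
#' characterization.
#'
#' @param f_min,f_max Grid end points in Hz.
#' @param points_per_decade Grid density.
#' @return Numeric vector of frequencies.
#' @export
freq_grid <- function(f_min = 0.1, f_max = 1e4, points_per_decade = 10) {
  stopifnot(f_min > 0, f_max > f_min, points_per_decade >= 1)
  10^seq(log10(f_min), log10(f_max), by = 1 / points_per_decade)
}

#' Impedance from a voltage phasor pair
#'
#' The series current through the reference resistor is `I = Vr / R_ref`,
#' so the impedance seen by the probe voltage is `Z = V21 / I`: magnitudes
#' divide and phases subtract.
#'
#' @param v21 [phasor] of the probe voltage difference V21.
#' @param vr [phasor] of the voltage across the reference resistor.
#' @param r_ref Reference resistance in ohm, `> 0`.
#' @return Complex impedance (ohm).
#' @examples
#' impedance_from_phasors(phasor(2, 45, 10), phasor(1, 0, 10), 1000)
#' @export
impedance_from_phasors <- function(v21, vr, r_ref) {
  stopifnot(inherits(v21, "phasor"), inherits(vr, "phasor"), r_ref > 0)
  if (vr$magnitude == 0) stop("|Vr| = 0: no current flows, impedance undefined")
  phasor_to_complex(v21) / (phasor_to_complex(vr) / r_ref)
}

#' Probe voltage difference for the two sweep configurations
#'
#' Configuration A probes the electrode-2 voltage, giving
#' `V21 = Ve2 - Vr`; configuration B drives electrode 2 directly, giving
#' `V21 = Vg - Vr`. Both are complex subtractions returned in
#' magnitude/phase form.
#'
#' @param ve2,vg,vr [phasor]s at the same frequency.
#' @return A [phasor].
#' @export
v21_config_a <- function(ve2, vr) {
  stopifnot(inherits(ve2, "phasor"), inherits(vr, "phasor"))
  if (!isTRUE(all.equal(ve2$frequency, vr$frequency))) {
    stop("phasor frequencies differ: ", ve2$frequency, " vs ", vr$frequency)
  }
  as_phasor(phasor_to_complex(ve2) - phasor_to_complex(vr), ve2$frequency)
}

#' @rdname v21_config_a
#' @export
v21_config_b <- function(vg, vr) {
  stopifnot(inherits(vg, "phasor"), inherits(vr, "phasor"))
  if (!isTRUE(all.equal(vg$frequency, vr$frequency))) {
    stop("phasor frequencies differ: ", vg$frequency, " vs ", vr$frequency)
  }
  as_phasor(phasor_to_complex(vg) - phasor_to_complex(vr), vg$frequency)
}

#' Decompose the two-configuration impedances
#'
#' With identical electrode contact impedances, configuration A measures
#' `Z_sum = Z_contact + Z_tissue` and configuration B measures
#' `Z_12 = 2 Z_contact + Z_tissue`, so the contact impedance is their
#' difference: `Z_contact = Z_12 - Z_sum` and `Z_tissue = 2 Z_sum - Z_12`.
#'
#' @param z_sum,z_12 Complex impedances (ohm) at the same frequency.
#' @return A list with complex elements `z_contact` and `z_sb`
#'   (tissue impedance). A negative real part of `z_contact` is
#'   non-physical and sets attribute `physical = FALSE` plus a warning.
#' @examples
#' decompose_impedance(11e3 + 0i, 21e3 + 0i)
#' @export
decompose_impedance <- function(z_sum, z_12) {
  z_contact <- z_12 - z_sum
  out <- list(z_contact = z_contact, z_sb = 2 * z_sum - z_12)
  if (any(Re(z_contact) < 0)) {
    warning("decomposed contact impedance has negative real part (non-physical)")
    attr(out, "physical") <- FALSE
  }
  out
}

#' Full sweep-to-spectrum measurement pipeline
#'
#' Converts paired configuration-A and configuration-B sweeps (as produced
#' by [simulate_sweep()]) into a contact-impedance spectrum: per frequency,
#' DC removal, phasor extraction of the probe and reference-resistor
#' waveforms, the configuration-specific V21 subtraction, division by the
#' series current, and the two-configuration decomposition. Frequencies at
#' which any stage fails are dropped with a warning; if every frequency
#' fails, an error is raised.
#'
#' @param sweep_a,sweep_b Sweep tibbles from [simulate_sweep()] (configs
#'   "A" and "B") on matching frequency grids.
#' @param r_ref Reference resistance in ohm.
#' @param method Phase-estimation method passed to [waveform_to_phasor()].
#' @param label Label for the resulting spectrum.
#' @return An [impedance_spectrum] of the contact impedance, with the
#'   tissue impedance in attribute `z_sb` and per-frequency `z_sum`/`z_12`
#'   in attribute `components`.
#' @export
sweep_pipeline <- function(sweep_a, sweep_b, r_ref,
                           method = c("lissajous", "xcorr"),
                           label = "contact") {
  method <- match.arg(method)
  stopifnot(nrow(sweep_a) > 0, nrow(sweep_b) > 0)
  if (!isTRUE(all.equal(sweep_a$f_hz, sweep_b$f_hz))) {
    stop("configuration A and B sweeps are on different frequency grids")
  }
  rows <- purrr::map(seq_len(nrow(sweep_a)), function(i) {
    f <- sweep_a$f_hz[i]
    tryCatch({
      wa <- sweep_a$waveform[[i]]
      wb <- sweep_b$waveform[[i]]
      fsa <- sweep_a$fs[i]
      fsb <- sweep_b$fs[i]
      # DC removal, then drop half the (possibly reduced) filter length at
      # each end so edge transients never reach the phasor estimators; the
      # same trim keeps all channels of a configuration aligned
      clean <- function(x, fs) {
        ord <- min(2000, 2 * floor(length(x) / 6))
        y <- suppressWarnings(remove_dc(x, fs, order = ord))
        y[(ord / 2 + 1):(length(y) - ord / 2)]
      }
      # configuration A: probe = Ve2
      vr_a <- suppressWarnings(waveform_to_phasor(
        clean(wa$v_r, fsa), clean(wa$v_g, fsa), f, fsa, method))
      ve2 <- suppressWarnings(waveform_to_phasor(
        clean(wa$v_probe, fsa), clean(wa$v_g, fsa), f, fsa, method))
      z_sum <- impedance_from_phasors(v21_config_a(ve2, vr_a), vr_a, r_ref)
      # configuration B: V21 = Vg - Vr
      vr_b <- suppressWarnings(waveform_to_phasor(
        clean(wb$v_r, fsb), clean(wb$v_g, fsb), f, fsb, method))
      vg <- suppressWarnings(waveform_to_phasor(
        clean(wb$v_g, fsb), clean(wb$v_g, fsb), f, fsb, method))
      z_12 <- impedance_from_phasors(v21_config_b(vg, vr_b), vr_b, r_ref)
      dec <- suppressWarnings(decompose_impedance(z_sum, z_12))
      tibble::tibble(f_hz = f, z_contact = dec$z_contact, z_sb = dec$z_sb,
                     z_sum = z_sum, z_12 = z_12)
    }, error = function(e) {
      warning("frequency ", f, " Hz dropped: ", conditionMessage(e))
      NULL
    })
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) stop("sweep pipeline failed at every frequency")
  out <- impedance_spectrum(res$f_hz, res$z_contact, label = label,
                            provenance = list(method = method, r_ref = r_ref))
  attr(out, "z_sb") <- res$z_sb
  attr(out, "components") <- res
  out
}

#' Area under the impedance magnitude curve
#'
#' Scalar summary of a spectrum for comparing materials: the trapezoidal
#' integral of `|Z|` against `log10(frequency)`, in ohm-decades. Impedance
#' magnitude decreases monotonically with frequency for these electrodes,
#' so a larger AUC means a larger overall contact impedance.
#'
#' @param spectrum An [impedance_spectrum] (or tibble with `f_hz` and
#'   `z_abs` or `z` columns) with at least 2 strictly positive frequencies.
#' @return AUC score in ohm-decades.
#' @examples
#' sp <- cole_eval(cole_reference_params(), freq_grid())
#' auc_score(sp)
#' @export
auc_score <- function(spectrum) {
  stopifnot(is.data.frame(spectrum), nrow(spectrum) >= 2)
  f <- spectrum$f_hz
  if (any(f <= 0)) stop("AUC score requires strictly positive frequencies")
  mag <- if ("z_abs" %in% names(spectrum)) spectrum$z_abs else Mod(spectrum$z)
  x <- log10(f)
  sum(diff(x) * (utils::head(mag, -1) + utils::tail(mag, -1)) / 2)
}

#' @method autoplot impedance_spectrum
#' @export
autoplot.impedance_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$f_hz, y = .data$z_abs,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "|Z| (ohm)", colour = NULL) +
    ggplot2::theme_minimal()
}
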