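#' Phasor records
#'
#' A phasor is the unit of exchange between waveform processing and circuit
#' algebra: the magnitude and phase of a voltage (or impedance) at a single
#' frequency. Phases are kept in degrees in the interval (-180, 180].
#'
#' @param magnitude Non-negative magnitude (volt or ohm, by context).
#' @param phase_deg Phase in degrees; wrapped into (-180, 180].
#' @param frequency Frequency in Hz.
#' @return An object of class `phasor`.
#' @examples
#' phasor(2.5, 45, 100)
#' @export
phasor <- function(magnitude, phase_deg, frequency) {
  stopifnot(is.numeric(magnitude), magnitude >= 0, is.numeric(frequency))
  structure(
    list(
      magnitude = magnitude,
      phase_deg = wrap_phase(phase_deg),
      frequency = frequency
    ),
    class = "phasor"
  )
}

# wrap degrees into (-180, 180]
wrap_phase <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  ifelse(out == -180, 180, out)
}

#' @export
print.phasor <- function(x, ...) {
  cat(sprintf(
    "<phasor> %.6g ∠ %.4g° @ %g Hz\n",
    x$magnitude, x$phase_deg, x$frequency
  ))
  invisible(x)
}

#' Convert between phasors and complex numbers
#'
#' @param x A `phasor`, or a complex number for [as_phasor()].
#' @param frequency Frequency in Hz attached by [as_phasor()].
#' @return [phasor_to_complex()] returns a complex scalar; [as_phasor()] a
#'   `phasor`.
#' @export
phasor_to_complex <- function(x) {
  stopifnot(inherits(x, "phasor"))
  x$magnitude * exp(1i * x$phase_deg * pi / 180)
}

#' @rdname phasor_to_complex
#' @export
as_phasor <- function(x, frequency) {
  phasor(Mod(x), Arg(x) * 180 / pi, frequency)
}

#' Remove the DC offset from a sampled waveform
#'
#' High-pass FIR filter with 0.05 Hz cut-off and (by default) order 2000,
#' applied with delay compensation so the output stays aligned with the
#' input. The filter is built as the spectral complement of a DC-normalized
#' windowed-sinc lowpass, which places an exact null at 0 Hz even at the
#' extreme normalized cut-offs that arise at high sampling rates. For
#' records shorter than three times the order, the order is reduced to
#' length/3 (rounded to even) with a warning.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (default 2000).
#' @param cutoff High-pass cut-off in Hz (default 0.05).
#' @return Numeric waveform, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' y <- remove_dc(1.5 + sin(2 * pi * 5 * t), fs = 1000)
#' mean(y)
#' @export
remove_dc <- function(x, fs, order = 2000, cutoff = 0.05) {
  stopifnot(is.numeric(x), fs > 0)
  if (length(x) < 12) {
    stop("signal of length ", length(x), " is shorter than any usable DC-removal filter")
  }
  max_order <- 2 * floor(length(x) / 6)
  if (order > max_order) {
    warning("DC-removal filter order reduced from ", order, " to ", max_order,
            " for a record of ", length(x), " samples")
    order <- max_order
  }
  b <- fir_highpass(order, cutoff, fs, window = "hamming")
  fir_apply(x, b)
}

#' Waveform amplitude from cycle extrema
#'
#' Estimates the amplitude of an oscillatory waveform as the mean absolute
#' extremum over half-cycles, where half-cycles are delimited by the zero
#' crossings of the mean-removed signal. Spurious, noise-induced short
#' half-cycles (shorter than half the median half-cycle) are discarded.
#' Each extremum is refined by a least-squares parabola over a window
#' around the raw maximum, which removes the sampling-grid bias and
#' averages out additive noise instead of riding its maximum.
#'
#' @param x Numeric waveform containing at least two full cycles.
#' @return Amplitude (same units as `x`).
#' @examples
#' t <- seq(0, 1, by = 1e-4)
#' amplitude_peaks(2 * sin(2 * pi * 10 * t))
#' @export
amplitude_peaks <- function(x) {
  stopifnot(is.numeric(x))
  xc <- x - mean(x)
  s <- sign(xc)
  s[s == 0] <- 1
  crossings <- which(diff(s) != 0)
  if (length(crossings) < 4) {
    stop("no detectable oscillation: fewer than two full cycles present")
  }
  bounds <- cbind(crossings[-length(crossings)] + 1, crossings[-1])
  len <- bounds[, 2] - bounds[, 1] + 1
  keep <- len >= stats::median(len) / 2
  if (sum(keep) < 4) {
    stop("no detectable oscillation: fewer than two full cycles present")
  }
  amps <- apply(bounds[keep, , drop = FALSE], 1, function(b) {
    seg <- abs(xc[b[1]:b[2]])
    peak <- which.max(seg)
    # least-squares parabola over up to +/-10% of the half-cycle
    w <- max(2, round(length(seg) * 0.1))
    lo <- max(1, peak - w); hi <- min(length(seg), peak + w)
    if (hi - lo < 4) return(seg[peak])
    i <- lo:hi
    fit <- stats::lm.fit(cbind(1, i, i^2), seg[i])
    cf <- fit$coefficients
    if (!is.finite(cf[3]) || cf[3] >= 0) return(seg[peak])
    vertex <- cf[1] - cf[2]^2 / (4 * cf[3])
    if (!is.finite(vertex) || vertex < seg[peak] / 2) seg[peak] else vertex
  })
  mean(amps)
}

#' Phase shift from the Lissajous figure
#'
#' For `x(t) = X0 sin(wt)` and `y(t) = Y0 sin(wt + theta)`, the Lissajous
#' figure of y against x crosses the y axis at `y0 = Y0 sin(theta)`, so
#' `theta = arcsin(y0 / Y0)`. `y0` is read at the positive-going zero
#' crossings of `x` (linearly interpolated between bracketing samples) and
#' `Y0` comes from [amplitude_peaks()]. The principal arcsin branch limits
#' the result to \[-90, 90\] degrees; see [waveform_to_phasor()] for the
#' quadrant disambiguation.
#'
#' @param x,y Numeric waveforms of equal length at the same frequency, with
#'   at least two cycles.
#' @return Phase of `y` relative to `x`, degrees in \[-90, 90\]. If noise
#'   pushes the estimated `|y0|` above `Y0` the value is clamped to +/-90
#'   with a warning, and the result carries attribute `clamped = TRUE`.
#' @export
phase_lissajous <- function(x, y) {
  stopifnot(length(x) == length(y))
  xc <- x - mean(x)
  yc <- y - mean(y)
  up <- which(xc[-length(xc)] < 0 & xc[-1] >= 0)
  if (length(up) < 1) stop("no positive-going zero crossings found in x")
  if (length(up) >= 2) {
    # re-estimate both means over the whole cycles between the first and
    # last up-crossing: a partial trailing cycle would otherwise bias the
    # baseline and hence the y-intercept reading
    cyc <- up[1]:(up[length(up)] - 1)
    xc <- x - mean(x[cyc])
    yc <- y - mean(y[cyc])
    up <- which(xc[-length(xc)] < 0 & xc[-1] >= 0)
    if (length(up) < 1) stop("no positive-going zero crossings found in x")
  }
  frac <- -xc[up] / (xc[up + 1] - xc[up])
  # read y at the interpolated crossing: cubic (4-point Lagrange) where
  # neighbors exist -- near +/-90 degrees y crosses its extremum here and
  # linear interpolation would be biased by the curvature -- else linear
  y0_at <- function(i, a) {
    if (i >= 2 && i + 2 <= length(yc)) {
      s <- a + 1 # position on the 4-sample stencil 0..3
      yv <- yc[(i - 1):(i + 2)]
      sum(yv * c(-(s - 1) * (s - 2) * (s - 3) / 6,
                 s * (s - 2) * (s - 3) / 2,
                 -s * (s - 1) * (s - 3) / 2,
                 s * (s - 1) * (s - 2) / 6))
    } else {
      yc[i] + a * (yc[i + 1] - yc[i])
    }
  }
  y0 <- mean(mapply(y0_at, up, frac))
  Y0 <- amplitude_peaks(y)
  ratio <- y0 / Y0
  clamped <- FALSE
  if (abs(ratio) > 1) {
    warning("estimated |y0| exceeds Y0 (noise); phase clamped to ", sign(ratio) * 90, " degrees")
    ratio <- sign(ratio)
    clamped <- TRUE
  }
  out <- asin(ratio) * 180 / pi
  if (clamped) attr(out, "clamped") <- TRUE
  out
}

#' Phase shift from the cross-correlation lag
#'
#' The discrete cross-correlation `r(l) = sum_n x(n) y(n - l)` is maximized
#' at the lag `l` aligning the two waveforms; the phase is then
#' `theta = 360 * l * f / fs` degrees, wrapped to (-180, 180]. Lags are
#' restricted to half a period either side of zero and ties among maxima
#' break toward the smallest `|l|`. The correlation is computed via FFT.
#'
#' By default the maximizing integer lag is refined by a three-point
#' parabolic interpolation of the correlation peak, giving sub-lag phase
#' resolution; `refine = "none"` keeps the raw integer lag, whose phase is
#' quantized to `360 * f / fs` degrees.
#'
#' @param x,y Numeric waveforms of equal length.
#' @param f Common frequency of the waveforms (Hz).
#' @param fs Sampling rate (Hz). `fs / f >= 8` is required; a warning is
#'   issued when the lag quantization `360 * f / fs` exceeds 5 degrees.
#' @param refine `"parabolic"` (default) or `"none"`.
#' @return Phase of `y` relative to `x`, degrees in (-180, 180].
#' @export
phase_xcorr <- function(x, y, f, fs, refine = c("parabolic", "none")) {
  refine <- match.arg(refine)
  stopifnot(length(x) == length(y), f > 0, fs > 0)
  if (fs / f < 8) {
    stop("fs/f = ", round(fs / f, 2), " < 8: phase resolution coarser than 45 degrees")
  }
  if (360 * f / fs > 5) {
    warning("phase resolution 360*f/fs = ", round(360 * f / fs, 2), " degrees exceeds 5 degrees")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  if (stats::sd(xc) == 0 || stats::sd(yc) == 0) {
    stop("constant input: cross-correlation undefined")
  }
  n <- length(xc)
  half <- round(fs / f / 2)
  # correlate a core window of x (whole cycles, margins >= half a period)
  # against the full y record: every lag then sees the same number of
  # terms and, for pure tones, r(l) is an exact sampled cosine in l
  period <- max(1L, round(fs / f))
  avail <- n - 2 * half
  w <- if (avail >= period) floor(avail / period) * period else max(avail, 1)
  xw <- numeric(n)
  core <- (half + 1):(half + w)
  xw[core] <- xc[core]
  m <- stats::nextn(2 * n, 2)
  r <- Re(stats::fft(stats::fft(c(xw, rep(0, m - n))) *
                       Conj(stats::fft(c(yc, rep(0, m - n)))), inverse = TRUE)) / m
  at <- function(l) {
    idx <- ((l %% m) + m) %% m
    r[idx + 1]
  }
  lags <- c(0:half, -(1:half))
  vals <- at(lags)
  ord <- order(abs(lags), lags)
  lags <- lags[ord]
  vals <- vals[ord]
  best <- lags[which(vals >= max(vals) * (1 - 1e-12))[1]]
  if (refine == "parabolic") {
    r0 <- at(best); rm1 <- at(best - 1); rp1 <- at(best + 1)
    denom <- rm1 - 2 * r0 + rp1
    if (is.finite(denom) && denom < 0) {
      best <- best + 0.5 * (rm1 - rp1) / denom
    }
  }
  wrap_phase(360 * best * f / fs)
}

#' Estimate a phasor from a waveform and a reference
#'
#' Combines [amplitude_peaks()] for the magnitude with either the Lissajous
#' or the cross-correlation phase estimate, the phase being that of
#' `signal` relative to `reference`. Because arcsin cannot distinguish
#' `theta` from `180 - theta`, the Lissajous estimate is quadrant-corrected
#' using the sign of the zero-lag cross-correlation between the two
#' mean-removed waveforms.
#'
#' @param signal,reference Numeric waveforms of equal length at frequency `f`.
#' @param f Frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param method `"lissajous"` or `"xcorr"`.
#' @return A [phasor].
#' @examples
#' t <- seq(0, 0.5, by = 1e-4)
#' x <- sin(2 * pi * 100 * t)
#' y <- 2 * sin(2 * pi * 100 * t + pi / 6)
#' waveform_to_phasor(y, x, f = 100, fs = 1e4)
#' @export
waveform_to_phasor <- function(signal, reference, f, fs,
                               method = c("lissajous", "xcorr")) {
  method <- match.arg(method)
  mag <- amplitude_peaks(signal)
  if (method == "xcorr") {
    ph <- phase_xcorr(reference, signal, f, fs)
  } else {
    ph <- as.numeric(phase_lissajous(reference, signal))
    r0 <- sum((reference - mean(reference)) * (signal - mean(signal)))
    if (r0 < 0) {
      ph <- if (ph >= 0) 180 - ph else -180 - ph
    }
  }
  phasor(mag, ph, f)
}
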