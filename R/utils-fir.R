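# Windowed-sinc FIR design and zero-delay application.
#
# The designs here follow the classic window method with explicit gain
# normalization: lowpass prototypes are scaled to exactly unity DC gain,
# high-pass / bandstop filters are built as spectral complements (delta
# minus a normalized prototype) so their nulls are exact, and bandpass
# filters are scaled to unity at the band center. Plain fir1-style scaling
# fails badly at the extreme normalized cutoffs this package needs
# (0.05 Hz at kHz-to-MHz sampling rates): the windowed sinc then carries
# almost no energy and the "high-pass" retains most of its DC gain.

# ideal (unscaled) windowed lowpass impulse response, linear phase, odd length
ideal_lowpass <- function(order, fc, fs) {
  stopifnot(order %% 2 == 0, fc > 0, fc < fs / 2)
  m <- seq(0, order) - order / 2
  ifelse(m == 0, 2 * fc / fs, sin(2 * pi * fc / fs * m) / (pi * m))
}

fir_window <- function(order, window = c("hamming", "kaiser"), beta = 0.5) {
  window <- match.arg(window)
  n <- order + 1
  if (window == "hamming") {
    0.54 - 0.46 * cos(2 * pi * seq(0, order) / order)
  } else {
    as.numeric(signal::kaiser(n, beta))
  }
}

# complex frequency response of FIR taps at frequencies f (Hz)
fir_response <- function(b, f, fs) {
  vapply(f, function(ff) {
    sum(b * exp(-1i * 2 * pi * ff / fs * (seq_along(b) - 1)))
  }, complex(1))
}

# high-pass with an exact DC null: complement of a DC-normalized lowpass
fir_highpass <- function(order, fc, fs, window = "hamming", beta = 0.5) {
  w <- fir_window(order, window, beta)
  lp <- ideal_lowpass(order, fc, fs) * w
  lp <- lp / sum(lp)
  hp <- -lp
  hp[order / 2 + 1] <- hp[order / 2 + 1] + 1
  hp
}

# bandpass scaled to unity gain at the arithmetic band center
fir_bandpass <- function(order, f_lo, f_hi, fs, window = "kaiser", beta = 0.5) {
  stopifnot(f_lo < f_hi, f_hi < fs / 2)
  w <- fir_window(order, window, beta)
  b <- (ideal_lowpass(order, f_hi, fs) - ideal_lowpass(order, f_lo, fs)) * w
  b / Mod(fir_response(b, (f_lo + f_hi) / 2, fs))
}

# bandstop as complement of a windowed ideal bandpass, unity DC gain
fir_bandstop <- function(order, f_lo, f_hi, fs, window = "kaiser", beta = 0.5) {
  stopifnot(f_lo < f_hi, f_hi < fs / 2)
  w <- fir_window(order, window, beta)
  nb <- (ideal_lowpass(order, f_hi, fs) - ideal_lowpass(order, f_lo, fs)) * w
  bs <- -nb
  bs[order / 2 + 1] <- bs[order / 2 + 1] + 1
  bs / Mod(fir_response(bs, 0, fs))
}

# Zero-delay application of a linear-phase FIR (odd tap count) by centered
# convolution with mirror padding; output has the input's length.
fir_apply <- function(x, b) {
  n <- length(b)
  stopifnot(n %% 2 == 1)
  k <- (n - 1) / 2
  if (length(x) <= k) {
    stop("signal (length ", length(x), ") too short for filter order ", n - 1)
  }
  xp <- c(rev(x[seq_len(k) + 1]), x, x[length(x) - seq_len(k)])
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  as.numeric(y[n:(length(xp))])
}
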