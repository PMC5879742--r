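# Independent oracles used across the suite.

# Cole impedance via an explicit polar expansion of the dispersion
# denominator (independent derivation path from the package's evaluator).
oracle_cole_z <- function(f, r_inf, r, c, alpha) {
  w <- 2 * pi * f
  denom <- 1 + r * c * w^alpha * complex(real = cos(alpha * pi / 2),
                                         imaginary = sin(alpha * pi / 2))
  r_inf + r / denom
}

# amplitude of the f0 component by least-squares projection on a
# sin/cos basis (Parseval-style tone-power oracle)
oracle_tone_amplitude <- function(x, t, f0) {
  b <- cbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t))
  cf <- stats::coef(stats::lm.fit(b, x))
  sqrt(sum(cf^2))
}

# greedy peak matching within a tolerance (samples); returns true positives
match_peaks <- function(detected, truth, tol) {
  sum(vapply(truth, function(b) any(abs(detected - b) <= tol), logical(1)))
}

# detection quality against ground-truth R indices
qrs_quality <- function(rec, tol_s = 0.02) {
  det <- detect_qrs(rec$signals$ref_mv, rec$fs)
  tr <- dplyr::filter(rec$annotations, wave == "r")$index
  tp <- match_peaks(det, tr, tol_s * rec$fs)
  list(sensitivity = tp / length(tr), ppv = tp / length(det),
       n_truth = length(tr), n_det = length(det))
}
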