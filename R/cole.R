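#' Cole impedance model parameters
#'
#' The Cole model describes dispersive (constant-phase-element) impedance:
#' \deqn{Z(\omega) = R_\infty + \sum_k \frac{R_k}{1 + R_k C_k (j\omega)^{\alpha_k}}}
#' with fractional exponents \eqn{0 < \alpha_k \le 1}. At \eqn{\alpha = 1}
#' each dispersion reduces exactly to a parallel RC branch. One or two
#' dispersions are supported.
#'
#' Note the time-constant convention: the dispersion term is
#' `R / (1 + R * C * (j w)^alpha)`, i.e. `C` enters as `R*C*(jw)^alpha`.
#' Literature conventions differ; this one is fixed here because it nests
#' the RC circuit at `alpha = 1`.
#'
#' @param r_inf High-frequency resistance \eqn{R_\infty} (ohm), `>= 0`.
#' @param r Dispersion resistance(s) (ohm), length 1 or 2, `> 0`.
#' @param c Dispersion capacitance(s) (farad), same length as `r`, `> 0`.
#' @param alpha Fractional exponent(s) in (0, 1], same length as `r`.
#' @return An object of class `cole_params`.
#' @examples
#' cole_params(35065, 3.701e6, 15.129e-9, 0.8397)
#' @export
cole_params <- function(r_inf, r, c, alpha) {
  stopifnot(
    is.numeric(r_inf), length(r_inf) == 1, r_inf >= 0,
    length(r) %in% 1:2, length(c) == length(r), length(alpha) == length(r),
    all(r > 0), all(c > 0), all(alpha > 0), all(alpha <= 1)
  )
  structure(
    list(
      r_inf = r_inf,
      dispersions = tibble::tibble(r = as.numeric(r), c = as.numeric(c),
                                   alpha = as.numeric(alpha))
    ),
    class = "cole_params"
  )
}

#' @export
print.cole_params <- function(x, ...) {
  cat(sprintf("<cole_params> R_inf = %.6g ohm, %d dispersion(s)\n",
              x$r_inf, nrow(x$dispersions)))
  print(x$dispersions)
  invisible(x)
}

#' Reference single-dispersion parameterization for PEDOT:PSS textile electrodes
#'
#' The published static contact-impedance model for dry textile electrodes
#' treated with PEDOT:PSS: `R_inf = 35.065 kOhm`, `R1 = 3.701 MOhm`,
#' `C1 = 15.129 nF`, `alpha1 = 0.8397`.
#'
#' @return A [cole_params] object.
#' @export
cole_reference_params <- function() {
  cole_params(r_inf = 35.065e3, r = 3.701e6, c = 15.129e-9, alpha = 0.8397)
}

# complex impedance of a cole_params object at frequencies f (Hz);
# f = 0 is the analytic limit R_inf + sum(R_k)
cole_impedance <- function(params, f) {
  stopifnot(inherits(params, "cole_params"), all(f >= 0))
  w <- 2 * pi * f
  z <- complex(real = rep(params$r_inf, length(f)), imaginary = 0)
  for (k in seq_len(nrow(params$dispersions))) {
    d <- params$dispersions[k, ]
    # (jw)^alpha -> 0+0i at w = 0, so the formula itself gives the R_k limit
    z <- z + d$r / (1 + d$r * d$c * (1i * w)^d$alpha)
  }
  z
}

#' Evaluate a Cole model on a frequency grid
#'
#' @param params A [cole_params] object.
#' @param frequencies Frequencies in Hz (strictly increasing; 0 allowed as
#'   the analytic low-frequency limit).
#' @param label Label attached to the resulting spectrum.
#' @return An [impedance_spectrum] tibble with columns `f_hz`, `z`
#'   (complex), `z_abs`, `z_phase_deg`, `label`.
#' @examples
#' cole_eval(cole_reference_params(), c(0.1, 1, 10, 100))
#' @export
cole_eval <- function(params, frequencies, label = "cole") {
  stopifnot(all(diff(frequencies) > 0))
  impedance_spectrum(frequencies, cole_impedance(params, frequencies),
                     label = label)
}

#' Fit a Cole impedance model by bounded least squares
#'
#' Fits a single- or double-dispersion Cole model to an impedance spectrum
#' with the Levenberg-Marquardt algorithm under box constraints
#' (`alpha` in (0, 1], resistances and capacitances positive; R, C are
#' optimized on a log10 scale). The default objective is the residual in
#' `log10 |Z|` ("magnitude" mode, matching magnitude-frequency Bode
#' presentations); "complex" mode stacks real and imaginary residuals,
#' each scaled by `1/|Z|`.
#'
#' Initialization uses plateau heuristics: `R_inf` from the minimum of
#' `|Z|`, the dispersion resistance from the plateau difference,
#' `alpha = 0.8`, and `C = 1 / (2 pi f_mid R)` at the geometric midpoint
#' frequency of the grid.
#'
#' @param spectrum An [impedance_spectrum] (or tibble with `f_hz` and `z`
#'   or `z_abs` columns). At least 5 frequencies spanning 2 decades are
#'   required for one dispersion (8 frequencies and 3 decades for two).
#' @param n_dispersions 1 or 2.
#' @param mode `"magnitude"` (default) or `"complex"`.
#' @return An object of class `cole_fit`: a list with elements `params`
#'   ([cole_params]), `diagnostics` (residual norm, convergence flag,
#'   solver message), `mode`, and the input `spectrum`. Non-convergence is
#'   reported through the flag, not as an error. Use [tidy()] / [glance()]
#'   to extract results.
#' @examples
#' sp <- cole_eval(cole_reference_params(), freq_grid())
#' fit <- cole_fit(sp)
#' tidy(fit)
#' @export
cole_fit <- function(spectrum, n_dispersions = 1,
                     mode = c("magnitude", "complex")) {
  mode <- match.arg(mode)
  stopifnot(n_dispersions %in% 1:2, is.data.frame(spectrum))
  f <- spectrum$f_hz
  stopifnot(all(f > 0), all(diff(f) > 0))
  z <- if ("z" %in% names(spectrum)) spectrum$z else spectrum$z_abs
  if (mode == "complex" && !is.complex(z)) {
    stop("complex-mode fitting needs a complex `z` column")
  }
  span <- log10(max(f) / min(f))
  min_n <- if (n_dispersions == 1) 5 else 8
  min_span <- if (n_dispersions == 1) 2 else 3
  if (length(f) < min_n || span < min_span) {
    stop("need >= ", min_n, " frequencies spanning >= ", min_span,
         " decades for ", n_dispersions, " dispersion(s)")
  }

  mag <- Mod(z)
  r_inf0 <- max(min(mag), .Machine$double.eps)
  r_tot0 <- max(max(mag) - min(mag), r_inf0 * 1e-3)
  f_mid <- sqrt(min(f) * max(f))
  # plateau-heuristic starting points; for two dispersions a small
  # deterministic grid of characteristic-frequency splits guards against
  # local minima, and the best residual wins
  if (n_dispersions == 1) {
    starts <- list(list(r = r_tot0, fc = f_mid, a = 0.8))
  } else {
    splits <- list(c(0.25, 0.75), c(0.1, 0.6), c(0.4, 0.9), c(0.2, 0.5))
    starts <- lapply(splits, function(sp) {
      list(r = c(r_tot0 / 2, r_tot0 / 2),
           fc = exp(log(min(f)) + sp * log(max(f) / min(f))),
           a = c(0.8, 0.8))
    })
  }

  pack <- function(r_inf, r, c, alpha) c(log10(r_inf), log10(r), log10(c), alpha)
  unpack <- function(p) {
    nd <- n_dispersions
    list(r_inf = 10^p[1],
         r = 10^p[2:(1 + nd)],
         c = 10^p[(2 + nd):(1 + 2 * nd)],
         alpha = p[(2 + 2 * nd):(1 + 3 * nd)])
  }
  model_z <- function(p) {
    q <- unpack(p)
    cole_impedance(cole_params(q$r_inf, q$r, q$c, q$alpha), f)
  }
  resid_fn <- if (mode == "magnitude") {
    function(p) log10(Mod(model_z(p))) - log10(mag)
  } else {
    function(p) {
      zm <- model_z(p)
      c(Re(zm - z), Im(zm - z)) / rep(mag, 2)
    }
  }

  nd <- n_dispersions
  lower <- c(-6, rep(-6, nd), rep(-15, nd), rep(1e-3, nd))
  upper <- c(12, rep(12, nd), rep(0, nd), rep(1, nd))
  fits <- lapply(starts, function(s) {
    c0 <- 1 / (2 * pi * s$fc * s$r)
    minpack.lm::nls.lm(
      par = pack(r_inf0, s$r, c0, s$a),
      fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 1e-15
      )
    )
  })
  fit <- fits[[which.min(vapply(fits, function(ft) sum(ft$fvec^2), numeric(1)))]]
  q <- unpack(fit$par)
  structure(
    list(
      params = cole_params(q$r_inf, q$r, q$c, q$alpha),
      diagnostics = list(
        residual_norm = sqrt(sum(fit$fvec^2)),
        converged = fit$info %in% 1:3,
        info = fit$info,
        message = fit$message,
        n_iter = fit$niter
      ),
      mode = mode,
      n_dispersions = n_dispersions,
      spectrum = spectrum
    ),
    class = "cole_fit"
  )
}

#' @export
print.cole_fit <- function(x, ...) {
  cat(sprintf("<cole_fit> %d dispersion(s), %s mode, %s (residual norm %.3g)\n",
              x$n_dispersions, x$mode,
              if (x$diagnostics$converged) "converged" else "NOT converged",
              x$diagnostics$residual_norm))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cole model fit
#'
#' @param x A `cole_fit` object.
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per parameter (`term`,
#'   `estimate`); for `glance()`, a one-row tibble of fit summaries.
#' @method tidy cole_fit
#' @export
tidy.cole_fit <- function(x, ...) {
  d <- x$params$dispersions
  tibble::tibble(
    term = c("r_inf",
             paste0(rep(c("r", "c", "alpha"), each = nrow(d)), seq_len(nrow(d)))),
    estimate = c(x$params$r_inf, d$r, d$c, d$alpha)
  )
}

#' @rdname tidy.cole_fit
#' @method glance cole_fit
#' @export
glance.cole_fit <- function(x, ...) {
  tibble::tibble(
    n_dispersions = x$n_dispersions,
    mode = x$mode,
    n_freq = nrow(x$spectrum),
    residual_norm = x$diagnostics$residual_norm,
    converged = x$diagnostics$converged,
    n_iter = x$diagnostics$n_iter
  )
}

#' @method autoplot cole_fit
#' @export
autoplot.cole_fit <- function(object, n_points = 200, ...) {
  sp <- object$spectrum
  fgrid <- 10^seq(log10(min(sp$f_hz)), log10(max(sp$f_hz)), length.out = n_points)
  fitline <- tibble::tibble(
    f_hz = fgrid,
    z_abs = Mod(cole_impedance(object$params, fgrid))
  )
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$f_hz, y = Mod(.data$z))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitline, ggplot2::aes(y = .data$z_abs),
                       colour = "cyan3") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "|Z| (ohm)",
                  title = "Cole model fit") +
    ggplot2::theme_minimal()
}
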