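# Statistical comparison workflow (assumption checks dispatching
# parametric vs non-parametric tests), sheet-conductivity calculation,
# and study report assembly.

#' Check normality and homoscedasticity of grouped data
#'
#' Normality is tested on the residuals about group means: Shapiro-Wilk
#' below 50 observations, a Lilliefors-corrected Kolmogorov-Smirnov test
#' otherwise. Homoscedasticity uses Levene's test (centered on the mean).
#' Both are judged at `alpha` (default 0.05).
#'
#' @param data A data frame in long format.
#' @param value,group Bare column names of the response and the grouping
#'   factor.
#' @param alpha Significance level.
#' @return A one-row tibble: `normal`, `normal_p`, `normal_test`,
#'   `homoscedastic`, `levene_p`, `n`, `n_groups`. With any constant group
#'   the Levene test is undefined: `homoscedastic` is `NA` with a warning.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 10), y = rnorm(20))
#' assumption_check(d, y, g)
#' @export
assumption_check <- function(data, value, group, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  stopifnot(is.numeric(v), length(v) == length(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 3)) stop("every group needs n >= 3")

  resid <- v - stats::ave(v, g)
  if (length(resid) < 50) {
    nt <- stats::shapiro.test(resid)
    normal_test <- "shapiro-wilk"
  } else {
    nt <- nortest::lillie.test(resid)
    normal_test <- "lilliefors-ks"
  }

  degenerate <- any(tapply(v, g, stats::sd) == 0)
  if (degenerate) {
    warning("constant group(s): homoscedasticity undefined")
    lev_p <- NA_real_
  } else {
    lev <- car::leveneTest(v ~ g, center = mean)
    lev_p <- lev[["Pr(>F)"]][1]
  }

  tibble::tibble(
    normal = nt$p.value > alpha,
    normal_p = nt$p.value,
    normal_test = normal_test,
    homoscedastic = if (is.na(lev_p)) NA else lev_p > alpha,
    levene_p = lev_p,
    n = length(v),
    n_groups = nlevels(g)
  )
}

#' Select the comparison test from the assumption booleans
#'
#' The decision tree is a pure function of the assumption outcomes, the
#' number of groups, and the design: assumptions met dispatches an ANOVA
#' (one-way for independent designs, repeated-measures otherwise);
#' assumptions violated dispatches Kruskal-Wallis for more than two
#' groups, or the Wilcoxon test for two (paired when the design says so).
#' An undefined homoscedasticity check (`NA`) is treated as a violation.
#'
#' @param normal,homoscedastic Logicals (NA allowed for homoscedastic).
#' @param n_groups Number of groups (>= 2).
#' @param design `"independent"`, `"paired"`, or `"repeated"`.
#' @return Test name: one of `"anova"`, `"repeated-anova"`,
#'   `"kruskal-wallis"`, `"wilcoxon"`, `"wilcoxon-paired"`.
#' @export
select_test <- function(normal, homoscedastic,
                        n_groups, design = c("independent", "paired", "repeated")) {
  design <- match.arg(design)
  stopifnot(n_groups >= 2)
  parametric <- isTRUE(normal) && isTRUE(homoscedastic)
  if (parametric) {
    if (design == "independent") "anova" else "repeated-anova"
  } else if (n_groups > 2) {
    "kruskal-wallis"
  } else if (design == "independent") {
    "wilcoxon"
  } else {
    "wilcoxon-paired"
  }
}

#' Compare groups with the study's statistical decision tree
#'
#' Runs [assumption_check()] and dispatches the test chosen by
#' [select_test()]. Repeated/paired designs require a `subject` column
#' identifying the blocking unit.
#'
#' @inheritParams assumption_check
#' @param design Study design.
#' @param subject Bare column name of the subject / block identifier
#'   (required for paired and repeated designs).
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `parametric`,
#'   `normal_p`, `levene_p`, `design`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 8), y = rnorm(24))
#' compare_groups(d, y, g)
#' @export
compare_groups <- function(data, value, group,
                           design = c("independent", "paired", "repeated"),
                           subject = NULL, alpha = 0.05) {
  design <- match.arg(design)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  s_quo <- rlang::enquo(subject)
  s <- if (!rlang::quo_is_null(s_quo)) {
    factor(rlang::eval_tidy(s_quo, data))
  } else NULL
  if (design != "independent" && is.null(s)) {
    stop("paired/repeated designs need a `subject` column")
  }

  chk <- assumption_check(data, {{ value }}, {{ group }}, alpha = alpha)
  test <- select_test(chk$normal, chk$homoscedastic, chk$n_groups, design)

  res <- switch(test,
    "anova" = {
      fit <- stats::aov(v ~ g)
      tab <- summary(fit)[[1]]
      list(statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
    },
    "repeated-anova" = {
      fit <- stats::aov(v ~ g + Error(s / g))
      tab <- summary(fit)[["Error: s:g"]][[1]]
      list(statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
    },
    "kruskal-wallis" = {
      k <- stats::kruskal.test(v ~ g)
      list(statistic = unname(k$statistic), p = k$p.value)
    },
    "wilcoxon" = ,
    "wilcoxon-paired" = {
      lv <- levels(g)
      paired <- test == "wilcoxon-paired"
      if (paired) {
        ord1 <- order(s[g == lv[1]]); ord2 <- order(s[g == lv[2]])
        w <- stats::wilcox.test(v[g == lv[1]][ord1], v[g == lv[2]][ord2],
                                paired = TRUE, exact = FALSE)
      } else {
        w <- stats::wilcox.test(v[g == lv[1]], v[g == lv[2]], exact = FALSE)
      }
      list(statistic = unname(w$statistic), p = w$p.value)
    }
  )

  tibble::tibble(
    test = test,
    statistic = res$statistic,
    p_value = res$p,
    parametric = test %in% c("anova", "repeated-anova"),
    normal_p = chk$normal_p,
    levene_p = chk$levene_p,
    design = design
  )
}

#' Bulk conductivity of a conductive fabric sheet
#'
#' Treating the fabric as a thin film of uniform thickness `t` and sheet
#' resistance `R_s` (ohm/square), the bulk resistivity is `rho = R_s * t`
#' and the conductivity its reciprocal, reported in S/cm:
#' `sigma = 1 / (R_s * t) / 100`.
#'
#' @param surface_resistance Sheet resistance in ohm/square, `> 0`.
#' @param thickness Sheet thickness in meters, `> 0`.
#' @return Conductivity in S/cm (vectorized).
#' @examples
#' conductivity(100, 100e-6) # 1 S/cm
#' @export
conductivity <- function(surface_resistance, thickness) {
  if (any(surface_resistance <= 0) || any(thickness <= 0)) {
    stop("surface resistance and thickness must be positive")
  }
  1 / (surface_resistance * thickness) / 100
}

#' Assemble a study report from stage outputs
#'
#' Deterministically collects the outputs of the pipeline stages into one
#' structured report: impedance spectra with their AUC scores, a Cole fit,
#' polarization summaries, ECG quality metrics, a long-term table, and
#' statistical comparisons. Missing stages are marked absent and the
#' assembly continues; an entirely empty call is an error.
#'
#' @param impedance Named list of [impedance_spectrum] objects (or one).
#' @param cole A `cole_fit`.
#' @param polarization A tibble of polarization summaries (e.g. subject x
#'   material rows with `potential_mv` and `variability_uv`).
#' @param noise A tibble of per-recording quality metrics
#'   (see [ecg_quality_metrics()]).
#' @param longterm A [longterm_table()] result.
#' @param comparisons A tibble of [compare_groups()] rows.
#' @return An object of class `electrode_study_report`: a list of
#'   sections, each either a tibble/object or `NULL` (absent), plus a
#'   `sections` character vector of what is present.
#' @export
build_report <- function(impedance = NULL, cole = NULL, polarization = NULL,
                         noise = NULL, longterm = NULL, comparisons = NULL) {
  stages <- list(impedance = impedance, cole = cole,
                 polarization = polarization, noise = noise,
                 longterm = longterm, comparisons = comparisons)
  if (all(vapply(stages, is.null, logical(1)))) {
    stop("no stage outputs supplied")
  }
  if (!is.null(impedance)) {
    specs <- if (inherits(impedance, "impedance_spectrum")) {
      list(impedance)
    } else impedance
    stages$impedance <- list(
      spectra = specs,
      auc = tibble::tibble(
        label = vapply(specs, function(s) s$label[1], character(1)),
        auc_ohm_decades = vapply(specs, auc_score, numeric(1))
      )
    )
  }
  structure(
    c(stages, list(sections = names(stages)[!vapply(stages, is.null, logical(1))])),
    class = "electrode_study_report"
  )
}

#' @export
print.electrode_study_report <- function(x, ...) {
  cat("<electrode_study_report> sections:",
      paste(x$sections, collapse = ", "), "\n")
  if ("impedance" %in% x$sections) {
    cat("\n-- impedance AUC (ohm-decades) --\n")
    print(x$impedance$auc)
  }
  if ("cole" %in% x$sections) {
    cat("\n-- Cole model --\n")
    print(tidy(x$cole))
  }
  if ("polarization" %in% x$sections) {
    cat("\n-- polarization --\n")
    print(x$polarization)
  }
  if ("noise" %in% x$sections) {
    cat("\n-- ECG quality --\n")
    print(x$noise)
  }
  if ("longterm" %in% x$sections) {
    cat("\n-- long-term error --\n")
    print(x$longterm)
  }
  if ("comparisons" %in% x$sections) {
    cat("\n-- statistical comparisons --\n")
    print(x$comparisons)
  }
  invisible(x)
}
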