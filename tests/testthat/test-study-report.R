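test_that("assumption checks classify well-behaved and pathological data", {
  set.seed(14)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 12), y = rnorm(36))
  chk <- assumption_check(d, y, g)
  expect_true(chk$normal)
  expect_true(chk$homoscedastic)
  expect_equal(chk$normal_test, "shapiro-wilk")

  # inflating one group's variance breaks homoscedasticity
  d2 <- d
  d2$y[d2$g == "c"] <- d2$y[d2$g == "c"] * 100
  expect_false(assumption_check(d2, y, g)$homoscedastic)

  # heavy tails break normality (large n switches to the KS variant)
  set.seed(15)
  d3 <- data.frame(g = rep(c("a", "b"), each = 40), y = rcauchy(80))
  chk3 <- assumption_check(d3, y, g)
  expect_false(chk3$normal)
  expect_equal(chk3$normal_test, "lilliefors-ks")

  # degenerate constant group
  d4 <- data.frame(g = rep(c("a", "b"), each = 5),
                   y = c(rep(1, 5), rnorm(5)))
  expect_warning(chk4 <- assumption_check(d4, y, g), "undefined")
  expect_true(is.na(chk4$homoscedastic))

  expect_error(assumption_check(data.frame(g = "a", y = 1), y, g))
})

test_that("the test-selection decision tree is total and correct", {
  expected <- tibble::tribble(
    ~normal, ~homo, ~groups, ~design,       ~test,
    TRUE,    TRUE,  2,       "independent", "anova",
    TRUE,    TRUE,  5,       "independent", "anova",
    TRUE,    TRUE,  2,       "paired",      "repeated-anova",
    TRUE,    TRUE,  5,       "repeated",    "repeated-anova",
    FALSE,   TRUE,  5,       "independent", "kruskal-wallis",
    TRUE,    FALSE, 5,       "paired",      "kruskal-wallis",
    FALSE,   FALSE, 2,       "independent", "wilcoxon",
    FALSE,   TRUE,  2,       "paired",      "wilcoxon-paired",
    TRUE,    NA,    2,       "repeated",    "wilcoxon-paired",
    TRUE,    NA,    3,       "independent", "kruskal-wallis"
  )
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    expect_equal(select_test(e$normal, e$homo, e$groups, e$design), e$test,
                 label = paste("branch", i))
  }
  # exhaustively: every combination returns one of the five tests
  combos <- expand.grid(normal = c(TRUE, FALSE), homo = c(TRUE, FALSE, NA),
                        groups = 2:4,
                        design = c("independent", "paired", "repeated"),
                        stringsAsFactors = FALSE)
  out <- purrr::pmap_chr(combos, function(normal, homo, groups, design) {
    select_test(normal, homo, groups, design)
  })
  expect_true(all(out %in% c("anova", "repeated-anova", "kruskal-wallis",
                             "wilcoxon", "wilcoxon-paired")))
})

test_that("group comparison dispatches and detects a large shift", {
  set.seed(16)
  base <- rnorm(24)
  d <- data.frame(g = rep(c("a", "b"), each = 24), y = c(base, base + 10))
  res <- compare_groups(d, y, g)
  expect_lt(res$p_value, 1e-6)
  expect_true(res$test %in% c("anova", "wilcoxon"))

  # no effect: identical groups with internal spread
  d0 <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rep(rnorm(10), 3))
  res0 <- compare_groups(d0, y, g)
  expect_gt(res0$p_value, 0.05)

  # heavy-tailed data fall through to Kruskal-Wallis
  set.seed(18)
  dk <- data.frame(g = rep(c("a", "b", "c"), each = 15), y = rcauchy(45))
  resk <- compare_groups(dk, y, g)
  expect_equal(resk$test, "kruskal-wallis")

  # repeated design without subject errors
  expect_error(compare_groups(d, y, g, design = "repeated"), "subject")
})

test_that("repeated-measures designs use the subject blocking", {
  set.seed(19)
  subj <- rep(1:8, times = 3)
  d <- data.frame(s = subj, g = rep(c("a", "b", "c"), each = 8),
                  y = rnorm(24) + rep(rnorm(8), times = 3))
  res <- compare_groups(d, y, g, design = "repeated", subject = s)
  expect_true(res$test %in% c("repeated-anova", "kruskal-wallis"))
  expect_true(is.finite(res$p_value))
})

test_that("conductivity is the reciprocal of sheet resistance times thickness", {
  expect_equal(conductivity(100, 100e-6), 1)
  expect_equal(conductivity(100, 200e-6), 0.5)
  # round trip: sigma -> R_s (at fixed t) -> sigma
  sigma <- 0.337
  t <- 150e-6
  rs <- 1 / (sigma * 100 * t)
  expect_equal(conductivity(rs, t), sigma, tolerance = 1e-12)
  expect_error(conductivity(-1, 1e-4), "positive")
  # strictly decreasing in each argument
  expect_lt(conductivity(200, 1e-4), conductivity(100, 1e-4))
  expect_lt(conductivity(100, 2e-4), conductivity(100, 1e-4))
})

test_that("report assembly collects present sections and flags absences", {
  sp <- cole_eval(cole_reference_params(), freq_grid())
  fit <- cole_fit(sp)
  rep_full <- build_report(
    impedance = list(sp),
    cole = fit,
    polarization = tibble::tibble(material = "cotton", potential_mv = 15.4,
                                  variability_uv = 308.93),
    comparisons = tibble::tibble(test = "anova", p_value = 0.3)
  )
  expect_s3_class(rep_full, "electrode_study_report")
  expect_true(all(c("impedance", "cole", "polarization", "comparisons")
                  %in% rep_full$sections))
  expect_equal(rep_full$impedance$auc$auc_ohm_decades, auc_score(sp))

  rep_one <- build_report(impedance = sp)
  expect_equal(rep_one$sections, "impedance")
  expect_null(rep_one$cole)

  expect_error(build_report(), "no stage outputs")
  expect_output(print(rep_one), "impedance")
})
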