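test_that("OLS matches hand-evaluated closed forms", {
  f <- fit_ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)

  f <- fit_ols(c(0, 1, 2), c(0.1, 0.9, 2.0))
  expect_equal(f$slope, 0.95, tolerance = 1e-12)
  expect_equal(f$intercept, 0.05, tolerance = 1e-12)
  expect_equal(f$r2, 0.9918, tolerance = 1e-4)

  expect_error(fit_ols(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_ols(c(1, 2), c(1, 2)), "3 complete pairs")
})

test_that("SMA matches the pinned closed forms including the CI", {
  f <- fit_sma(c(0, 1, 2), c(0.1, 0.9, 2.0))
  expect_equal(f$slope, 0.9539, tolerance = 1e-4)
  # slope equals OLS slope / r
  o <- fit_ols(c(0, 1, 2), c(0.1, 0.9, 2.0))
  expect_equal(f$slope, o$slope / sqrt(o$r2), tolerance = 1e-12)
  # CI from B = F(0.95; 1, 1) * (1 - r2) / (n - 2)
  expect_equal(f$ci_low, 0.356, tolerance = 1e-3)
  expect_equal(f$ci_high, 2.556, tolerance = 2e-3)

  ex <- fit_sma(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(ex$slope, 2)
  expect_equal(ex$ci_low, 2)
  expect_equal(ex$ci_high, 2)
  expect_equal(ex$p_vs_1, 0)

  expect_error(fit_sma(c(0, 1, 2), c(5, 5, 5)), "degenerate")
})

test_that("both fits agree with an independent oracle on small datasets", {
  set.seed(101)
  for (i in 1:50) {
    d <- random_pairs(5)
    f <- fit_ols(d$u, d$v)
    o <- lm_oracle(d$u, d$v)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
    expect_equal(f$ci_low, unname(o$ci_low), tolerance = 1e-10)
    expect_equal(f$ci_high, unname(o$ci_high), tolerance = 1e-10)
    expect_equal(f$p_vs_1, unname(o$p_vs_1), tolerance = 1e-10)
    # SMA slope against the sd-ratio definition
    s <- fit_sma(d$u, d$v)
    expect_equal(s$slope,
                 sign(stats::cor(d$u, d$v)) * stats::sd(d$v) / stats::sd(d$u),
                 tolerance = 1e-10)
    expect_equal(s$intercept, mean(d$v) - s$slope * mean(d$u), tolerance = 1e-10)
  }
})

test_that("|SMA| = |OLS|/|r| and |SMA| >= |OLS| across random datasets", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    d <- random_pairs(n)
    o <- fit_ols(d$u, d$v)
    s <- fit_sma(d$u, d$v)
    r <- stats::cor(d$u, d$v)
    expect_equal(abs(s$slope), abs(o$slope) / abs(r), tolerance = 1e-10)
    expect_gte(abs(s$slope) + 1e-12, abs(o$slope))
    expect_true(s$ci_low <= s$slope && s$slope <= s$ci_high)
    expect_true(o$ci_low <= o$slope && o$slope <= o$ci_high)
  }
})

test_that("slope-vs-1 p-value and 95% CI reject together", {
  set.seed(303)
  for (i in 1:1000) {
    n <- sample(4:25, 1)
    d <- random_pairs(n)
    fits <- list(fit_ols(d$u, d$v))
    # the SMA interval and slope test are dual on the positive branch; a
    # negative fitted slope trivially excludes 1 from the CI while the
    # residual-vs-fitted-axis correlation test addresses |slope| only
    if (stats::cor(d$u, d$v) > 0) fits <- c(fits, list(fit_sma(d$u, d$v)))
    for (f in fits) {
      outside <- f$ci_low > 1 || f$ci_high < 1
      expect_identical(f$p_vs_1 < 0.05, outside,
                       label = sprintf("%s p=%g CI=[%g,%g]", f$method,
                                       f$p_vs_1, f$ci_low, f$ci_high))
    }
  }
})

test_that("classification follows the CI-vs-1 rule with stars and isometry subtypes", {
  mk <- function(ci_low, ci_high, p) {
    structure(list(method = "OLS", n = 108, slope = (ci_low + ci_high) / 2,
                   intercept = 0, r2 = 0.99, ci_low = ci_low,
                   ci_high = ci_high, p_vs_1 = p),
              class = "regression_result")
  }
  expect_equal(classify(mk(1.117, 1.147, 1e-5))$category, "positive")
  expect_equal(classify(mk(0.643, 0.689, 1e-6))$category, "negative")
  expect_equal(classify(mk(0.95, 1.05, 0.4))$category, "isometric")
  # inclusive endpoints: CI touching 1 is isometric
  expect_equal(classify(mk(1.0, 1.2, 0.05))$category, "isometric")
  expect_equal(classify(mk(0.8, 1.0, 0.05))$category, "isometric")
  # star grades
  expect_equal(classify(mk(1.1, 1.2, 2e-5))$stars, "****")
  expect_equal(classify(mk(1.1, 1.2, 2e-4))$stars, "***")
  expect_equal(classify(mk(1.1, 1.2, 2e-3))$stars, "**")
  expect_equal(classify(mk(1.1, 1.2, 0.03))$stars, "*")
  expect_equal(classify(mk(0.9, 1.2, 0.1199))$stars, "")
  # hard/soft isometry at the 0.15 default threshold
  expect_equal(classify(mk(0.99, 1.03, 0.1199))$iso_subtype, "soft")
  expect_equal(classify(mk(0.99, 1.03, 0.0898))$iso_subtype, "soft")
  expect_equal(classify(mk(0.97, 1.01, 0.2266))$iso_subtype, "hard")
  expect_equal(classify(mk(1.1, 1.2, 1e-5))$iso_subtype, "not-applicable")
  # threshold is configurable
  expect_equal(classify(mk(0.99, 1.03, 0.1199), soft_threshold = 0.1)$iso_subtype,
               "hard")
})

test_that("regress_all returns one classified row per non-reference variable", {
  tab <- noise_free_table(slopes = c(0.5, 1.0, 2.0), n = 30)
  res <- regress_all(tab, "OLS")
  expect_equal(nrow(res), 3)
  expect_equal(res$category, c("negative", "isometric", "positive"))
  expect_equal(res$slope, c(0.5, 1.0, 2.0), tolerance = 1e-9)

  res_sma <- regress_all(tab, "SMA")
  expect_equal(res_sma$category, c("negative", "isometric", "positive"))
})

test_that("degenerate variables are flagged, not fatal", {
  m <- cbind(ref = c(10, 20, 40, 80), good = c(5, 10, 20, 40),
             flat = c(7, 7, 7, 7))
  tab <- measurement_table(m, "ref")
  res <- regress_all(tab, "SMA")
  expect_true(res$degenerate[res$variable == "flat"])
  expect_false(res$degenerate[res$variable == "good"])
  expect_equal(res$slope[res$variable == "good"], 1, tolerance = 1e-12)
})

test_that("regression report mirrors the standard column layout", {
  tab <- noise_free_table(slopes = c(0.5, 2.0), n = 20)
  rep <- report_regression(regress_all(tab, "OLS"))
  expect_equal(names(rep), c("variable", "R2", "intercept", "slope", "lCI",
                             "uCI", "trend", "sig"))
  path <- withr::local_tempfile(fileext = ".csv")
  report_regression(regress_all(tab, "OLS"), path)
  expect_true(file.exists(path))
  expect_equal(nrow(utils::read.csv(path)), 2)
})
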