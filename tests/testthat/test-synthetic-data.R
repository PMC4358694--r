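test_that("noise-free generation reproduces the generating slopes exactly", {
  tab <- noise_free_table(slopes = c(0.5, 1.2), n = 25)
  lt <- log_transform(tab)
  for (i in 1:2) {
    o <- fit_ols(lt$values[, "ref"], lt$values[, paste0("v", i)])
    s <- fit_sma(lt$values[, "ref"], lt$values[, paste0("v", i)])
    expect_equal(o$slope, c(0.5, 1.2)[i], tolerance = 1e-10)
    expect_equal(s$slope, c(0.5, 1.2)[i], tolerance = 1e-10)
  }
})

test_that("generation is deterministic given seed and bounded by the size range", {
  spec <- allometry_model_spec(list(variable_spec("v1", -0.3, 1.1, 0.03)),
                               l_min = 29, l_max = 689)
  a <- simulate_dataset(spec, 40, seed = 7)
  b <- simulate_dataset(spec, 40, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, simulate_dataset(spec, 40, seed = 8)$values))
  for (dist in c("log-uniform", "uniform", "adult-skewed")) {
    sp <- allometry_model_spec(list(variable_spec("v1", 0, 1, 0)),
                               l_min = 29, l_max = 689,
                               size_distribution = dist)
    L <- reference_values(simulate_dataset(sp, 200, seed = 9))
    expect_true(all(L >= 29 & L <= 689))
  }
})

test_that("adult-skewed sizes concentrate near the adult end", {
  mk <- function(dist) {
    sp <- allometry_model_spec(list(variable_spec("v1", 0, 1, 0)),
                               l_min = 29, l_max = 689,
                               size_distribution = dist, alpha = 4)
    stats::median(reference_values(simulate_dataset(sp, 2000, seed = 10)))
  }
  expect_gt(mk("adult-skewed"), mk("log-uniform"))
})

test_that("empirical-weights resamples the supplied reference vector", {
  refv <- c(30, 30, 30, 650)
  sp <- allometry_model_spec(list(variable_spec("v1", 0, 1, 0)),
                             l_min = 29, l_max = 689,
                             size_distribution = "empirical-weights",
                             empirical_ref = refv)
  L <- reference_values(simulate_dataset(sp, 500, seed = 11))
  expect_true(all(L %in% refv))
  expect_gt(mean(L == 30), 0.5)
  expect_error(allometry_model_spec(list(variable_spec("v1", 0, 1, 0)),
                                    size_distribution = "empirical-weights"),
               "empirical_ref")
})

test_that("least squares recovers the generating slope without bias", {
  spec <- allometry_model_spec(list(variable_spec("v1", 0, 1.2, 0.02)),
                               l_min = 29, l_max = 689)
  slopes <- vapply(1:200, function(s) {
    tab <- simulate_dataset(spec, 500, seed = s)
    lt <- log_transform(tab)
    fit_ols(lt$values[, "ref"], lt$values[, "v1"])$slope
  }, numeric(1))
  expect_equal(mean(slopes), 1.2, tolerance = 0.01 / 1.2)
})

test_that("the 95% slope CI covers the generating slope at the nominal rate", {
  spec <- allometry_model_spec(list(variable_spec("v1", -0.2, 1.1, 0.05)),
                               l_min = 29, l_max = 689)
  cover <- vapply(1:1000, function(s) {
    lt <- log_transform(simulate_dataset(spec, 200, seed = 4000 + s))
    f <- fit_ols(lt$values[, "ref"], lt$values[, "v1"])
    f$ci_low <= 1.1 && 1.1 <= f$ci_high
  }, logical(1))
  expect_equal(mean(cover), 0.95, tolerance = 0.02 / 0.95)
})

test_that("sigma_from_r2 inverts the R-squared of the generating model", {
  expect_equal(sigma_from_r2(1, 0.5, 1), 1)
  # printed slope/R2 pair: 1.132 * 0.4 * sqrt(0.005/0.995)
  expect_equal(sigma_from_r2(1.132, 0.995, 0.4), 0.0321, tolerance = 1e-3)
  # monotone decreasing in r2, vanishing toward 1
  s <- sigma_from_r2(1, c(0.5, 0.9, 0.99, 0.9999), 1)
  expect_true(all(diff(s) < 0))
  expect_lt(s[4], 0.011)
  expect_error(sigma_from_r2(1, 0, 1), "r2")
  expect_error(sigma_from_r2(1, 1, 1), "r2")
  expect_error(sigma_from_r2(1, 0.5, 0), "sd_u")
  # round trip: simulated data realize the requested R2
  sg <- sigma_from_r2(1.1, 0.95, log10(689 / 29) / sqrt(12))
  spec <- allometry_model_spec(list(variable_spec("v1", 0, 1.1, sg)),
                               l_min = 29, l_max = 689)
  r2s <- vapply(1:100, function(s) {
    lt <- log_transform(simulate_dataset(spec, 400, seed = 100 + s))
    fit_ols(lt$values[, "ref"], lt$values[, "v1"])$r2
  }, numeric(1))
  expect_equal(mean(r2s), 0.95, tolerance = 0.01)
})

test_that("the alligator-like spec carries the 22 published variable models", {
  spec <- alligator_like_spec()
  expect_length(spec$variables, 22)
  expect_equal(spec$reference_id, "var6")
  expect_equal(c(spec$l_min, spec$l_max), c(29, 689))
  v7 <- Filter(function(v) v$variable_id == "var7", spec$variables)[[1]]
  expect_equal(v7$a, -0.562)
  expect_equal(v7$b, 1.132)
  v10 <- Filter(function(v) v$variable_id == "var10", spec$variables)[[1]]
  expect_equal(v10$a, -0.073)
  expect_equal(v10$b, 0.666)
  expect_false("var6" %in% vapply(spec$variables, function(v) v$variable_id,
                                  character(1)))
})

test_that("1-mm rounding barely perturbs slopes when values stay above 10 mm", {
  vars <- list(variable_spec("v1", 0.2, 1.1, 0.02))  # >= 10^0.2 * 29^1.1 mm
  raw <- allometry_model_spec(vars, l_min = 29, l_max = 689, round_mm = FALSE)
  rnd <- allometry_model_spec(vars, l_min = 29, l_max = 689, round_mm = TRUE)
  for (s in 1:10) {
    t1 <- simulate_dataset(raw, 108, seed = s)
    t2 <- simulate_dataset(rnd, 108, seed = s)
    expect_true(all(t2$values > 10))
    l1 <- log_transform(t1); l2 <- log_transform(t2)
    d <- abs(fit_ols(l1$values[, "ref"], l1$values[, "v1"])$slope -
               fit_ols(l2$values[, "ref"], l2$values[, "v1"])$slope)
    expect_lt(d, 0.01)
  }
})

test_that("survey simulation respects degenerate and clamped specifications", {
  cells <- data.frame(group = "vertebrate", status = "extinct", count = 50,
                      mu = log(20), s = 0, min_n = 3)
  sv <- simulate_survey(survey_sim_spec(cells), seed = 1)
  expect_true(all(sv$n == 20))

  cells2 <- data.frame(group = "vertebrate", status = "extinct", count = 500,
                       mu = log(3), s = 1.5, min_n = 3)
  sv2 <- simulate_survey(survey_sim_spec(cells2), seed = 2)
  expect_true(all(sv2$n >= 3))

  expect_identical(simulate_survey(survey_sim_spec(cells2), seed = 3)$n,
                   simulate_survey(survey_sim_spec(cells2), seed = 3)$n)
})

test_that("log-normal moment identities reproduce a target mean and median", {
  mu <- log(32.5); s <- sqrt(2 * log(72.3 / 32.5))
  cells <- data.frame(group = "invertebrate", status = "extant", count = 10000,
                      mu = mu, s = s, min_n = 1)
  sv <- simulate_survey(survey_sim_spec(cells), seed = 13)
  expect_equal(stats::median(sv$n), 32.5, tolerance = 0.05)
  expect_equal(mean(sv$n), 72.3, tolerance = 0.05)
})

test_that("the default survey spec mirrors the published cell structure", {
  spec <- default_survey_spec()
  expect_equal(nrow(spec$cells), 4)
  expect_equal(sum(spec$cells$count), 542)
  sv <- simulate_survey(spec, seed = 3)
  expect_equal(nrow(sv), 542)
  expect_true(all(sv$n >= 3))
  gs <- summarize_groups(sv)
  # extant cells sit right of extinct cells, as in the published survey
  med <- function(g, s) gs$median[gs$group == g & gs$status == s]
  expect_gt(med("invertebrate", "extant"), med("invertebrate", "extinct"))
  expect_gt(med("vertebrate", "extant"), med("vertebrate", "extinct"))
})
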