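# small programmatic fixtures shared across test files

# 3-specimen, 2-variable table with complete reference column
tiny_table <- function() {
  m <- matrix(c(29, 100, 689, 15, 50, 300), ncol = 2,
              dimnames = list(c("s1", "s2", "s3"), c("bsl", "orbit")))
  measurement_table(m, reference_id = "bsl")
}

# noise-free synthetic table: variables with exact slopes against the reference
noise_free_table <- function(slopes = c(0.5, 1.0, 2.0), n = 30, seed = 1) {
  vars <- lapply(seq_along(slopes), function(i) {
    variable_spec(paste0("v", i), a = 0, b = slopes[i], sigma = 0)
  })
  spec <- allometry_model_spec(vars, l_min = 10, l_max = 1000)
  simulate_dataset(spec, n, seed = seed)
}

# write a CSV fixture and return its path
write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random small (u, v) dataset for property loops
random_pairs <- function(n = 5) {
  u <- stats::rnorm(n)
  v <- 0.3 + stats::runif(1, 0.5, 1.5) * u + stats::rnorm(n, 0, 0.3)
  list(u = u, v = v)
}

# independent OLS oracle built on stats::lm / confint
lm_oracle <- function(u, v) {
  fit <- stats::lm(v ~ u)
  ci <- stats::confint(fit, "u", level = 0.95)
  se <- summary(fit)$coefficients["u", "Std. Error"]
  tstat <- (stats::coef(fit)[["u"]] - 1) / se
  list(slope = stats::coef(fit)[["u"]], intercept = stats::coef(fit)[["(Intercept)"]],
       r2 = summary(fit)$r.squared, ci_low = ci[1], ci_high = ci[2],
       p_vs_1 = 2 * stats::pt(-abs(tstat), stats::df.residual(fit)))
}

# power_curve object built directly from given isometric/positive proportions
fake_power_curve <- function(n, p_positive, p_isometric = NULL,
                             p_negative = NULL, reps = 100) {
  if (is.null(p_isometric)) p_isometric <- 1 - p_positive
  if (is.null(p_negative)) p_negative <- 1 - p_positive - p_isometric
  tab <- data.frame(n = n,
                    n_positive = round(p_positive * reps),
                    n_isometric = round(p_isometric * reps),
                    n_negative = round(p_negative * reps),
                    n_failed = 0L, total = reps,
                    p_positive = p_positive, p_isometric = p_isometric,
                    p_negative = p_negative, skipped = FALSE)
  structure(list(variable_id = "fake", method = "OLS", scheme = "random",
                 reps = reps, seed = 0, table = tab), class = "power_curve")
}
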