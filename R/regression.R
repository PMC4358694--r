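#' Ordinary least squares fit of a log-log allometry
#'
#' Fits `v = intercept + slope * u` by least squares and tests the slope
#' against the isometric expectation of 1 (for same-dimension linear
#' measurements on a log-log scale, equal proportional growth means slope 1).
#'
#' @param u numeric vector, log reference values.
#' @param v numeric vector, log variable values (same length).
#' @return An object of class `regression_result`: list with `method`
#'   (`"OLS"`), `n`, `slope`, `intercept`, `r2`, `ci_low`, `ci_high` (95%
#'   two-sided), `p_vs_1` (two-sided p of slope != 1).
#' @examples
#' fit_ols(c(0, 1, 2), c(0.1, 0.9, 2.0))
#' @export
fit_ols <- function(u, v) {
  keep <- !is.na(u) & !is.na(v)
  u <- u[keep]; v <- v[keep]
  n <- length(u)
  if (n < 3) stop("at least 3 complete pairs required (got ", n, ")", call. = FALSE)
  res <- .fit_ols_core(u, v, n)
  if (is.null(res)) stop("degenerate input: reference values have zero variance", call. = FALSE)
  structure(c(list(method = "OLS"), res), class = "regression_result")
}

# closed-form OLS on complete pairs; returns NULL when Var(u) = 0
.fit_ols_core <- function(u, v, n) {
  mu <- mean(u); mv <- mean(v)
  du <- u - mu; dv <- v - mv
  sxx <- sum(du * du)
  if (sxx <= 0) return(NULL)
  syy <- sum(dv * dv)
  sxy <- sum(du * dv)
  slope <- sxy / sxx
  intercept <- mv - slope * mu
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  se2 <- (syy - slope * sxy) / sxx / (n - 2)
  se <- sqrt(max(se2, 0))
  tq <- stats::qt(0.975, n - 2)
  p <- if (se > 0) {
    2 * stats::pt(-abs((slope - 1) / se), n - 2)
  } else if (slope == 1) 1 else 0
  list(n = n, slope = slope, intercept = intercept, r2 = r2,
       ci_low = slope - tq * se, ci_high = slope + tq * se, p_vs_1 = p)
}

#' Standardized (reduced) major axis fit of a log-log allometry
#'
#' The SMA slope is `sign(r) * sd(v)/sd(u)`, symmetric in the two variables
#' and the conventional line-fitting method in allometry when both variables
#' carry error. The 95% CI uses the standardized-major-axis interval
#' `slope * (sqrt(B + 1) -/+ sqrt(B))` with
#' `B = F(0.95; 1, n-2) * (1 - r^2)/(n - 2)`; the slope-vs-1 test is the
#' correlation test between `v - u` and `v + u` (residual vs fitted axes
#' under the isometric null).
#'
#' @inheritParams fit_ols
#' @return A `regression_result` with `method = "SMA"`.
#' @examples
#' fit_sma(c(0, 1, 2), c(0.1, 0.9, 2.0))
#' @export
fit_sma <- function(u, v) {
  keep <- !is.na(u) & !is.na(v)
  u <- u[keep]; v <- v[keep]
  n <- length(u)
  if (n < 3) stop("at least 3 complete pairs required (got ", n, ")", call. = FALSE)
  res <- .fit_sma_core(u, v, n)
  if (is.null(res)) {
    stop("degenerate input: zero variance or zero correlation; SMA slope undefined",
         call. = FALSE)
  }
  structure(c(list(method = "SMA"), res), class = "regression_result")
}

.fit_sma_core <- function(u, v, n) {
  mu <- mean(u); mv <- mean(v)
  du <- u - mu; dv <- v - mv
  sxx <- sum(du * du)
  syy <- sum(dv * dv)
  if (sxx <= 0 || syy <= 0) return(NULL)
  sxy <- sum(du * dv)
  if (sxy == 0) return(NULL)
  r2 <- sxy^2 / (sxx * syy)
  slope <- sign(sxy) * sqrt(syy / sxx)
  intercept <- mv - slope * mu
  B <- stats::qf(0.95, 1, n - 2) * (1 - r2) / (n - 2)
  lo <- slope * (sqrt(B + 1) - sqrt(B))
  hi <- slope * (sqrt(B + 1) + sqrt(B))
  ci <- sort(c(lo, hi))
  # slope = 1 test: correlation of (v - u) with (v + u)
  a <- v - u; b <- v + u
  sa <- sum((a - mean(a))^2); sb <- sum((b - mean(b))^2)
  if (sa <= 0 || sb <= 0) {
    # v - u constant: slope exactly 1 with perfect fit, or degenerate sum axis
    p <- if (sa <= 0) 1 else 0
  } else {
    rp <- sum((a - mean(a)) * (b - mean(b))) / sqrt(sa * sb)
    rp <- max(min(rp, 1), -1)
    if (abs(rp) >= 1) {
      p <- 0
    } else {
      tstat <- rp * sqrt((n - 2) / (1 - rp^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  list(n = n, slope = slope, intercept = intercept, r2 = r2,
       ci_low = ci[1], ci_high = ci[2], p_vs_1 = p)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d, slope = %.4f [%.4f, %.4f], intercept = %.4f, r2 = %.4f, p(slope != 1) = %.4g\n",
              x$method, x$n, x$slope, x$ci_low, x$ci_high, x$intercept, x$r2,
              x$p_vs_1))
  invisible(x)
}

#' Classify a fitted slope into a scaling category
#'
#' Positive allometry when the whole 95% CI of the slope lies above 1,
#' negative when it lies below 1, isometric otherwise (CI endpoints exactly 1
#' count as isometric). Isometric results are subdivided into "hard" isometry
#' (slope-vs-1 p-value at or above `soft_threshold`: the data genuinely look
#' isometric) and "soft" isometry (p below the threshold: the non-rejection
#' plausibly reflects low power and may flip with more sampling). Significance
#' stars follow the conventional 4-level scheme.
#'
#' @param result a `regression_result`.
#' @param soft_threshold p-value boundary between soft and hard isometry
#'   (default 0.15).
#' @return An object of class `scaling_category`: list with `category`
#'   (`"positive"`, `"negative"`, `"isometric"`), `iso_subtype` (`"hard"`,
#'   `"soft"`, `"not-applicable"`), `stars` (`""`, `"*"`, `"**"`, `"***"`,
#'   `"****"`).
#' @examples
#' classify(fit_ols(c(0, 1, 2, 3), c(0, 2, 4, 6)))
#' @export
classify <- function(result, soft_threshold = 0.15) {
  stopifnot(inherits(result, "regression_result"))
  category <- .classify_core(result$ci_low, result$ci_high)
  p <- result$p_vs_1
  stars <- if (is.na(p)) "" else if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 1e-2) "**" else if (p < 0.05) "*" else ""
  iso_subtype <- if (category != "isometric") "not-applicable" else
    if (!is.na(p) && p < soft_threshold) "soft" else "hard"
  structure(list(category = category, iso_subtype = iso_subtype, stars = stars),
            class = "scaling_category")
}

.classify_core <- function(ci_low, ci_high) {
  if (ci_low > 1) "positive" else if (ci_high < 1) "negative" else "isometric"
}

#' @export
print.scaling_category <- function(x, ...) {
  lab <- switch(x$category,
                positive = "positive allometry",
                negative = "negative allometry",
                isometric = paste0(x$iso_subtype, " isometry"))
  cat(sprintf("<scaling> %s %s\n", lab, x$stars))
  invisible(x)
}

#' Regress every variable against the reference datum
#'
#' Fits each non-reference variable of a measurement table against the
#' reference on a log-log scale (pairwise complete cases) and classifies its
#' scaling. Per-variable degenerate fits (constant columns and the like) are
#' flagged, not fatal.
#'
#' @param table a [measurement_table()] (raw mm; log-transform is applied
#'   internally with `base`) or a `log_table`.
#' @param method `"OLS"` or `"SMA"`.
#' @param base log base used when `table` is raw.
#' @param soft_threshold passed to [classify()].
#' @return A data.frame of class `allometry_results` with one row per
#'   non-reference variable: variable, method, n, slope, intercept, r2,
#'   ci_low, ci_high, p_vs_1, trend (`"+"`, `"-"`, `"iso"`), category,
#'   iso_subtype, stars, degenerate (logical).
#' @export
regress_all <- function(table, method = c("OLS", "SMA"), base = 10,
                        soft_threshold = 0.15) {
  method <- match.arg(method)
  stopifnot(inherits(table, "measurement_table"))
  logtab <- if (inherits(table, "log_table")) table else log_transform(table, base)
  vars <- setdiff(logtab$variable_ids, logtab$reference_id)
  fit_fun <- if (method == "OLS") fit_ols else fit_sma
  rows <- lapply(vars, function(vid) {
    pr <- log_pairs(logtab, vid)
    res <- tryCatch(fit_fun(pr$u, pr$v), error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(variable = vid, method = method, n = length(pr$u),
                        slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p_vs_1 = NA_real_,
                        trend = NA_character_, category = NA_character_,
                        iso_subtype = NA_character_, stars = NA_character_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    cl <- classify(res, soft_threshold = soft_threshold)
    data.frame(variable = vid, method = method, n = res$n, slope = res$slope,
               intercept = res$intercept, r2 = res$r2, ci_low = res$ci_low,
               ci_high = res$ci_high, p_vs_1 = res$p_vs_1,
               trend = switch(cl$category, positive = "+", negative = "-",
                              isometric = "iso"),
               category = cl$category, iso_subtype = cl$iso_subtype,
               stars = cl$stars, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("allometry_results", "data.frame")
  out
}

#' Export allometry results in report layout
#'
#' Columns ordered as in standard allometry result tables: variable, R2,
#' intercept, slope, lower and upper CI, trend, stars.
#'
#' @param results an `allometry_results` data.frame from [regress_all()].
#' @param path optional CSV output path.
#' @return The reordered data.frame (invisibly if `path` given).
#' @export
report_regression <- function(results, path = NULL) {
  out <- results[, c("variable", "r2", "intercept", "slope", "ci_low",
                     "ci_high", "trend", "stars")]
  names(out) <- c("variable", "R2", "intercept", "slope", "lCI", "uCI",
                  "trend", "sig")
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
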