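#' Build scaling points from slopes and minimum sample sizes
#'
#' Pairs each variable's fitted log-log slope (x) with its minimum sample
#' size for 95% categorical agreement (y). Censored minima (crossing never
#' reached within the sweep) keep their flag and are excluded from model
#' fitting rather than truncated to the sweep bound.
#'
#' @param slope numeric vector of fitted slopes.
#' @param min_n integer vector of minimum sample sizes (NA where censored).
#' @param censored logical vector (default: `is.na(min_n)`).
#' @return Data.frame of class `scaling_points`: slope, min_n, censored.
#' @export
scaling_points <- function(slope, min_n, censored = is.na(min_n)) {
  stopifnot(length(slope) == length(min_n), length(censored) == length(slope))
  out <- data.frame(slope = as.numeric(slope), min_n = as.numeric(min_n),
                    censored = as.logical(censored))
  if (any(!out$censored & out$min_n < 3, na.rm = TRUE)) {
    stop("non-censored minimum sample sizes must be >= 3", call. = FALSE)
  }
  class(out) <- c("scaling_points", "data.frame")
  out
}

# model prediction and per-parameter derivatives
.hyperbola_predict <- function(par, x, model) {
  m <- par[["m"]]; b <- par[["b"]]
  c0 <- if (model == "eq2") par[["c"]] else 0
  m / abs(x - b) + c0
}

# best (m[, c]) for fixed b, solved linearly; returns list(par, rss)
.hyperbola_profile <- function(b, x, y, model) {
  w <- 1 / abs(x - b)
  if (any(!is.finite(w))) return(NULL)
  if (model == "eq1") {
    m <- sum(y * w) / sum(w * w)
    r <- y - m * w
    list(par = c(m = m, b = b), rss = sum(r * r))
  } else {
    fit <- stats::lm.fit(cbind(1, w), y)
    cf <- fit$coefficients
    list(par = c(m = unname(cf[2]), b = b, c = unname(cf[1])),
         rss = sum(fit$residuals^2))
  }
}

#' Fit a hyperbolic minimum-n-versus-slope model
#'
#' Least-squares fit of `y = m / |x - b|` (`model = "eq1"`) or
#' `y = m / |x - b| + c` (`model = "eq2"`) to (slope, minimum sample size)
#' points. `b` locates the vertical asymptote (expected near the isometric
#' slope 1, where no finite sample suffices), `m` sets the curve shape, and
#' the optional `c` absorbs a vertical offset. The objective is non-smooth at
#' the data abscissae, so `b` is first profiled over a grid spanning
#' `(min x, max x)` (data abscissae excluded) with the remaining parameters
#' solved linearly, then the best grid point is refined by Nelder-Mead.
#' Parameter 95% CIs come from the asymptotic Jacobian-based covariance with
#' t quantiles on `n - p` degrees of freedom.
#'
#' @param points a [scaling_points()] data.frame (censored rows are dropped)
#'   or any data.frame with columns `slope` and `min_n`.
#' @param model `"eq1"` (two parameters) or `"eq2"` (three).
#' @param grid_points size of the initialization grid for `b` (default 201).
#' @return Object of class `hyperbolic_fit`: list with `model`, `par` (named
#'   vector m, b[, c]), `ci` (matrix with rows m, b[, c] and columns low,
#'   high), `rss`, `n_points`, `n_excluded`, `aic`.
#' @examples
#' x <- c(0.7, 0.9, 1.05, 1.2)
#' fit_hyperbola(scaling_points(x, round(3 / abs(x - 0.99))), "eq1")
#' @export
fit_hyperbola <- function(points, model = c("eq1", "eq2"), grid_points = 201) {
  model <- match.arg(model)
  stopifnot(is.data.frame(points), all(c("slope", "min_n") %in% names(points)))
  cens <- if ("censored" %in% names(points)) points$censored else is.na(points$min_n)
  use <- points[!cens & !is.na(points$min_n), , drop = FALSE]
  x <- use$slope; y <- use$min_n
  p <- if (model == "eq1") 2L else 3L
  if (length(x) < p + 2) {
    stop(sprintf("need at least %d non-censored points for %s (got %d)",
                 p + 2, model, length(x)), call. = FALSE)
  }
  # grid over b, avoiding the poles at the data abscissae
  grid <- seq(min(x), max(x), length.out = grid_points + 2)
  grid <- grid[-c(1, length(grid))]
  eps <- diff(range(x)) * 1e-9
  grid <- grid[vapply(grid, function(g) min(abs(g - x)) > eps, logical(1))]
  prof <- lapply(grid, .hyperbola_profile, x = x, y = y, model = model)
  rssv <- vapply(prof, function(z) if (is.null(z)) Inf else z$rss, numeric(1))
  if (!any(is.finite(rssv))) stop("no finite optimum on the b grid", call. = FALSE)
  start <- prof[[which.min(rssv)]]$par
  if (model == "eq2") {
    # nestedness: the eq1 optimum with c = 0 is a valid eq2 start
    e1 <- fit_hyperbola(points, "eq1", grid_points = grid_points)
    alt <- c(e1$par, c = 0)
    if (sum((y - .hyperbola_predict(alt, x, model))^2) < min(rssv)) start <- alt
  }
  obj <- function(par) {
    names(par) <- names(start)
    r <- y - .hyperbola_predict(par, x, model)
    sum(r * r)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  # polish the linear parameters at the refined b
  pol <- .hyperbola_profile(opt$par[["b"]], x, y, model)
  par <- if (!is.null(pol) && pol$rss <= opt$value) pol$par else {
    pp <- opt$par; names(pp) <- names(start); pp
  }
  rss <- sum((y - .hyperbola_predict(par, x, model))^2)
  ci <- .hyperbola_ci(par, x, y, rss, model)
  aic <- length(x) * log(rss / length(x)) + 2 * (p + 1)
  structure(list(model = model, par = par, ci = ci, rss = rss,
                 n_points = length(x), n_excluded = sum(cens), aic = aic),
            class = "hyperbolic_fit")
}

.hyperbola_ci <- function(par, x, y, rss, model) {
  w <- 1 / abs(x - par[["b"]])
  J <- cbind(m = w,
             b = par[["m"]] * w^2 * sign(x - par[["b"]]))
  if (model == "eq2") J <- cbind(J, c = rep(1, length(x)))
  p <- ncol(J)
  df <- length(x) - p
  ci <- matrix(NA_real_, p, 2, dimnames = list(colnames(J), c("low", "high")))
  if (df < 1 || rss <= 0) {
    ci[, 1] <- par[colnames(J)]
    ci[, 2] <- par[colnames(J)]
    return(ci)
  }
  s2 <- rss / df
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) return(ci)
  se <- sqrt(pmax(diag(cov), 0))
  tq <- stats::qt(0.975, df)
  ci[, 1] <- par[colnames(J)] - tq * se
  ci[, 2] <- par[colnames(J)] + tq * se
  ci
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("<hyperbolic_fit %s> %s; rss = %.4g, aic = %.4g, n = %d (%d censored excluded)\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
              x$rss, x$aic, x$n_points, x$n_excluded))
  invisible(x)
}

#' Akaike weights from AIC differences
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` — the normalized
#' evidence for each model in the set.
#'
#' @param delta numeric vector of AIC differences (minimum need not be 0; it
#'   is re-centered internally).
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(0, 1.767))
#' @export
akaike_weights <- function(delta) {
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Compare hyperbolic fits with AIC
#'
#' AIC is the Gaussian concentrated-likelihood form
#' `n * ln(rss / n) + 2 * k` with `k` = number of curve parameters plus one
#' for the residual variance; delta AIC and Akaike weights are therefore
#' free of the additive constant and comparable across models fitted to the
#' same points.
#'
#' @param fits list of `hyperbolic_fit` objects on the same point set.
#' @return Data.frame of class `model_comparison`: model, n_par, rss, aic,
#'   delta_aic, weight.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "hyperbolic_fit")))
  n <- vapply(fits, function(f) f$n_points, integer(1))
  if (length(unique(n)) != 1) {
    stop("fits use different point sets (n = ",
         paste(unique(n), collapse = ", "), ")", call. = FALSE)
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  out <- data.frame(model = vapply(fits, function(f) f$model, character(1)),
                    n_par = vapply(fits, function(f) length(f$par), integer(1)),
                    rss = vapply(fits, function(f) f$rss, numeric(1)),
                    aic = aic,
                    delta_aic = aic - min(aic),
                    weight = akaike_weights(aic - min(aic)),
                    stringsAsFactors = FALSE)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Model-fit report in tabular layout
#'
#' One row per reported quantity (residual SS, AIC, delta AIC, Akaike
#' weight, then each parameter with its 95% CI), one column per model.
#'
#' @param fits list of `hyperbolic_fit` objects.
#' @param path optional CSV output path.
#' @return The report data.frame (invisibly if `path` given).
#' @export
report_hyperbola <- function(fits, path = NULL) {
  cmp <- compare_models(fits)
  fmt_ci <- function(f, pname) {
    if (!pname %in% names(f$par)) return("NA")
    sprintf("%.3g (%.3g-%.3g)", f$par[[pname]], f$ci[pname, "low"],
            f$ci[pname, "high"])
  }
  out <- data.frame(quantity = c("residual_ss", "aic", "delta_aic",
                                 "akaike_weight", "m", "b", "c"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(fits)) {
    out[[cmp$model[i]]] <- c(sprintf("%.6g", cmp$rss[i]),
                             sprintf("%.6g", cmp$aic[i]),
                             sprintf("%.6g", cmp$delta_aic[i]),
                             sprintf("%.6g", cmp$weight[i]),
                             fmt_ci(fits[[i]], "m"),
                             fmt_ci(fits[[i]], "b"),
                             fmt_ci(fits[[i]], "c"))
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
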