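#' Run a Monte-Carlo subsampling sweep for one variable
#'
#' For each subsample size `n` in `n_range` and each of `reps` replicates:
#' draw a subsample under `scheme`, fit the log-log regression of the variable
#' against the reference by `method`, classify the scaling category, and
#' tally. The result is the data behind an allometric power plot: the
#' proportion of replicates concluding positive allometry, isometry, or
#' negative allometry at each sample size.
#'
#' Every replicate runs on its own RNG substream derived from
#' `(seed, scheme, variable_id, n, replicate)`, so single replicates are
#' independently reproducible. Degenerate fits (e.g., zero variance after
#' rounding) are counted as `failed` and excluded from the proportions.
#' Subsample sizes infeasible for a binned scheme (an empty bin, a too-small
#' size class) are recorded as skipped.
#'
#' @param table a [measurement_table()] (raw mm) or `log_table`.
#' @param variable_id variable to regress against the reference.
#' @param method `"OLS"` or `"SMA"`.
#' @param scheme subsampling scheme, see [draw_subsample()].
#' @param n_range integer vector of subsample sizes (all >= 3); default
#'   [default_sweep_range()] for the scheme.
#' @param reps replicates per subsample size (default 1000).
#' @param seed master seed.
#' @param base log base when `table` is raw.
#' @return An object of class `power_curve`: list with `variable_id`,
#'   `method`, `scheme`, `reps`, `seed`, and `table` — a data.frame with one
#'   row per n: n, n_positive, n_isometric, n_negative, n_failed, total,
#'   p_positive, p_isometric, p_negative, skipped.
#' @export
run_sweep <- function(table, variable_id, method = c("OLS", "SMA"),
                      scheme = c("random", "even_length", "even_occupancy",
                                 "adult_biased"),
                      n_range = NULL, reps = 1000, seed = 1, base = 10) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "measurement_table"), reps >= 1)
  if (is.null(n_range)) n_range <- default_sweep_range(scheme)
  if (any(n_range < 3)) stop("sweep subsample sizes must be >= 3", call. = FALSE)
  logtab <- if (inherits(table, "log_table")) table else log_transform(table, base)
  ref <- reference_values(if (inherits(table, "log_table")) unlog(table) else table)
  pr <- log_pairs(logtab, variable_id)
  # subsample indices refer to specimens present in the complete-pair set
  keep <- !is.na(logtab$values[, logtab$reference_id]) &
    !is.na(logtab$values[, variable_id])
  ref <- ref[keep]
  u_all <- pr$u; v_all <- pr$v
  N <- length(u_all)
  core <- if (method == "OLS") .fit_ols_core else .fit_sma_core

  rows <- lapply(n_range, function(n) {
    if (n > N || .infeasible(scheme, ref, n)) {
      return(data.frame(n = n, n_positive = 0L, n_isometric = 0L,
                        n_negative = 0L, n_failed = 0L, total = 0L,
                        p_positive = NA_real_, p_isometric = NA_real_,
                        p_negative = NA_real_, skipped = TRUE))
    }
    counts <- c(positive = 0L, isometric = 0L, negative = 0L, failed = 0L)
    for (r in seq_len(reps)) {
      set.seed(replicate_seed(seed, scheme, variable_id, n, r))
      idx <- draw_subsample(scheme, ref, n)
      fit <- core(u_all[idx], v_all[idx], n)
      cat_r <- if (is.null(fit)) "failed" else
        .classify_core(fit$ci_low, fit$ci_high)
      counts[cat_r] <- counts[cat_r] + 1L
    }
    ok <- sum(counts[c("positive", "isometric", "negative")])
    data.frame(n = n,
               n_positive = counts[["positive"]],
               n_isometric = counts[["isometric"]],
               n_negative = counts[["negative"]],
               n_failed = counts[["failed"]], total = reps,
               p_positive = if (ok > 0) counts[["positive"]] / ok else NA_real_,
               p_isometric = if (ok > 0) counts[["isometric"]] / ok else NA_real_,
               p_negative = if (ok > 0) counts[["negative"]] / ok else NA_real_,
               skipped = FALSE)
  })
  structure(list(variable_id = variable_id, method = method, scheme = scheme,
                 reps = reps, seed = seed, table = do.call(rbind, rows)),
            class = "power_curve")
}

# feasibility check that does not consume RNG
.infeasible <- function(scheme, ref, n) {
  switch(scheme,
         random = n > length(ref),
         even_length = !is.null(.even_length_assign(ref, n)$empty),
         even_occupancy = n > length(ref),
         adult_biased = sum(ref >= max(ref) / 2) < n - 1 ||
           sum(ref < max(ref) / 2) < 1)
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> %s / %s / %s, %d replicates, n = %d..%d (%d skipped)\n",
              x$variable_id, x$method, x$scheme, x$reps, min(x$table$n),
              max(x$table$n), sum(x$table$skipped)))
  invisible(x)
}

#' Minimum sample size for categorical agreement
#'
#' The smallest subsample size at which at least `level` (default 95%) of the
#' replicates reproduce the full-sample ("true") scaling category — the first
#' crossing, without a persistence requirement, so that e.g. proportions
#' 93% at n = 23 and 96% at n = 24 give a minimum of 24. Only defined for
#' allometric truths: isometry is the null hypothesis, and small subsamples
#' trivially "agree" with it. When the crossing is never reached the result
#' is censored at the sweep maximum (reported "> nmax").
#'
#' @param curve a `power_curve`.
#' @param true_category `"positive"` or `"negative"` (the full-sample
#'   classification).
#' @param level agreement level (default 0.95).
#' @param persistent if `TRUE`, require the proportion to stay at or above
#'   `level` for all larger n in the sweep (sensitivity variant; default
#'   `FALSE`, plain first crossing).
#' @return An object of class `min_sample_result`: list with `variable_id`,
#'   `method`, `scheme`, `true_category`, `level`, `min_n` (NA when censored
#'   or not applicable), `censored`, `sweep_max`, `label` (e.g. `"24"` or
#'   `"> 100"`).
#' @export
min_sample_for_agreement <- function(curve, true_category, level = 0.95,
                                     persistent = FALSE) {
  stopifnot(inherits(curve, "power_curve"))
  tab <- curve$table[!curve$table$skipped, , drop = FALSE]
  if (nrow(tab) == 0) stop("power curve has no usable subsample sizes", call. = FALSE)
  base_out <- list(variable_id = curve$variable_id, method = curve$method,
                   scheme = curve$scheme, true_category = true_category,
                   level = level, sweep_max = max(tab$n))
  if (true_category == "isometric") {
    out <- c(base_out, list(min_n = NA_integer_, censored = FALSE,
                            label = "not-applicable"))
    return(structure(out, class = "min_sample_result"))
  }
  if (!true_category %in% c("positive", "negative")) {
    stop("true_category must be 'positive', 'negative' or 'isometric'",
         call. = FALSE)
  }
  prop <- tab[[paste0("p_", true_category)]]
  hit <- !is.na(prop) & prop >= level
  if (persistent) hit <- rev(cumprod(rev(hit))) == 1
  if (any(hit)) {
    mn <- tab$n[which(hit)[1]]
    out <- c(base_out, list(min_n = mn, censored = FALSE,
                            label = as.character(mn)))
  } else {
    out <- c(base_out, list(min_n = NA_integer_, censored = TRUE,
                            label = paste0("> ", max(tab$n))))
  }
  structure(out, class = "min_sample_result")
}

#' @export
print.min_sample_result <- function(x, ...) {
  cat(sprintf("<min_sample> %s / %s / %s (truth %s): %s\n", x$variable_id,
              x$method, x$scheme, x$true_category, x$label))
  invisible(x)
}

#' Error-rate curves from a power curve
#'
#' Translates category proportions into the three subsampling errors. For an
#' allometric truth: false isometry (concluding isometry; the analogue of
#' Type II error) and sign error (allometry of the wrong direction); false
#' allometry is identically 0. For an isometric truth: false allometry
#' (concluding allometry either way; the analogue of Type I error); the other
#' two are identically 0.
#'
#' @param curve a `power_curve`.
#' @param true_category full-sample category (`"positive"`, `"negative"`,
#'   `"isometric"`).
#' @return Data.frame of class `error_rate_curve`: n, false_allometry,
#'   false_isometry, sign_error.
#' @export
error_rates <- function(curve, true_category) {
  stopifnot(inherits(curve, "power_curve"),
            true_category %in% c("positive", "negative", "isometric"))
  tab <- curve$table[!curve$table$skipped, , drop = FALSE]
  out <- data.frame(n = tab$n)
  if (true_category == "isometric") {
    out$false_allometry <- tab$p_positive + tab$p_negative
    out$false_isometry <- 0
    out$sign_error <- 0
  } else {
    opposite <- if (true_category == "positive") "p_negative" else "p_positive"
    out$false_allometry <- 0
    out$false_isometry <- tab$p_isometric
    out$sign_error <- tab[[opposite]]
  }
  class(out) <- c("error_rate_curve", "data.frame")
  out
}

#' Aggregate error-rate curves across variables
#'
#' Unweighted mean and sample SD per subsample size, per error type — the
#' summary drawn as solid (mean) and dotted (one SD) lines on error-rate
#' plots across all measured variables.
#'
#' @param curves list of `error_rate_curve` objects on a common n grid.
#' @return Data.frame: n, then mean_ and sd_ columns for false_allometry,
#'   false_isometry and sign_error.
#' @export
aggregate_error_rates <- function(curves) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$n
  for (cv in curves) {
    if (!identical(cv$n, grid)) {
      stop("error-rate curves are on different subsample-size grids", call. = FALSE)
    }
  }
  out <- data.frame(n = grid)
  for (type in c("false_allometry", "false_isometry", "sign_error")) {
    mat <- vapply(curves, function(cv) cv[[type]], numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    out[[paste0("mean_", type)]] <- rowMeans(mat)
    out[[paste0("sd_", type)]] <- apply(mat, 1, stats::sd)
  }
  out
}

#' Power-curve report rows
#'
#' Flattens power curves into the tabular layout behind power plots:
#' variable, method, scheme, n, reps, p_positive, p_isometric, p_negative,
#' n_failed.
#'
#' @param curves a `power_curve` or list of them.
#' @param path optional CSV output path.
#' @return The assembled data.frame (invisibly if `path` given).
#' @export
report_power <- function(curves, path = NULL) {
  if (inherits(curves, "power_curve")) curves <- list(curves)
  out <- do.call(rbind, lapply(curves, function(cv) {
    tab <- cv$table[!cv$table$skipped, , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    data.frame(variable = cv$variable_id, method = cv$method,
               scheme = cv$scheme, n = tab$n, reps = tab$total,
               p_positive = tab$p_positive, p_isometric = tab$p_isometric,
               p_negative = tab$p_negative, n_failed = tab$n_failed,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
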