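#' Construct a replicate-measurement set
#'
#' Holds repeated measurements of the same specimen/variable pairs, used to
#' summarize measurement error. Each record needs at least two replicates for
#' a deviation to be defined.
#'
#' @param records data.frame with columns `specimen_id`, `variable_id`,
#'   `instrument` (`"caliper"` or `"tape"`), and `values` (a list column of
#'   numeric replicate vectors), or built via repeated calls to
#'   `replicate_record()`.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("specimen_id", "variable_id", "instrument", "values") %in%
                  names(records)))
  if (!all(records$instrument %in% c("caliper", "tape"))) {
    stop("instrument must be 'caliper' or 'tape'", call. = FALSE)
  }
  k <- vapply(records$values, length, integer(1))
  if (any(k < 2)) {
    stop("every record needs k >= 2 replicate values (record ",
         which(k < 2)[1], " has ", k[k < 2][1], ")", call. = FALSE)
  }
  structure(list(records = records), class = "replicate_set")
}

#' Helper to build one replicate record
#'
#' @param specimen_id,variable_id labels.
#' @param instrument `"caliper"` or `"tape"`; if `NULL`, assigned from the
#'   replicate mean: < 150 mm caliper, otherwise tape (the instrument
#'   switch-over used when collecting skull measurements).
#' @param values numeric vector of k >= 2 replicate measurements (mm).
#' @return One-row data.frame suitable for [replicate_set()].
#' @export
replicate_record <- function(specimen_id, variable_id, values,
                             instrument = NULL) {
  if (is.null(instrument)) {
    instrument <- if (mean(values) < 150) "caliper" else "tape"
  }
  data.frame(specimen_id = specimen_id, variable_id = variable_id,
             instrument = instrument, values = I(list(as.numeric(values))),
             stringsAsFactors = FALSE)
}

#' Summarize measurement error from replicate measurements
#'
#' Per record: the average deviation (mean absolute difference between each
#' replicate and the replicate mean), the sample standard deviation, and the
#' mean magnitude. Per instrument: the unweighted mean average deviation over
#' records, and the Pearson correlation (with p-value) of per-record error
#' against per-record magnitude — a check on whether error scales with the
#' size of the measurement.
#'
#' @param reps a [replicate_set()].
#' @return A list of class `error_summary` with elements `per_record`
#'   (data.frame: specimen_id, variable_id, instrument, k, magnitude,
#'   average_deviation, standard_deviation) and `per_instrument` (data.frame:
#'   instrument, n_records, mean_average_deviation, cor_error_magnitude,
#'   cor_p_value).
#' @examples
#' rs <- replicate_set(rbind(
#'   replicate_record("s1", "v1", c(10.0, 10.2, 10.4)),
#'   replicate_record("s1", "v2", c(200, 202, 201), instrument = "tape")))
#' measurement_error_summary(rs)
#' @export
measurement_error_summary <- function(reps) {
  stopifnot(inherits(reps, "replicate_set"))
  rec <- reps$records
  per_record <- data.frame(
    specimen_id = rec$specimen_id,
    variable_id = rec$variable_id,
    instrument = rec$instrument,
    k = vapply(rec$values, length, integer(1)),
    magnitude = vapply(rec$values, mean, numeric(1)),
    average_deviation = vapply(rec$values,
                               function(x) mean(abs(x - mean(x))), numeric(1)),
    standard_deviation = vapply(rec$values, stats::sd, numeric(1)),
    stringsAsFactors = FALSE)
  per_instrument <- do.call(rbind, lapply(split(per_record, per_record$instrument),
    function(g) {
      if (nrow(g) >= 3 && stats::sd(g$average_deviation) > 0 &&
          stats::sd(g$magnitude) > 0) {
        ct <- stats::cor.test(g$average_deviation, g$magnitude)
        r <- unname(ct$estimate); p <- ct$p.value
      } else if (nrow(g) == 2 && diff(range(g$magnitude)) > 0) {
        r <- unname(stats::cor(g$average_deviation, g$magnitude)); p <- NA_real_
      } else {
        r <- NA_real_; p <- NA_real_
      }
      data.frame(instrument = g$instrument[1], n_records = nrow(g),
                 mean_average_deviation = mean(g$average_deviation),
                 cor_error_magnitude = r, cor_p_value = p,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_instrument) <- NULL
  structure(list(per_record = per_record, per_instrument = per_instrument),
            class = "error_summary")
}
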