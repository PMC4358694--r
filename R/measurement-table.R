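#' Construct a measurement table
#'
#' The unit of regression and subsampling: a specimens x variables matrix of
#' positive linear measurements (mm) with one column designated the reference
#' datum (here, typically basal skull length). Specimens lacking the reference
#' value are rejected: every downstream operation (log-log regression against
#' the reference, size-binned subsampling) is undefined without it.
#'
#' @param values numeric matrix, specimens in rows, variables in columns; NAs
#'   mark missing measurements. Must have row and column names unless
#'   `specimen_ids`/`variable_ids` are given.
#' @param reference_id column name of the reference variable.
#' @param specimen_ids,variable_ids optional dimnames overriding those of
#'   `values`.
#' @return An object of class `measurement_table`: a list with elements
#'   `values` (named matrix), `reference_id`, `specimen_ids`, `variable_ids`.
#' @examples
#' m <- matrix(c(29, 100, 689, 15, 50, 300), ncol = 2,
#'             dimnames = list(c("a", "b", "c"), c("bsl", "orbit")))
#' measurement_table(m, reference_id = "bsl")
#' @export
measurement_table <- function(values, reference_id,
                              specimen_ids = rownames(values),
                              variable_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(specimen_ids)) specimen_ids <- paste0("specimen_", seq_len(nrow(values)))
  if (is.null(variable_ids)) stop("variable_ids (column names) are required", call. = FALSE)
  specimen_ids <- as.character(specimen_ids)
  variable_ids <- as.character(variable_ids)
  stopifnot(length(specimen_ids) == nrow(values),
            length(variable_ids) == ncol(values))
  if (anyDuplicated(variable_ids)) stop("duplicate variable ids", call. = FALSE)
  if (!reference_id %in% variable_ids) {
    stop("reference_id '", reference_id, "' is not a variable of the table",
         call. = FALSE)
  }
  dimnames(values) <- list(specimen_ids, variable_ids)
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive measurement at specimen '%s', variable '%s' (lengths must be > 0 mm)",
                 specimen_ids[bad[1, 1]], variable_ids[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(values[, reference_id])) {
    stop("specimens missing the reference value must be dropped before construction; use read_measurement_table() or drop_missing_reference()",
         call. = FALSE)
  }
  structure(list(values = values,
                 reference_id = reference_id,
                 specimen_ids = specimen_ids,
                 variable_ids = variable_ids),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d specimens x %d variables (reference: %s)\n",
              length(x$specimen_ids), length(x$variable_ids), x$reference_id))
  cat(sprintf("  reference range: %.4g-%.4g mm\n",
              min(x$values[, x$reference_id]), max(x$values[, x$reference_id])))
  invisible(x)
}

#' @export
dim.measurement_table <- function(x) dim(x$values)

#' Subset a measurement table by specimen indices
#'
#' @param table a [measurement_table()].
#' @param i integer specimen indices.
#' @return A `measurement_table` (or `log_table`) with the selected specimens.
#' @export
subset_specimens <- function(table, i) {
  stopifnot(inherits(table, "measurement_table"))
  out <- table
  out$values <- table$values[i, , drop = FALSE]
  out$specimen_ids <- table$specimen_ids[i]
  out
}

#' Reference (size) values of a measurement table
#'
#' @param table a [measurement_table()].
#' @return Numeric vector of the reference variable, one value per specimen.
#' @export
reference_values <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  table$values[, table$reference_id]
}

#' Read a measurement table from CSV
#'
#' Expects a header row; the first column holds specimen ids, the remaining
#' columns are variables. Missing cells are empty or "NA". Rows missing the
#' reference value are dropped with a warning reporting the count.
#'
#' @param path path to a CSV file.
#' @param reference_id name of the reference variable column.
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path, reference_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("expected a specimen-id column plus at least one variable", call. = FALSE)
  ids <- df[[1]]
  vars <- names(df)[-1]
  if (!reference_id %in% vars) {
    stop("reference_id '", reference_id, "' not among columns: ",
         paste(vars, collapse = ", "), call. = FALSE)
  }
  num <- matrix(NA_real_, nrow(df), length(vars),
                dimnames = list(ids, vars))
  for (j in seq_along(vars)) {
    cell <- df[[j + 1]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("malformed numeric cell '%s' at row %d, column '%s'",
                   cell[bad[1]], bad[1], vars[j]), call. = FALSE)
    }
    num[, j] <- val
  }
  miss <- is.na(num[, reference_id])
  if (any(miss)) {
    warning(sprintf("dropped %d specimen(s) missing the reference value '%s'",
                    sum(miss), reference_id), call. = FALSE)
    num <- num[!miss, , drop = FALSE]
    ids <- ids[!miss]
  }
  measurement_table(num, reference_id = reference_id, specimen_ids = ids)
}

#' Write a measurement table to CSV
#'
#' Values are printed at full precision so a write/read round trip is
#' bit-identical.
#'
#' @param table a [measurement_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  df <- data.frame(specimen = table$specimen_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (v in table$variable_ids) {
    df[[v]] <- sprintf("%.17g", table$values[, v])
    df[[v]][is.na(table$values[, v])] <- ""
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform a measurement table
#'
#' Elementwise logarithm of all measurements prior to allometric analysis.
#' Slopes of log-log regressions are invariant to the base; intercepts are
#' reported in the chosen base (default 10).
#'
#' @param table a [measurement_table()]; must not already be log-transformed.
#' @param base logarithm base, positive and not 1.
#' @return A `log_table` (inherits `measurement_table`) with log values and a
#'   `base` element.
#' @examples
#' m <- matrix(c(10, 100, 1000, 1, 10, 100), ncol = 2,
#'             dimnames = list(NULL, c("bsl", "v1")))
#' lt <- log_transform(measurement_table(m, "bsl"))
#' lt$values
#' @export
log_transform <- function(table, base = 10) {
  stopifnot(inherits(table, "measurement_table"))
  if (inherits(table, "log_table")) {
    stop("table is already log-transformed; refusing to transform twice",
         call. = FALSE)
  }
  if (!is.numeric(base) || length(base) != 1 || base <= 0 || base == 1) {
    stop("base must be a positive number different from 1", call. = FALSE)
  }
  out <- table
  out$values <- log(table$values, base = base)
  out$base <- base
  class(out) <- c("log_table", "measurement_table")
  out
}

#' Invert a log table back to raw measurements
#'
#' @param table a `log_table`.
#' @return A `measurement_table` with raw mm values.
#' @export
unlog <- function(table) {
  stopifnot(inherits(table, "log_table"))
  out <- table
  out$values <- table$base^table$values
  out$base <- NULL
  class(out) <- "measurement_table"
  out
}

#' Complete log-log pairs for one variable against the reference
#'
#' Pairwise complete-case extraction used by all regressions: specimens with
#' the variable present (reference presence is guaranteed by construction).
#'
#' @param logtab a `log_table`.
#' @param variable_id variable to pair with the reference.
#' @return List with `u` (log reference) and `v` (log variable).
#' @keywords internal
log_pairs <- function(logtab, variable_id) {
  stopifnot(inherits(logtab, "log_table"))
  u <- logtab$values[, logtab$reference_id]
  v <- logtab$values[, variable_id]
  keep <- !is.na(u) & !is.na(v)
  list(u = u[keep], v = v[keep])
}
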