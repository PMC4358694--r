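#' Construct a literature-survey table
#'
#' Each record is one intraspecific sample from a published allometric study:
#' study label, species, vertebrate/invertebrate group, extinct/extant
#' status, and the sample size used. Samples (not studies) are the unit: a
#' study comparing several species contributes several records.
#'
#' @param records data.frame with columns `study`, `species`, `group`
#'   (`"invertebrate"`/`"vertebrate"`), `status` (`"extant"`/`"extinct"`),
#'   `n` (positive integer).
#' @return Data.frame of class `survey_table`.
#' @export
survey_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("study", "species", "group", "status", "n") %in% names(records)))
  bad <- which(!records$group %in% c("invertebrate", "vertebrate"))
  if (length(bad) > 0) {
    stop("unknown group '", records$group[bad[1]], "' at row ", bad[1], call. = FALSE)
  }
  bad <- which(!records$status %in% c("extant", "extinct"))
  if (length(bad) > 0) {
    stop("unknown status '", records$status[bad[1]], "' at row ", bad[1], call. = FALSE)
  }
  if (any(records$n < 1 | records$n != round(records$n))) {
    stop("sample sizes must be positive integers", call. = FALSE)
  }
  records$n <- as.integer(records$n)
  class(records) <- c("survey_table", "data.frame")
  records
}

#' Read a literature-survey table from CSV
#'
#' @param path CSV with columns study, species, group, status, n.
#' @return A [survey_table()].
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  survey_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Summarize sample sizes per (group, status) cell
#'
#' For each vertebrate/invertebrate x extant/extinct cell: number of samples,
#' minimum, maximum, arithmetic mean, median (midpoint of the two central
#' order statistics for even N), and the proportion of samples with n <= 10 —
#' the band where subsampling shows isometry conclusions to be unreliable.
#'
#' @param table a [survey_table()].
#' @return Data.frame of class `group_summary`: group, status, N, min, max,
#'   mean, median, prop_n_le_10.
#' @export
summarize_groups <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  cells <- expand.grid(group = c("invertebrate", "vertebrate"),
                       status = c("extant", "extinct"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$n[table$group == cells$group[i] & table$status == cells$status[i]]
    if (length(sel) == 0) {
      warning(sprintf("no samples for %s %s; cell omitted", cells$group[i],
                      cells$status[i]), call. = FALSE)
      return(NULL)
    }
    data.frame(group = cells$group[i], status = cells$status[i],
               N = length(sel), min = min(sel), max = max(sel),
               mean = mean(sel), median = stats::median(sel),
               prop_n_le_10 = mean(sel <= 10), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of sample-size distributions
#'
#' D is the supremum distance between the two empirical CDFs; the two-sided
#' p-value is asymptotic (integer sample sizes carry heavy ties, for which
#' the exact small-sample p is not defined).
#'
#' @param a,b numeric vectors of sample sizes.
#' @return List with `D`, `p_value`, `n_a`, `n_b`, `ties` (logical).
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b), ties = ties)
}

#' Pairwise KS comparisons between survey cells
#'
#' The four standard pairings: extant vs extinct within each group, and
#' vertebrate vs invertebrate within each status. Significance bands:
#' `***` p < 0.001, `*` p < 0.05, blank otherwise.
#'
#' @param table a [survey_table()].
#' @return Data.frame: comparison, D, p_value, significance.
#' @export
compare_survey_groups <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  cell <- function(g, s) table$n[table$group == g & table$status == s]
  pairs <- list(
    "invertebrate: extant vs extinct" = list(cell("invertebrate", "extant"),
                                             cell("invertebrate", "extinct")),
    "vertebrate: extant vs extinct" = list(cell("vertebrate", "extant"),
                                           cell("vertebrate", "extinct")),
    "extant: vertebrate vs invertebrate" = list(cell("vertebrate", "extant"),
                                                cell("invertebrate", "extant")),
    "extinct: vertebrate vs invertebrate" = list(cell("vertebrate", "extinct"),
                                                 cell("invertebrate", "extinct")))
  rows <- lapply(names(pairs), function(nm) {
    ab <- pairs[[nm]]
    if (length(ab[[1]]) == 0 || length(ab[[2]]) == 0) {
      warning("comparison '", nm, "' skipped: empty cell", call. = FALSE)
      return(NULL)
    }
    kt <- ks_compare(ab[[1]], ab[[2]])
    data.frame(comparison = nm, D = kt$D, p_value = kt$p_value,
               significance = if (kt$p_value < 0.001) "***" else
                 if (kt$p_value < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Survey report: group summaries plus KS comparisons
#'
#' @param table a [survey_table()].
#' @param summary_path,comparison_path optional CSV output paths.
#' @return List with `summary` and `comparisons` data.frames.
#' @export
report_survey <- function(table, summary_path = NULL, comparison_path = NULL) {
  s <- summarize_groups(table)
  k <- compare_survey_groups(table)
  if (!is.null(summary_path)) utils::write.csv(s, summary_path, row.names = FALSE)
  if (!is.null(comparison_path)) utils::write.csv(k, comparison_path, row.names = FALSE)
  list(summary = s, comparisons = k)
}
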