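#' Random subsample without replacement
#'
#' Uniform draw of `n` distinct specimens from `N`, the baseline Monte-Carlo
#' scheme: every specimen is equally likely regardless of its size.
#'
#' @param N population size.
#' @param n subsample size, `3 <= n <= N`.
#' @return Integer vector of `n` distinct indices in `1..N`.
#' @export
random_subsample <- function(N, n) {
  if (n < 2) stop("subsample size must be at least 2", call. = FALSE)
  if (n > N) stop("subsample size ", n, " exceeds population size ", N, call. = FALSE)
  sample.int(N, n, replace = FALSE)
}

#' Even-length binned subsample
#'
#' Splits the reference-size range into `n` equal-width intervals (half-open
#' except the last, which is closed at the maximum) and draws one specimen
#' uniformly from each. Maximizes and evens out the size coverage of the
#' subsample — the best-case sampling scenario. Errors when a bin is empty
#' (with sparse size series this bounds the usable `n`).
#'
#' @param ref numeric vector of reference sizes (mm), one per specimen.
#' @param n number of bins = subsample size, `n >= 3`.
#' @return Integer vector of `n` distinct specimen indices.
#' @export
even_length_bins <- function(ref, n) {
  if (n < 2) stop("subsample size must be at least 2", call. = FALSE)
  assign <- .even_length_assign(ref, n)
  if (!is.null(assign$empty)) {
    stop(sprintf("even-length bin %d of %d ([%.6g, %.6g%s) is empty; n = %d infeasible for this size series",
                 assign$empty, n, assign$breaks[assign$empty],
                 assign$breaks[assign$empty + 1],
                 if (assign$empty == n) "]" else ")", n),
         call. = FALSE)
  }
  vapply(assign$bins, function(ix) if (length(ix) == 1) ix else
    ix[sample.int(length(ix), 1)], integer(1))
}

# bin membership for even-length bins; returns bins (list of index vectors),
# breaks, and the first empty bin (or NULL)
.even_length_assign <- function(ref, n) {
  lo <- min(ref); hi <- max(ref)
  if (hi <= lo) return(list(bins = NULL, breaks = NULL, empty = 1L))
  breaks <- lo + (hi - lo) * (0:n) / n
  bin <- pmin(floor((ref - lo) / (hi - lo) * n) + 1, n)  # max goes to last bin
  bins <- lapply(seq_len(n), function(b) which(bin == b))
  sizes <- lengths(bins)
  empty <- if (any(sizes == 0)) which(sizes == 0)[1] else NULL
  list(bins = bins, breaks = breaks, empty = empty)
}

#' Even-occupancy binned subsample
#'
#' Sorts specimens by reference size (ties kept in input order), cuts the
#' sorted series into `n` bins of (as near as possible) equal occupancy with
#' boundaries at `round(i * N / n)` (round-half-to-even), and draws one
#' specimen uniformly per bin.
#'
#' @inheritParams even_length_bins
#' @return Integer vector of `n` distinct specimen indices (into `ref`).
#' @export
even_occupancy_bins <- function(ref, n) {
  N <- length(ref)
  if (n < 2) stop("subsample size must be at least 2", call. = FALSE)
  if (n > N) stop("subsample size ", n, " exceeds population size ", N, call. = FALSE)
  ord <- order(ref)               # radix sort: stable in input order for ties
  bounds <- c(0, round(seq_len(n - 1) * N / n), N)
  picks <- integer(n)
  for (b in seq_len(n)) {
    ix <- (bounds[b] + 1):bounds[b + 1]
    picks[b] <- if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
  }
  ord[picks]
}

#' Adult-biased subsample
#'
#' Mimics taphonomic/collection bias toward large individuals: specimens are
#' split at half the maximum reference size; `n - 1` are drawn without
#' replacement from the large ("adult") class (sizes at or above half the
#' maximum) and exactly one from the small class (sizes strictly below).
#'
#' @inheritParams even_length_bins
#' @return Integer vector of `n` distinct specimen indices.
#' @export
adult_biased <- function(ref, n) {
  if (n < 2) stop("subsample size must be at least 2", call. = FALSE)
  half <- max(ref) / 2
  large <- which(ref >= half)
  small <- which(ref < half)
  if (length(large) < n - 1) {
    stop(sprintf("large size class has %d specimen(s); need n - 1 = %d",
                 length(large), n - 1), call. = FALSE)
  }
  if (length(small) < 1) {
    stop("small size class (reference < max/2) is empty", call. = FALSE)
  }
  c(large[sample.int(length(large), n - 1)],
    small[sample.int(length(small), 1)])
}

#' Draw a subsample under a named scheme
#'
#' Dispatcher over the four Monte-Carlo subsampling schemes.
#'
#' @param scheme one of `"random"`, `"even_length"`, `"even_occupancy"`,
#'   `"adult_biased"`.
#' @param ref reference sizes of the full series.
#' @param n subsample size.
#' @return Integer vector of `n` distinct specimen indices.
#' @export
draw_subsample <- function(scheme = c("random", "even_length",
                                      "even_occupancy", "adult_biased"),
                           ref, n) {
  scheme <- match.arg(scheme)
  switch(scheme,
         random = random_subsample(length(ref), n),
         even_length = even_length_bins(ref, n),
         even_occupancy = even_occupancy_bins(ref, n),
         adult_biased = adult_biased(ref, n))
}

#' Default sweep range for a scheme
#'
#' Random subsampling sweeps n = 3..100; even-occupancy and adult-biased
#' 3..20; even-length 3..10 (sparse tails of real size series rarely permit
#' more even-length bins).
#'
#' @param scheme scheme name as in [draw_subsample()].
#' @return Integer vector of subsample sizes.
#' @export
default_sweep_range <- function(scheme = c("random", "even_length",
                                           "even_occupancy", "adult_biased")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         random = 3:100,
         even_length = 3:10,
         even_occupancy = 3:20,
         adult_biased = 3:20)
}
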