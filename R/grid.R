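#' Discrete time grid
#'
#' A grid of `k` right-open time intervals \eqn{[0, a_1), [a_1, a_2), \ldots,
#' [a_{k-1}, \infty)}. Interval index `t` refers to \eqn{[a_{t-1}, a_t)} with
#' \eqn{a_0 = 0} and \eqn{a_k = \infty}. Cut points are optional: purely
#' discrete data carry only `k`.
#'
#' @param k Number of intervals (integer, at least 2).
#' @param cut_points Optional strictly increasing numeric vector of the
#'   `k - 1` interior boundaries \eqn{a_1 < \ldots < a_{k-1}}, in the units of
#'   the raw times.
#' @return An object of class `time_grid`.
#' @export
#' @examples
#' time_grid(4, cut_points = c(1, 2, 5))
time_grid <- function(k, cut_points = NULL) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("'k' must be a single integer >= 2")
  if (!is.null(cut_points)) {
    cut_points <- as.numeric(cut_points)
    if (length(cut_points) != k - 1L)
      stop("'cut_points' must have length k - 1 = ", k - 1L)
    if (any(!is.finite(cut_points)) || any(diff(cut_points) <= 0))
      stop("'cut_points' must be finite and strictly increasing")
  }
  structure(list(k = k, cut_points = cut_points), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Discrete time grid: k =", x$k, "intervals\n")
  if (!is.null(x$cut_points))
    cat("  cut points:", paste(signif(x$cut_points, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Discretize continuous times into empirical-quantile intervals
#'
#' Maps continuous non-negative times onto a grid of `k` intervals whose
#' interior boundaries are the \eqn{j/k} empirical quantiles
#' (\eqn{j = 1, \ldots, k-1}) of the supplied times. A value exactly equal to
#' a cut point belongs to the higher interval (intervals are right-open).
#'
#' Which times to pool is the caller's choice; the competing-risks simulator
#' pools the uncensored continuous event times of both event types.
#'
#' @param times Numeric vector of continuous non-negative times.
#' @param k Number of intervals (at least 2).
#' @param grid Optional existing `time_grid` with cut points; when given,
#'   `times` are mapped onto it and no quantiles are computed.
#' @return A list with components `index` (integer interval indices in
#'   `1:k`) and `grid` (the `time_grid` used).
#' @export
#' @examples
#' d <- discretize_times(rexp(100), k = 5)
#' table(d$index)
discretize_times <- function(times, k, grid = NULL) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative")
  if (is.null(grid)) {
    k <- as.integer(k)
    if (k < 2L) stop("'k' must be >= 2")
    if (length(unique(times)) < k)
      stop("degenerate grid: fewer than k = ", k, " distinct time values")
    cuts <- unname(stats::quantile(times, probs = seq_len(k - 1L) / k))
    if (any(diff(cuts) <= 0))
      stop("degenerate grid: tied empirical quantiles")
    grid <- time_grid(k, cut_points = cuts)
  } else {
    if (!inherits(grid, "time_grid") || is.null(grid$cut_points))
      stop("'grid' must be a time_grid with cut points")
  }
  idx <- findInterval(times, grid$cut_points) + 1L
  list(index = as.integer(idx), grid = grid)
}
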