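#' Life-table estimate of the censoring survival function
#'
#' Estimates \eqn{G(t) = P(C > t)} on \eqn{t = 0, 1, \ldots, k-1} from
#' discrete competing-risks data by a product-limit life table over the
#' discrete censoring hazards,
#' \deqn{\hat G(t) = \prod_{s \le t} (1 - c_s / n^c_s),}
#' with \eqn{c_s} the number of censored records in interval `s` and
#' \eqn{n^c_s} the censoring risk set. Because ties within an interval are
#' resolved in favour of the event (\eqn{\Delta_i = I(T_i \le C_i)}), a
#' censoring in the same interval as an event can never be observed; the
#' censoring risk set therefore excludes the records whose event occurred in
#' interval `s` (the reverse-Kaplan-Meier tie rule),
#' \eqn{n^c_s = \#\{\tilde T_i \ge s\} - \#\{\tilde T_i = s,\,
#' \Delta_i \epsilon_i > 0\}}. This keeps the censoring-hazard estimator
#' unbiased under independent censoring when event and censoring hazards
#' share intervals.
#'
#' \eqn{\hat G(0) = 1} by construction of the 1-based grid. \eqn{G(k-1)} is
#' the last estimable value: a censoring in the final interval is never
#' observable under the tie rule.
#'
#' @param data A [cr_dataset].
#' @return An object of class `censoring_survival`: a list with `time`
#'   (`0:(k-1)`), `surv` (\eqn{\hat G(t)}), `at_risk` (censoring risk sets
#'   \eqn{n^c_t}, `NA` at t = 0) and `censored` (counts \eqn{c_t}).
#' @export
#' @examples
#' d <- cr_dataset(c(1, 2, 2, 3), c(0, 1, 0, 2), matrix(0, 4, 1), k = 4)
#' censoring_survival(d)
censoring_survival <- function(data) {
  stopifnot(inherits(data, "cr_dataset"))
  k <- data$grid$k
  n_at <- rev(cumsum(rev(tabulate(data$time, nbins = k))))  # #{T~ >= s}
  d_ev <- tabulate(data$time[data$status > 0L], nbins = k)
  c_cn <- tabulate(data$time[data$status == 0L], nbins = k)
  risk <- n_at - d_ev
  G <- numeric(k)  # G[t + 1] = G(t), t = 0..k-1
  G[1L] <- 1
  warned <- FALSE
  for (s in seq_len(k - 1L)) {
    if (risk[s] <= 0L) {
      if (c_cn[s] > 0L) stop("censoring risk set empty at interval ", s,
                             " but censored records present")
      if (!warned && s < max(data$time)) {
        warning("empty censoring risk set at interval ", s,
                "; carrying last value forward")
        warned <- TRUE
      }
      G[s + 1L] <- G[s]
    } else {
      G[s + 1L] <- G[s] * (1 - c_cn[s] / risk[s])
    }
  }
  structure(list(time = 0:(k - 1L), surv = G,
                 at_risk = c(NA_integer_, risk[seq_len(k - 1L)]),
                 censored = c(NA_integer_, c_cn[seq_len(k - 1L)])),
            class = "censoring_survival")
}

#' @export
print.censoring_survival <- function(x, ...) {
  cat("Censoring survival function G(t) = P(C > t), life-table estimate\n")
  print(data.frame(t = x$time, G = signif(x$surv, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.censoring_survival <- function(x, ...) {
  data.frame(t = x$time, G = x$surv)
}

# G(t) lookup for t in 0..k-1 (vectorized)
G_at <- function(G, t) G$surv[t + 1L]
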