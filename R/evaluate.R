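#' Aalen-Johansen cumulative incidence estimator
#'
#' Covariate-free nonparametric CIF for event type `j` in the presence of
#' competing risks,
#' \deqn{\hat F_j(t) = \sum_{s \le t} \hat S(s-1)\, d_{js} / n_s,}
#' with \eqn{n_s} the all-cause risk set, \eqn{d_{js}} the type-`j` event
#' count in interval `s`, and \eqn{\hat S} the all-cause Kaplan-Meier
#' survival (\eqn{\hat S(0) = 1}).
#'
#' @param data A [cr_dataset].
#' @param j Event type in `1:J`.
#' @return An object of class `step_cif`: list with `time` (`1:k`), `cif`,
#'   `at_risk` and `events` (type-`j` counts).
#' @export
aalen_johansen <- function(data, j = 1L) {
  stopifnot(inherits(data, "cr_dataset"))
  if (!j %in% seq_len(data$J)) stop("'j' must be an event type in 1..J")
  k <- data$grid$k
  n_at <- rev(cumsum(rev(tabulate(data$time, nbins = k))))
  d_j <- tabulate(data$time[data$status == j], nbins = k)
  d_all <- tabulate(data$time[data$status > 0L], nbins = k)
  cif <- numeric(k)
  S <- 1
  warned <- FALSE
  for (s in seq_len(k)) {
    if (n_at[s] == 0L) {
      if (!warned && s < max(data$time)) {
        warning("empty risk set at interval ", s, "; carrying forward")
        warned <- TRUE
      }
      cif[s] <- if (s > 1L) cif[s - 1L] else 0
      next
    }
    cif[s] <- (if (s > 1L) cif[s - 1L] else 0) + S * d_j[s] / n_at[s]
    S <- S * (1 - d_all[s] / n_at[s])
  }
  structure(list(time = seq_len(k), cif = cif, at_risk = n_at, events = d_j),
            class = "step_cif")
}

#' Kaplan-Meier complement on single-event data
#'
#' \eqn{1 - \hat S_{KM}(t)} from a single-event dataset, evaluated on the
#' grid `1:k`. When the dataset has a single event type and no competing
#' events this coincides with the Aalen-Johansen estimator. Computed with
#' [survival::survfit()].
#'
#' @param data An [se_dataset].
#' @return A `step_cif`.
#' @export
km_complement <- function(data) {
  stopifnot(inherits(data, "se_dataset"))
  k <- data$grid$k
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = data.frame(time = data$time,
                                             event = data$event))
  sm <- summary(fit, times = seq_len(k), extend = TRUE)
  structure(list(time = seq_len(k), cif = 1 - sm$surv,
                 at_risk = sm$n.risk, events = sm$n.event),
            class = "step_cif")
}

#' @export
print.step_cif <- function(x, ...) {
  cat("Step cumulative incidence on", length(x$time), "intervals\n")
  print(data.frame(t = x$time, cif = signif(x$cif, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.step_cif <- function(x, ...) {
  data.frame(t = x$time, cif = x$cif)
}

#' Calibration curves: model-averaged CIF against a nonparametric reference
#'
#' Averages per-individual model CIF curves over a test set and pairs them
#' with a covariate-free reference (typically [aalen_johansen()] on the
#' original competing-risks test data). The sup-norm gap is taken over
#' `t = 1..k-1` by default: when imputed censoring times are capped at
#' `k-1`, the final interval of single-event data contains no censored
#' records and its hazard estimate is structurally degenerate.
#'
#' @param model_cifs Matrix of per-individual CIF values (n x k, as from
#'   [predict_cif()]) or an already-averaged numeric vector of length `k`.
#' @param reference A `step_cif` (or numeric vector of length `k`).
#' @param drop_last Exclude the final interval from the gap (default TRUE).
#' @return A data frame `(time, model, reference)` with attribute `"gap"`,
#'   the sup-norm distance over the compared intervals.
#' @export
calibration_curves <- function(model_cifs, reference, drop_last = TRUE) {
  model <- if (is.matrix(model_cifs)) colMeans(model_cifs)
           else as.numeric(model_cifs)
  ref <- if (inherits(reference, "step_cif")) reference$cif
         else as.numeric(reference)
  if (length(model) != length(ref))
    stop("model and reference are on different grids")
  k <- length(ref)
  cmp <- if (drop_last && k > 1L) seq_len(k - 1L) else seq_len(k)
  out <- data.frame(time = seq_len(k), model = model, reference = ref)
  attr(out, "gap") <- max(abs(model[cmp] - ref[cmp]))
  out
}

#' Sup-norm calibration gap
#'
#' @inheritParams calibration_curves
#' @return The sup-norm distance between the averaged model CIF and the
#'   reference.
#' @export
calibration_gap <- function(model_cifs, reference, drop_last = TRUE) {
  attr(calibration_curves(model_cifs, reference, drop_last), "gap")
}

#' Time-dependent concordance index for competing risks (IPCW)
#'
#' Estimates
#' \deqn{C_1(t) = P(M(t,x_i) > M(t,x_j) \mid \epsilon_i = 1,\,
#'       T_i \le t,\, (T_i < T_j \ \mathrm{or}\ \epsilon_j = 2))}
#' by inverse-probability-of-censoring weighting. Ordered pairs with an
#' observed type-1 event for `i` at \eqn{T_i \le t} are compared against
#' every `j` observed beyond \eqn{T_i} (pair weight
#' \eqn{\hat G(T_i-1)^{-2}}) and against every `j` with an observed
#' competing event at or before \eqn{T_i} (pair weight
#' \eqn{\hat G(T_i-1)^{-1} \hat G(T_j-1)^{-1}}), where \eqn{\hat G} is the
#' censoring life table of the evaluation data. Marker ties count 1/2.
#' Without censoring all weights are 1 and the estimate reduces to the
#' plain comparable-pair concordance fraction.
#'
#' @param data A [cr_dataset] (evaluation set).
#' @param marker Numeric vector \eqn{M(t, x_i)} for all individuals, or a
#'   matrix whose column `t` is used. Larger markers should indicate
#'   earlier type-1 events; the default choice is the model CIF
#'   \eqn{\hat F_1(t|x)}.
#' @param t Evaluation time in `1..k-1`.
#' @param censoring Optional precomputed [censoring_survival].
#' @return \eqn{\hat C_1(t)} in `[0, 1]`, or `NA` when no comparable pairs
#'   exist.
#' @export
cindex_ipcw <- function(data, marker, t, censoring = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  k <- data$grid$k
  t <- as.integer(t)
  if (t < 1L || t > k - 1L) stop("'t' must lie in 1..k-1")
  if (is.matrix(marker)) marker <- marker[, t]
  if (length(marker) != length(data$time))
    stop("'marker' must provide one value per individual")
  if (is.null(censoring)) censoring <- censoring_survival(data)
  Ginv <- 1 / G_at(censoring, data$time - 1L)
  num <- den <- 0
  for (s in unique(data$time[data$status == 1L & data$time <= t])) {
    I <- which(data$status == 1L & data$time == s)
    mi <- marker[I]
    # pairs against individuals observed beyond s
    A <- which(data$time > s)
    if (length(A)) {
      mj <- sort(marker[A])
      lt <- findInterval(mi, mj, left.open = TRUE)
      le <- findInterval(mi, mj)
      wA <- Ginv[I]^2
      num <- num + sum(wA * (lt + 0.5 * (le - lt)))
      den <- den + sum(wA) * length(A)
    }
    # pairs against competing events at or before s
    B <- which(data$status == 2L & data$time <= s)
    if (length(B)) {
      o <- order(marker[B])
      mj <- marker[B][o]
      cw <- cumsum(Ginv[B][o])
      tot <- cw[length(cw)]
      lt <- findInterval(mi, mj, left.open = TRUE)
      le <- findInterval(mi, mj)
      cw0 <- c(0, cw)
      sw_lt <- cw0[lt + 1L]
      sw_le <- cw0[le + 1L]
      wB <- Ginv[I]
      num <- num + sum(wB * (sw_lt + 0.5 * (sw_le - sw_lt)))
      den <- den + sum(wB) * tot
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Concordance curve over the grid
#'
#' Evaluates [cindex_ipcw()] at every `t = 1..k-1`.
#'
#' @param data A [cr_dataset].
#' @param marker An n x (k-1) (or n x k) marker matrix, column `t` holding
#'   \eqn{M(t, x_i)}.
#' @param censoring Optional precomputed [censoring_survival].
#' @return Numeric vector of \eqn{\hat C_1(t)}, `NA` where undefined.
#' @export
cindex_curve <- function(data, marker, censoring = NULL) {
  k <- data$grid$k
  if (is.null(censoring)) censoring <- censoring_survival(data)
  vapply(seq_len(k - 1L), function(t)
    cindex_ipcw(data, marker, t, censoring = censoring), numeric(1L))
}

#' Time-averaged concordance
#'
#' Unweighted mean of \eqn{\hat C_1(t)} over the time points where it is
#' defined.
#'
#' @param cvals Numeric vector of per-time concordance values (as from
#'   [cindex_curve()]); `NA` entries are excluded.
#' @return The mean, or `NA` when no time point is defined.
#' @export
mean_cindex <- function(cvals) {
  if (all(is.na(cvals))) {
    warning("concordance undefined at every time point")
    return(NA_real_)
  }
  mean(cvals, na.rm = TRUE)
}
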