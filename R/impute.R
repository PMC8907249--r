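#' Subdistribution weights for competing-event individuals
#'
#' After a competing event at \eqn{\tilde T_i}, individual `i` conceptually
#' remains in the type-1 risk set until censored. The probability of still
#' being at risk at time `t`, given membership at \eqn{\tilde T_i}, is
#' estimated by the subdistribution weight
#' \deqn{w_{it} = \hat G(t-1) / \hat G(\tilde T_i - 1), \qquad
#'       \tilde T_i < t \le k-1,}
#' with \eqn{w_{it} = 1} for \eqn{t \le \tilde T_i}. The weights are
#' non-increasing in `t` and lie in \eqn{[0, 1]}.
#'
#' From the weights, a per-individual censoring-time distribution is formed
#' on the support \eqn{\{\tilde T_i, \ldots, k-1\}}:
#' \eqn{P(\hat C_i = t) = w_{it} - w_{i,t+1}} for \eqn{t \le k-2}, with the
#' residual mass \eqn{w_{i,k-1}} placed on \eqn{t = k-1} (administrative end
#' of estimable follow-up). This is exactly the estimated conditional law of
#' the censoring time given \eqn{C \ge \tilde T_i}, truncated at
#' \eqn{k-1}; it satisfies \eqn{P(\hat C_i \ge t) = w_{it}} for every `t`,
#' so a record censored at \eqn{\hat C_i} contributes to the discrete risk
#' set at `t` with expectation exactly \eqn{w_{it}}. The distribution sums
#' to 1 by construction.
#'
#' Since the censoring model is marginal, weights and distributions depend
#' on `i` only through \eqn{\tilde T_i}.
#'
#' @param data A [cr_dataset].
#' @param censoring A [censoring_survival] estimated on the same grid;
#'   defaults to `censoring_survival(data)`.
#' @return An object of class `subdist_weights`: list with `W` (n x (k-1)
#'   weight matrix; all-ones rows for individuals without a competing
#'   event), `pmf` (per observed time \eqn{\tilde T}: `support` and `prob`
#'   of the imputed-censoring distribution), `status`, `time`, `grid` and
#'   `censoring`.
#' @export
subdist_weights <- function(data, censoring = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  if (is.null(censoring)) censoring <- censoring_survival(data)
  k <- data$grid$k
  if (length(censoring$surv) != k)
    stop("'censoring' was not estimated on the same grid (k mismatch)")
  n <- length(data$time)
  W <- matrix(1, n, k - 1L)
  comp <- which(data$status >= 2L)
  bad <- comp[G_at(censoring, data$time[comp] - 1L) <= 0]
  if (length(bad))
    stop("degenerate weights: G(T-1) = 0 for individual(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; no later censoring is estimable")
  pmf <- vector("list", k)
  for (Ti in sort(unique(data$time[comp]))) {
    rows <- comp[data$time[comp] == Ti]
    if (Ti >= k - 1L) {
      pmf[[Ti]] <- list(support = k - 1L, prob = 1)
      next
    }
    tt <- Ti:(k - 1L)
    w <- G_at(censoring, tt - 1L) / G_at(censoring, Ti - 1L)
    W[rows, tt[-1L]] <- rep(w[-1L], each = length(rows))
    pmf[[Ti]] <- list(support = tt,
                      prob = c(w[-length(w)] - w[-1L], w[length(w)]))
  }
  structure(list(W = W, pmf = pmf, status = data$status, time = data$time,
                 grid = data$grid, censoring = censoring),
            class = "subdist_weights")
}

#' Sample one imputed censoring time
#'
#' Draws \eqn{\hat C_i} for a single competing-event individual from its
#' subdistribution censoring-time distribution (see [subdist_weights()]),
#' using the current RNG state. Individuals with \eqn{\tilde T_i \ge k-1}
#' receive the degenerate draw \eqn{\hat C_i = k-1}.
#'
#' @param weights A [subdist_weights] object.
#' @param i Individual index; must have status >= 2.
#' @return A list with `index`, `time` (the sampled \eqn{\hat C_i},
#'   satisfying \eqn{\hat C_i \ge \tilde T_i}), `support` and `prob`.
#' @export
sample_imputed_censoring <- function(weights, i) {
  stopifnot(inherits(weights, "subdist_weights"))
  if (weights$status[i] < 2L)
    stop("individual ", i, " has status ", weights$status[i],
         "; only competing-event individuals (status >= 2) are imputed")
  pm <- weights$pmf[[weights$time[i]]]
  ci <- if (length(pm$support) == 1L) pm$support
        else sample(pm$support, 1L, prob = pm$prob)
  list(index = i, time = as.integer(ci),
       support = pm$support, prob = pm$prob)
}

# vectorized draws for all competing individuals; uses current RNG state
sample_all_imputed <- function(weights) {
  comp <- which(weights$status >= 2L)
  out <- integer(length(comp))
  for (Ti in sort(unique(weights$time[comp]))) {
    sel <- weights$time[comp] == Ti
    pm <- weights$pmf[[Ti]]
    out[sel] <- if (length(pm$support) == 1L) rep(pm$support, sum(sel))
                else sample(pm$support, sum(sel), replace = TRUE,
                            prob = pm$prob)
  }
  names(out) <- comp
  out
}

#' Impute censoring times after competing events
#'
#' Converts a discrete competing-risks dataset into a single-event dataset.
#' Individuals with status 0 (censored) or 1 (event of interest) pass
#' through unchanged. For each individual with a competing event (status
#' >= 2) the subdistribution time is \eqn{\vartheta_i = \infty}, so the
#' event indicator is 0 and the unobserved \eqn{\min(\vartheta_i, C_i) =
#' C_i} is imputed by a draw \eqn{\hat C_i} from the subdistribution
#' censoring-time distribution. A single imputation is performed; see
#' [impute_replicates()] for the repeated-imputation protocol.
#'
#' @param data A [cr_dataset] with k >= 3.
#' @param seed Optional integer seed making the imputation reproducible.
#' @param weights Optional precomputed [subdist_weights].
#' @return An [se_dataset] with the same individuals and covariates.
#' @export
#' @seealso [naive_censor()] for the baseline that keeps competing-event
#'   times as censoring times.
impute_dataset <- function(data, seed = NULL, weights = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  if (data$grid$k < 3L) stop("imputation needs k >= 3")
  if (is.null(weights)) weights <- subdist_weights(data)
  if (!is.null(seed)) set.seed(seed)
  time <- data$time
  event <- as.integer(data$status == 1L)
  draws <- sample_all_imputed(weights)
  if (length(draws)) time[as.integer(names(draws))] <- draws
  se_dataset(time, event, data$x, grid = data$grid)
}

#' Repeated single imputations
#'
#' Re-imputes the same dataset `R` times with seeds derived from a base
#' seed, as in the repeated-experiment protocol where individuals stay
#' fixed and only the imputed censoring times are redrawn. Datasets are
#' returned individually and never averaged.
#'
#' @param data A [cr_dataset].
#' @param R Number of imputations.
#' @param base_seed Integer base seed; imputation `r` uses seed
#'   `base_seed + r - 1`.
#' @return A list of `R` [se_dataset] objects.
#' @export
impute_replicates <- function(data, R = 10L, base_seed = 1L) {
  weights <- subdist_weights(data)
  lapply(seq_len(R), function(r)
    impute_dataset(data, seed = base_seed + r - 1L, weights = weights))
}

#' Treat competing events as censoring (naive baseline)
#'
#' Maps every competing event (status >= 2) to a censored record at the
#' original observed time. This baseline ignores the competing-risks
#' structure: the Kaplan-Meier complement computed from its output
#' systematically overestimates the type-1 cumulative incidence.
#'
#' @param data A [cr_dataset].
#' @return An [se_dataset]; times are identical to the input.
#' @export
naive_censor <- function(data) {
  stopifnot(inherits(data, "cr_dataset"))
  se_dataset(data$time, as.integer(data$status == 1L), data$x,
             grid = data$grid)
}
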