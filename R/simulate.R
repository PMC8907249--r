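#' Simulator configuration
#'
#' Parameters of the discrete competing-risks simulator: a two-event model
#' in which the type-1 (event of interest) times follow the continuous
#' subdistribution model
#' \deqn{F_1(t | x) = 1 - (1 - q + q e^{-t})^{\exp(x^\top \gamma_1)},}
#' type-2 times are exponential with rate \eqn{\exp(x^\top \gamma_2)},
#' event times are discretized into `k` empirical-quantile intervals, and
#' discrete censoring times are drawn from
#' \eqn{P(C = t) = b^{k+1-t} / \sum_{i=1}^k b^i}.
#'
#' @param n Sample size.
#' @param q Type-1 mixture parameter in (0, 1); at `x = 0`,
#'   \eqn{P(\epsilon = 1) = q}.
#' @param b Censoring shape (> 0): `b = 1` gives uniform censoring over
#'   `1:k`; larger `b` concentrates censoring early.
#' @param k Number of time intervals.
#' @param gamma1,gamma2 Regression coefficient vectors (length 4) of the
#'   type-1 and type-2 models.
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 30000L, q = 0.2, b = 1, k = 20L,
                       gamma1 = c(0.4, -0.4, 0.2, -0.2),
                       gamma2 = c(-0.4, 0.4, -0.2, 0.2),
                       seed = NULL) {
  stopifnot(n >= 1, q > 0, q < 1, b > 0, k >= 2,
            length(gamma1) == 4L, length(gamma2) == 4L)
  structure(list(n = as.integer(n), q = q, b = b, k = as.integer(k),
                 gamma1 = as.numeric(gamma1), gamma2 = as.numeric(gamma2),
                 seed = seed),
            class = "sim_config")
}

#' Sample the simulator's covariates
#'
#' Four independent predictors: \eqn{x_1, x_2 \sim N(0,1)} and
#' \eqn{x_3, x_4 \sim} Bernoulli(0.5).
#'
#' @param n Number of individuals.
#' @return An `n` x 4 numeric matrix with columns `x1..x4`.
#' @export
sample_covariates <- function(n) {
  x <- cbind(stats::rnorm(n), stats::rnorm(n),
             stats::rbinom(n, 1L, 0.5), stats::rbinom(n, 1L, 0.5))
  colnames(x) <- paste0("x", 1:4)
  x
}

#' Conditional probability of a type-1 event
#'
#' \eqn{P(\epsilon = 1 | x) = 1 - (1-q)^{\exp(x^\top \gamma_1)}}, the total
#' mass of the type-1 subdistribution. The complement is the type-2
#' probability.
#'
#' @param x Covariate vector or matrix (rows = individuals).
#' @param q Type-1 mixture parameter in (0, 1).
#' @param gamma1 Type-1 coefficient vector.
#' @return Probability (vector).
#' @export
type1_probability <- function(x, q, gamma1 = c(0.4, -0.4, 0.2, -0.2)) {
  stopifnot(q > 0, q < 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  1 - (1 - q)^exp(drop(x %*% gamma1))
}

#' Sample continuous type-1 event times
#'
#' Inverts the subdistribution \eqn{F_1(t|x)} conditional on
#' \eqn{\epsilon = 1}: with \eqn{\eta = \exp(x^\top \gamma_1)} and
#' \eqn{u \sim U(0, p_1)}, \eqn{p_1 = 1-(1-q)^\eta},
#' \deqn{T = -\log\{((1-u)^{1/\eta} - (1-q)) / q\} > 0.}
#'
#' @param x Covariate matrix of the individuals (one row each).
#' @param q Type-1 mixture parameter.
#' @param gamma1 Type-1 coefficient vector.
#' @return Positive continuous times, one per row of `x`.
#' @export
sample_type1_time <- function(x, q, gamma1 = c(0.4, -0.4, 0.2, -0.2)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  eta <- exp(drop(x %*% gamma1))
  p1 <- 1 - (1 - q)^eta
  u <- stats::runif(nrow(x)) * p1
  arg <- ((1 - u)^(1 / eta) - (1 - q)) / q
  # probability-zero numerical boundary: resample u
  bad <- which(arg <= 0)
  while (length(bad)) {
    u[bad] <- stats::runif(length(bad)) * p1[bad]
    arg[bad] <- ((1 - u[bad])^(1 / eta[bad]) - (1 - q)) / q
    bad <- bad[arg[bad] <= 0]
  }
  -log(arg)
}

#' Sample continuous type-2 (competing) event times
#'
#' Exponential times with covariate-dependent rate
#' \eqn{\xi_2 = \exp(x^\top \gamma_2)}.
#'
#' @param x Covariate matrix (one row per individual).
#' @param gamma2 Type-2 coefficient vector.
#' @return Positive continuous times.
#' @export
sample_type2_time <- function(x, gamma2 = c(-0.4, 0.4, -0.2, 0.2)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stats::rexp(nrow(x), rate = exp(drop(x %*% gamma2)))
}

#' Sample discrete censoring times
#'
#' Draws from \eqn{P(C = t) = b^{k+1-t} / \sum_{i=1}^k b^i} on `1:k`.
#' `b = 1` is uniform; `b > 1` front-loads censoring.
#'
#' @param n Number of draws.
#' @param b Shape parameter (> 0).
#' @param k Number of intervals.
#' @return Integer vector of censoring times in `1:k`.
#' @export
sample_censoring_time <- function(n, b, k) {
  stopifnot(b > 0, k >= 2)
  p <- b^((k + 1) - seq_len(k))
  sample.int(k, n, replace = TRUE, prob = p / sum(p))
}

#' Censoring probability mass function of the simulator
#'
#' @param b Shape parameter (> 0).
#' @param k Number of intervals.
#' @return Numeric vector of \eqn{P(C = t)} for `t = 1:k`.
#' @export
censoring_pmf <- function(b, k) {
  p <- b^((k + 1) - seq_len(k))
  p / sum(p)
}

#' Simulate a discrete competing-risks dataset
#'
#' Per individual: draw covariates, draw the event type from
#' [type1_probability()], draw the continuous event time from the matching
#' model, pool the continuous event times of both types and discretize to
#' `k` empirical-quantile intervals ([discretize_times()]), draw a discrete
#' censoring time, and set \eqn{\tilde T = \min(T, C)},
#' status \eqn{= \epsilon \cdot I(T \le C)} (ties go to the event).
#'
#' @param n,q,b,k,gamma1,gamma2,seed See [sim_config()]; alternatively pass
#'   a `sim_config` as `config`.
#' @param config Optional `sim_config` overriding the individual arguments.
#' @return A [cr_dataset] whose grid carries the quantile cut points, with
#'   attributes `eps` (latent event type), `t_cont` (latent continuous
#'   event time) and `cens` (latent censoring time) for validation use.
#' @export
#' @examples
#' d <- crsim(n = 500, q = 0.2, seed = 1)
#' table(d$status)
crsim <- function(n = 30000L, q = 0.2, b = 1, k = 20L,
                  gamma1 = c(0.4, -0.4, 0.2, -0.2),
                  gamma2 = c(-0.4, 0.4, -0.2, 0.2),
                  seed = NULL, config = NULL) {
  if (is.null(config))
    config <- sim_config(n, q, b, k, gamma1, gamma2, seed)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n; k <- config$k; q <- config$q
  x <- sample_covariates(n)
  p1 <- type1_probability(x, q, config$gamma1)
  eps <- ifelse(stats::runif(n) < p1, 1L, 2L)
  t_cont <- numeric(n)
  i1 <- eps == 1L
  if (any(i1))
    t_cont[i1] <- sample_type1_time(x[i1, , drop = FALSE], q, config$gamma1)
  if (any(!i1))
    t_cont[!i1] <- sample_type2_time(x[!i1, , drop = FALSE], config$gamma2)
  disc <- discretize_times(t_cont, k)
  cens <- sample_censoring_time(n, config$b, k)
  obs <- pmin(disc$index, cens)
  status <- ifelse(disc$index <= cens, eps, 0L)
  out <- cr_dataset(obs, status, x, grid = disc$grid, J = 2L)
  attr(out, "eps") <- eps
  attr(out, "t_cont") <- t_cont
  attr(out, "cens") <- cens
  out
}

#' True type-1 cumulative incidence on the discrete grid
#'
#' Evaluates the generating model's type-1 CIF at the upper boundaries of
#' the grid intervals: \eqn{P(T_{disc} \le t, \epsilon = 1 | x) =
#' F_1(a_t | x)} with \eqn{a_k = \infty}. Used as the oracle marker and
#' calibration truth in validation studies.
#'
#' @param x Covariate matrix.
#' @param grid A [time_grid] with cut points (as produced by [crsim()]).
#' @param q,gamma1 Generating parameters.
#' @return An `nrow(x)` x `k` matrix of CIF values.
#' @export
true_type1_cif <- function(x, grid, q, gamma1 = c(0.4, -0.4, 0.2, -0.2)) {
  stopifnot(inherits(grid, "time_grid"), !is.null(grid$cut_points))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  eta <- exp(drop(x %*% gamma1))
  a <- c(grid$cut_points, Inf)
  out <- vapply(a, function(tt) 1 - (1 - q + q * exp(-tt))^eta,
                numeric(nrow(x)))
  matrix(out, nrow = nrow(x))
}
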