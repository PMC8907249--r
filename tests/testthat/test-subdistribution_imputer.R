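test_that("weights are all ones when there is no censoring", {
  d <- cr_dataset(c(1, 2, 3, 4), c(1, 2, 1, 2), matrix(0, 4, 1), k = 5)
  sw <- subdist_weights(d)
  expect_true(all(sw$W == 1))
})

test_that("weights and sampling pmf match the hand computation", {
  # G(1) = 3/4, G(2) = 1/2; individual with T = 2, status 2, k = 4:
  # w_{i,3} = G(2)/G(1) = 2/3, and the censoring-time distribution is
  # P(C_hat = 2) = w2 - w3 = 1/3, P(C_hat = 3) = w3 = 2/3 (residual).
  G <- manual_G(c(1, 3 / 4, 1 / 2, 1 / 2))
  d <- cr_dataset(time = c(2, 1, 4, 3), status = c(2, 0, 1, 0),
                  x = matrix(0, 4, 1), k = 4)
  sw <- subdist_weights(d, censoring = G)
  expect_equal(sw$W[1, ], c(1, 1, 2 / 3))
  pm <- sw$pmf[[2]]
  expect_equal(pm$support, c(2L, 3L))
  expect_equal(pm$prob, c(1 / 3, 2 / 3))
  expect_equal(sum(pm$prob), 1)
})

test_that("weight invariants hold on simulated data", {
  d <- crsim(n = 2000, q = 0.4, seed = 5)
  sw <- subdist_weights(d)
  expect_true(all(sw$W >= 0 & sw$W <= 1))
  expect_true(all(apply(sw$W, 1, function(w) all(diff(w) <= 1e-12))))
  # w_it = 1 for t <= T (check a sample of competing individuals)
  comp <- which(d$status == 2L)[1:50]
  for (i in comp)
    expect_true(all(sw$W[i, seq_len(min(d$time[i], d$grid$k - 1L))] == 1))
  # every stored pmf is a proper distribution
  for (pm in Filter(Negate(is.null), sw$pmf)) {
    expect_true(all(pm$prob >= -1e-12))
    expect_equal(sum(pm$prob), 1)
  }
})

test_that("degenerate weights are reported when G hits zero", {
  # a censoring model with no survivors past t = 1 cannot supply weights
  # for a competing event observed at 2 (G(T - 1) = 0); unreachable from
  # the package's own life table, but user-supplied estimates may do this
  G <- manual_G(c(1, 0, 0, 0))
  d <- cr_dataset(time = c(2, 1, 4, 3), status = c(2, 0, 1, 0),
                  x = matrix(0, 4, 1), k = 4)
  expect_error(subdist_weights(d, censoring = G), "degenerate")
})

test_that("a degenerate pmf yields a deterministic draw", {
  G <- manual_G(c(1, 1, 0, 0))  # all censoring mass in interval 2
  d <- cr_dataset(time = c(2, 1, 4, 3), status = c(2, 0, 1, 0),
                  x = matrix(0, 4, 1), k = 4)
  sw <- subdist_weights(d, censoring = G)
  pm <- sw$pmf[[2]]
  expect_equal(pm$prob[pm$support == 2L], 1)
  draws <- replicate(20, sample_imputed_censoring(sw, 1L)$time)
  expect_true(all(draws == 2L))
})

test_that("sampling frequencies follow the stored pmf", {
  G <- manual_G(c(1, 0.8, 0.5, 0.3, 0.2, 0.2))  # k = 6
  d <- cr_dataset(time = c(1, 2, 3, 4), status = c(2, 0, 1, 0),
                  x = matrix(0, 4, 1), k = 6)
  sw <- subdist_weights(d, censoring = G)
  pm <- sw$pmf[[1]]
  expect_equal(length(pm$support), 5L)
  set.seed(42)
  n_draw <- 5000
  draws <- replicate(n_draw, sample_imputed_censoring(sw, 1L)$time)
  freq <- tabulate(draws, 6)[pm$support] / n_draw
  tol <- 3 * sqrt(pm$prob * (1 - pm$prob) / n_draw)
  expect_true(all(abs(freq - pm$prob) <= tol))
})

test_that("sampling rejects non-competing individuals", {
  d <- crsim(n = 200, q = 0.4, seed = 2)
  sw <- subdist_weights(d)
  i0 <- which(d$status == 0L)[1]
  expect_error(sample_imputed_censoring(sw, i0), "status")
})

test_that("imputation passes through data without competing events", {
  d <- cr_dataset(c(1, 2, 3, 4), c(0, 1, 0, 1), matrix(0, 4, 1), k = 5)
  se <- impute_dataset(d, seed = 1)
  expect_equal(se$time, d$time)
  expect_equal(se$event, as.integer(d$status == 1L))
})

test_that("imputation modifies exactly the competing-event records", {
  # eight individuals, two of whom experienced the competing event first
  d <- cr_dataset(time = c(2, 1, 3, 5, 3, 4, 2, 5),
                  status = c(2, 0, 1, 0, 2, 1, 0, 1),
                  x = matrix(stats::rnorm(8), 8, 1), k = 6)
  se <- impute_dataset(d, seed = 99)
  comp <- which(d$status == 2L)
  expect_length(comp, 2L)
  expect_true(all(se$event[comp] == 0L))
  expect_true(all(se$time[comp] >= d$time[comp]))
  expect_true(all(se$time[comp] <= d$grid$k - 1L))
  keep <- setdiff(seq_len(8), comp)
  expect_equal(se$time[keep], d$time[keep])
  expect_equal(se$event[keep], as.integer(d$status[keep] == 1L))
  expect_equal(se$x, d$x)
})

test_that("imputation is reproducible and varies only in imputed times", {
  d <- crsim(n = 1000, q = 0.3, seed = 21)
  a <- impute_dataset(d, seed = 7)
  b <- impute_dataset(d, seed = 7)
  expect_identical(a$time, b$time)
  expect_identical(a$event, b$event)
  c2 <- impute_dataset(d, seed = 8)
  expect_identical(a$event, c2$event)
  diff_rows <- which(a$time != c2$time)
  expect_true(all(d$status[diff_rows] >= 2L))
  expect_gt(length(diff_rows), 0L)
})

test_that("competing events at the grid end are censored at k - 1", {
  d <- cr_dataset(time = c(5, 4, 1, 2), status = c(2, 2, 0, 1),
                  x = matrix(0, 4, 1), k = 5)
  se <- impute_dataset(d, seed = 3)
  expect_equal(se$time[1:2], c(4L, 4L))
})

test_that("repeated imputations share structure but differ in draws", {
  d <- crsim(n = 500, q = 0.3, seed = 13)
  reps <- impute_replicates(d, R = 3, base_seed = 100)
  expect_length(reps, 3L)
  for (r in reps) expect_identical(r$event, reps[[1]]$event)
  expect_false(identical(reps[[1]]$time, reps[[2]]$time))
})

test_that("naive censoring keeps times and relabels competing events", {
  d <- crsim(n = 400, q = 0.3, seed = 31)
  se <- naive_censor(d)
  expect_identical(se$time, d$time)
  expect_equal(se$event, as.integer(d$status == 1L))
  # bookkeeping: censored rows = original censored + competing
  expect_equal(sum(se$event == 0L),
               sum(d$status == 0L) + sum(d$status >= 2L))
})
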