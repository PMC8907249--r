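test_that("covariate-free fit recovers the empirical hazard", {
  set.seed(1)
  n <- 400
  event <- stats::rbinom(n, 1, 0.3)
  time <- ifelse(event == 1L, 1L, sample(1:2, n, replace = TRUE))
  tr <- se_dataset(time, event, matrix(0, n, 1), grid = time_grid(2))
  fit <- fit_hazard(tr, alpha = 0, lr = 0.05, epochs = 2000, patience = 200)
  h <- predict_hazard(fit, matrix(0, 1, 1))
  # MLE of the first-interval hazard is the fraction of events at t = 1
  expect_lt(abs(h[1] - mean(event)), 0.01)
})

test_that("alpha = 0 reproduces the person-period glm fit", {
  set.seed(2)
  d <- crsim(n = 3000, q = 0.3, k = 5, seed = 6)
  tr <- impute_dataset(d, seed = 3)
  fit <- fit_hazard(tr, alpha = 0, lr = 0.05, epochs = 3000, patience = 300)
  # independent route: logistic regression on the person-period expansion
  id <- rep(seq_along(tr$time), tr$time)
  s <- unlist(lapply(tr$time, seq_len))
  y <- as.integer(s == tr$time[id] & tr$event[id] == 1L)
  dfl <- data.frame(y = y, s = factor(s), tr$x[id, , drop = FALSE])
  gfit <- stats::glm(y ~ s + x1 + x2 + x3 + x4, stats::binomial(), dfl)
  beta_glm <- stats::coef(gfit)[c("x1", "x2", "x3", "x4")]
  beta_fit <- fit$par$beta / fit$scale
  expect_true(all(abs(beta_fit - beta_glm) < 0.05))
  # predicted hazards agree too
  h_fit <- predict_hazard(fit, tr$x[1:20, ])
  eta <- stats::predict(gfit,
                        newdata = data.frame(s = factor(rep(1:5, each = 20),
                                                        levels = 1:5),
                                             tr$x[rep(1:20, 5), ]))
  h_glm <- matrix(stats::plogis(eta), 20, 5)
  expect_lt(max(abs(h_fit - h_glm)), 0.01)
})

test_that("coefficients of a known logistic hazard are recovered", {
  set.seed(3)
  n <- 8000
  k <- 6
  a <- c(-2.5, -2, -2, -1.5, -1.5, -1)
  X <- cbind(stats::rnorm(n), stats::rbinom(n, 1, 0.5))
  beta <- c(0.5, -0.7)
  eta <- drop(X %*% beta)
  U <- matrix(stats::runif(n * k), n, k)
  H <- stats::plogis(outer(eta, a, "+"))
  first <- apply(U < H, 1, function(z) if (any(z)) which.max(z) else NA_integer_)
  time <- ifelse(is.na(first), k, first)
  event <- as.integer(!is.na(first))
  cens <- sample.int(k, n, replace = TRUE)
  obs <- pmin(time, cens)
  ev <- as.integer(event == 1L & time <= cens)
  tr <- se_dataset(obs, ev, X, grid = time_grid(k))
  fit <- fit_hazard(tr, alpha = 0, lr = 0.05, epochs = 3000, patience = 300)
  beta_hat <- fit$par$beta / fit$scale
  # standard errors from the person-period expansion
  id <- rep(seq_len(n), obs)
  s <- unlist(lapply(obs, seq_len))
  y <- as.integer(s == obs[id] & ev[id] == 1L)
  gfit <- stats::glm(y ~ factor(s) + x1 + x2, stats::binomial(),
                     data.frame(y = y, s = s, x1 = X[id, 1], x2 = X[id, 2]))
  se <- summary(gfit)$coefficients[c("x1", "x2"), "Std. Error"]
  expect_true(all(abs(beta_hat - beta) < 3 * se))
})

test_that("two-term objective reduces to the likelihood at alpha = 0", {
  d <- crsim(n = 800, q = 0.3, k = 5, seed = 9)
  tr <- impute_dataset(d, seed = 1)
  f0 <- fit_hazard(tr, alpha = 0, epochs = 40, patience = 40, seed = 5)
  f0b <- fit_hazard(tr, alpha = 0, epochs = 40, patience = 40, seed = 5)
  expect_identical(f0$par, f0b$par)
  # alpha > 0 changes the optimum (uncensored records are upweighted)
  f1 <- fit_hazard(tr, alpha = 0.5, epochs = 40, patience = 40, seed = 5)
  expect_false(identical(f0$par$a, f1$par$a))
})

test_that("predicted CIF sums interval probabilities correctly", {
  # hand-built model: h = (0.1, 2/9, 1/14) gives P(T=1..3) = (0.1, 0.2, 0.05)
  mdl <- structure(list(par = list(a = stats::qlogis(c(0.1, 2 / 9, 1 / 14)),
                                   beta = 0),
                        k = 3L, p = 1L, alpha = 0, hidden = 0L,
                        center = 0, scale = 1),
                   class = "discrete_hazard")
  x <- matrix(0, 1, 1)
  expect_equal(predict_cif(mdl, x, t = 2), 0.3, tolerance = 1e-12)
  cif <- predict_cif(mdl, x)
  # summation form equals product form
  h <- c(0.1, 2 / 9, 1 / 14)
  pmf <- h * cumprod(c(1, 1 - h[-3]))
  expect_equal(drop(cif), cumsum(pmf), tolerance = 1e-12)
  expect_error(predict_cif(mdl, x, t = 4), "1..k")
})

test_that("predicted CIF is monotone and hazards stay in (0,1)", {
  d <- crsim(n = 1500, q = 0.3, seed = 33)
  sp <- stratified_split(d, seed = 1)
  fit <- fit_hazard(impute_dataset(sp$train, seed = 2),
                    impute_dataset(sp$validation, seed = 3),
                    epochs = 120, patience = 20, seed = 4)
  H <- predict_hazard(fit, sp$test$x)
  expect_true(all(H > 0 & H < 1))
  cif <- predict_cif(fit, sp$test$x)
  expect_true(all(apply(cif, 1, function(z) all(diff(z) >= -1e-12))))
  expect_true(all(cif >= 0 & cif <= 1))
})

test_that("the hidden-layer variant trains and predicts", {
  d <- crsim(n = 1500, q = 0.3, seed = 44)
  sp <- stratified_split(d, seed = 1)
  fit <- fit_hazard(impute_dataset(sp$train, seed = 2),
                    impute_dataset(sp$validation, seed = 3),
                    hidden = 4, epochs = 80, patience = 15, seed = 4)
  expect_equal(fit$hidden, 4L)
  cif <- predict_cif(fit, sp$test$x)
  expect_true(all(cif >= 0 & cif <= 1))
  expect_true(all(apply(cif, 1, function(z) all(diff(z) >= -1e-12))))
})
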