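test_that("BCF recovers a null effect under targeted selection", {
  set.seed(12)
  res <- run_estimator_battery(
    synthetic_config(delta = c(0, 0, 0, 0), het_strength = 0, lambda = 1),
    seed = 301, estimators = "bcf")
  expect_lt(abs(res$bcf), 0.2)  # single replicate, loose bound
})

test_that("BCF beats the naive contrast under strong selection", {
  cfg <- synthetic_config(delta = c(0.5, 0.25, 0.12, 0.05),
                          het_strength = 0, lambda = 3)
  res <- lapply(302:304, function(s)
    run_estimator_battery(cfg, s, estimators = "bcf"))
  d <- vapply(res, `[[`, numeric(1), "bcf")
  err <- vapply(res, function(r) r$bcf - r$d_true_all, numeric(1))
  err_naive <- vapply(res, function(r) r$naive - r$d_true_all, numeric(1))
  expect_gt(mean(d), 0.3)
  expect_lt(mean(d), 0.7)
  expect_lt(abs(mean(err)), abs(mean(err_naive)))
})

test_that("under randomization BCF matches the difference in means", {
  set.seed(14)
  n <- 600
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  g = factor(sample(letters[1:3], n, TRUE)))
  z <- rbinom(n, 1, 0.5)
  y <- sin(X$x1) + 0.5 * (X$g == "a") + 0.6 * z + rnorm(n, 0, 0.8)
  fit <- fit_bcf(X, z, rep(0.5, n), y, fast_bcf())
  dim_est <- mean(y[z == 1]) - mean(y[z == 0])
  dim_se <- sqrt(var(y[z == 1]) / sum(z) + var(y[z == 0]) / sum(1 - z))
  expect_lt(abs(mean(fit$att_draws) - dim_est), 2.5 * dim_se)
})

test_that("tau draws are consistent with the posterior ATT", {
  set.seed(15)
  n <- 120
  X <- data.frame(x1 = rnorm(n))
  z <- rbinom(n, 1, 0.5)
  y <- X$x1 + 0.5 * z + rnorm(n, 0, 0.5)
  fit <- fit_bcf(X, z, rep(0.5, n), y, fast_bcf())
  tr <- which(z == 1)
  expect_equal(mean(bcf_tau_draws(fit, tr)), mean(fit$att_draws))
  # a repeated row yields identical columns
  dd <- bcf_tau_draws(fit, c(tr[1], tr[1]))
  expect_identical(dd[, 1], dd[, 2])
  expect_error(bcf_tau_draws(fit, n + 5), "unknown row")
  # degenerate group sizes are refused
  expect_error(fit_bcf(X, rep(1L, n), rep(0.5, n), y, fast_bcf()),
               "fewer than 10")
  expect_error(fit_bcf(X, z, rep(1.2, n), y, fast_bcf()), "pihat")
})

test_that("a hand-built single-stump moderating forest evaluates to its leaf", {
  fake <- structure(list(tau_draws = matrix(0.7, nrow = 5, ncol = 4),
                         n = 4), class = "cp_bcf")
  expect_true(all(bcf_tau_draws(fake, 1:4) == 0.7))
})

test_that("BCF is deterministic under a fixed seed", {
  set.seed(16)
  n <- 150
  X <- data.frame(x1 = rnorm(n))
  z <- rbinom(n, 1, 0.4)
  y <- X$x1 + 0.3 * z + rnorm(n, 0, 0.5)
  set.seed(99); f1 <- fit_bcf(X, z, rep(0.4, n), y, fast_bcf())
  set.seed(99); f2 <- fit_bcf(X, z, rep(0.4, n), y, fast_bcf())
  expect_identical(f1$tau_draws, f2$tau_draws)
  expect_identical(f1$sigma, f2$sigma)
  expect_gt(f1$accept_rate, 0)
  expect_lt(f1$accept_rate, 1)
})
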