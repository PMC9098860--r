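test_that("degenerate fits collapse to the sample mean", {
  set.seed(1)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  # constant outcome: conjugacy collapses to the grand mean
  fit <- fit_bart(X, rep(3, 40), fast_bart(), keep_forest = FALSE)
  expect_lt(max(abs(fit$yhat_train - 3)), 1e-6 * 3 + 1e-6)
  # a single tree with splits forbidden (alpha ~ 0) is a stump
  y <- rnorm(40)
  p <- bart_params(n_trees = 1, alpha = 1e-9, n_burn = 100, n_keep = 100)
  fit1 <- fit_bart(X, y, p, keep_forest = FALSE)
  expect_lt(max(abs(fit1$yhat_train - mean(y))), 0.05 * sd(y))
})

test_that("regression accuracy is competitive with a reference ensemble", {
  set.seed(4)
  n <- 500; p <- 6
  X <- as.data.frame(matrix(runif(n * p), n, p))
  names(X) <- paste0("x", 1:p)
  f <- function(d) 10 * sin(pi * d$x1 * d$x2) + 20 * (d$x3 - 0.5)^2 +
    10 * d$x4 + 5 * d$x5
  y <- f(X) + rnorm(n)
  Xh <- as.data.frame(matrix(runif(200 * p), 200, p))
  names(Xh) <- names(X)
  yh <- f(Xh) + rnorm(200)
  fit <- fit_bart(X, y, calib_bart())
  pred <- predict(fit, Xh)$mean
  rmse_bart <- sqrt(mean((pred - yh)^2))
  # independent oracle: off-the-shelf gradient-boosted trees
  ref <- xgboost::xgboost(as.matrix(X), y, nrounds = 200, max_depth = 3,
                          learning_rate = 0.1, verbosity = 0,
                          nthreads = 1)
  rmse_ref <- sqrt(mean((predict(ref, as.matrix(Xh)) - yh)^2))
  expect_lt(rmse_bart, 1.25 * rmse_ref)
  # MH acceptance rate strictly inside (0, 1) on non-degenerate data
  expect_gt(fit$accept_rate, 0)
  expect_lt(fit$accept_rate, 1)
})

test_that("posterior predictions are consistent and deterministic", {
  set.seed(5)
  X <- data.frame(x1 = rnorm(80), g = factor(sample(c("a", "b", "Miss"),
                                                    80, TRUE)))
  y <- X$x1 + (X$g == "a") + rnorm(80, 0, 0.3)
  fit <- fit_bart(X, y, fast_bart())
  pr <- predict(fit, X)
  expect_equal(pr$mean, fit$yhat_train, tolerance = 1e-10)
  # duplicated row gives identical predictions
  two <- X[c(7, 7), ]
  pd <- predict(fit, two)
  expect_identical(pd$mean[1], pd$mean[2])
  # same seed, same posterior, bit for bit
  set.seed(9); f1 <- fit_bart(X, y, fast_bart(), keep_forest = FALSE)
  set.seed(9); f2 <- fit_bart(X, y, fast_bart(), keep_forest = FALSE)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(f1$fit_draws, f2$fit_draws)
})

test_that("a hand-built forest is evaluated exactly", {
  X <- data.frame(x1 = c(-1, 1))
  des <- cpcausal:::build_design(X)
  # one tree: split on x1 at 0, leaves 1 (left) and 3 (right)
  forest <- matrix(c(1, 1, 0, 2, 3, 0,
                     1, 0, 0, 0, 0, 1,
                     1, 0, 0, 0, 0, 3), nrow = 3, byrow = TRUE)
  fake <- structure(list(forests = list(forest), center = -0.5, scale = 1,
                         probit = FALSE, schema = des$schema),
                    class = "cp_bart")
  pr <- predict(fake, X)
  expect_equal(unname(pr$mean), c(1, 3))
})

test_that("probit BART recovers prevalence and separates a signal", {
  set.seed(6)
  n <- 1500
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  z <- rbinom(n, 1, 0.3)  # independent of X
  fit <- fit_bart_probit(X, z, calib_bart(), keep_forest = FALSE)
  expect_lt(abs(mean(fit$yhat_train) - 0.3), 0.05)
  expect_lt(sd(fit$yhat_train), 0.05)  # no spurious signal

  # perfectly separated toy: strong held-out discrimination
  n2 <- 200
  X2 <- data.frame(x1 = rnorm(n2))
  z2 <- as.integer(X2$x1 > 0)
  hold <- seq(1, n2, by = 4)
  f2 <- fit_bart_probit(X2[-hold, , drop = FALSE], z2[-hold],
                        fast_bart(), X_test = X2[hold, , drop = FALSE],
                        keep_forest = FALSE)
  auc <- evaluate_propensity(f2$yhat_test, z2[hold])["auc"]
  expect_gte(unname(auc), 0.95)

  expect_error(fit_bart_probit(X2, rep(1, n2)), "degenerate")
})

test_that("probit predictions respect label symmetry", {
  set.seed(7)
  n <- 400
  X <- data.frame(x1 = rnorm(n))
  z <- rbinom(n, 1, plogis(1.5 * X$x1))
  p1 <- fit_bart_probit(X, z, calib_bart(), keep_forest = FALSE)$yhat_train
  p2 <- fit_bart_probit(X, 1L - z, calib_bart(),
                        keep_forest = FALSE)$yhat_train
  expect_lt(mean(abs(p1 - (1 - p2))), 0.06)
})

test_that("sigma posterior concentrates on the truth as n grows", {
  gen <- function(n, seed) {
    set.seed(seed)
    X <- data.frame(x1 = runif(n, -2, 2))
    list(X = X, y = X$x1 + rnorm(n))  # noise SD 1
  }
  small <- gen(200, 8); big <- gen(2000, 8)
  s_small <- mean(fit_bart(small$X, small$y, fast_bart(),
                           keep_forest = FALSE)$sigma)
  s_big <- mean(fit_bart(big$X, big$y, fast_bart(),
                         keep_forest = FALSE)$sigma)
  expect_lt(abs(s_big - 1), 0.1)
  expect_lte(abs(s_big - 1), abs(s_small - 1) + 0.03)
})

test_that("propensity metrics match exhaustive pair counting", {
  expect_equal(unname(evaluate_propensity(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               c(1, 1, 1, 1))
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  z <- c(1, 1, 0, 1, 0, 0)
  # oracle: count concordant positive-negative pairs explicitly
  pos <- scores[z == 1]; neg <- scores[z == 0]
  conc <- 0
  for (a in pos) for (b in neg) conc <- conc + (a > b) + 0.5 * (a == b)
  expect_equal(conc / (length(pos) * length(neg)), 8 / 9)
  expect_equal(unname(evaluate_propensity(scores, z)["auc"]), 8 / 9)
  # uninformative scores: AUC near 1/2
  set.seed(10)
  zz <- rbinom(4000, 1, 0.4)
  ss <- runif(4000)
  expect_lt(abs(evaluate_propensity(ss, zz)["auc"] - 0.5), 0.03)
  expect_error(evaluate_propensity(c(0.1, 0.2), c(1, 1)), "single class")
})
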