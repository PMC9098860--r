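test_that("null and homogeneous effect profiles give exact truths", {
  # tau identically zero => realized ATT is zero at every level
  cfg0 <- synthetic_config(n_subjects = 80, delta = c(0, 0, 0, 0),
                           het_strength = 0, seed = 3)
  g0 <- generate_cohort(cfg0)
  expect_equal(unname(g0$truth$att), rep(0, 4))

  # homogeneous delta: ATT = delta * change-SD exactly (mean of constant)
  cfg1 <- synthetic_config(n_subjects = 80, delta = c(0.5, 0.2, 0.1, 0.05),
                           het_strength = 0, seed = 3)
  g1 <- generate_cohort(cfg1)
  expect_equal(unname(g1$truth$att),
               c(0.5, 0.2, 0.1, 0.05) * change_sd_true(cfg1))
})

test_that("truth ATT is the mean of individual effects over treated limbs", {
  cfg <- synthetic_config(n_subjects = 500, het_strength = 1, lambda = 2,
                          seed = 1)
  g <- generate_cohort(cfg)
  z <- g$truth$z_index
  expect_equal(unname(g$truth$att),
               unname(colMeans(g$truth$tau[z == 1, ])))
  # the estimand is stable: an independent re-simulation at 4x the size
  # gives an ATT within Monte-Carlo error
  cfg2 <- cfg; cfg2$n_subjects <- 2000L; cfg2$seed <- 77L
  g2 <- generate_cohort(cfg2)
  se <- stats::sd(g$truth$tau[z == 1, 1]) / sqrt(sum(z))
  expect_lt(abs(g$truth$att[1] - g2$truth$att[1]), 4 * se)
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- synthetic_config(n_subjects = 60, seed = 42)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$tau, g2$truth$tau)
  m1 <- inject_missingness(g1$cohort, cfg)
  m2 <- inject_missingness(g2$cohort, cfg)
  expect_identical(m1, m2)
})

test_that("targeted selection correlates assignment with benefit", {
  base <- synthetic_config(n_subjects = 2000, het_strength = 1, seed = 5)
  g_pos <- generate_cohort(base)
  cfg0 <- base; cfg0$lambda <- 0
  g_null <- generate_cohort(cfg0)
  r_pos <- cor(g_pos$truth$pi_x, g_pos$truth$tau[, 1])
  r_null <- cor(g_null$truth$pi_x, g_null$truth$tau[, 1])
  expect_gt(r_pos, r_null)
  expect_gt(r_pos, 0.2)
})

test_that("effects attenuate along the causal chain", {
  cfg <- synthetic_config(n_subjects = 300, seed = 7)  # default delta
  g <- generate_cohort(cfg)
  att <- unname(g$truth$att) / change_sd_true(cfg)
  expect_true(all(diff(att) <= 0))
  expect_lte(g$truth$att[4], g$truth$att[1])
})

test_that("missingness injection follows the configured rates", {
  cfg <- synthetic_config(n_subjects = 100, seed = 9)
  g <- generate_cohort(cfg)

  # all-zero rates are a no-op
  cfg0 <- cfg
  cfg0$missingness <- list(gmfcs = 0, motor_control = 0, spasticity = 0,
                           strength = 0, ank_dors = 0, faq_item = 0,
                           faq_block = 0, severity_dependent = FALSE)
  expect_identical(inject_missingness(g$cohort, cfg0), g$cohort)

  # rate 1 blanks the whole column, leaving the rest untouched
  cfg1 <- cfg0
  cfg1$missingness$gmfcs <- 1
  m <- inject_missingness(g$cohort, cfg1)
  expect_true(all(is.na(m$gmfcs)))
  expect_identical(m$ank_dors, g$cohort$ank_dors)
  expect_identical(m$motor_control, g$cohort$motor_control)

  # binomial oracle: blanked fraction within 3 SE of the rate
  cfgb <- synthetic_config(n_subjects = 5000, seed = 10)
  cfgb$missingness <- list(gmfcs = 0.2, severity_dependent = FALSE)
  gb <- generate_cohort(cfgb)
  mb <- inject_missingness(gb$cohort, cfgb)
  n <- nrow(mb)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(is.na(mb$gmfcs)) - 0.2), 3 * se)

  # out-of-range rate is rejected
  cfge <- cfg
  cfge$missingness$gmfcs <- 1.2
  expect_error(inject_missingness(g$cohort, cfge), "rates")
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 0), "positive")
  expect_error(synthetic_config(delta = c(0.4, 0.2)), "length 4")
  expect_error(synthetic_config(noise_sd = c(1, 1, -1, 1)))
})
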