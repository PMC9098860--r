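test_that("direct-matching ATT is the mean pair difference", {
  coh <- toy_cohort(changes_t = c(5, 7), changes_c = c(3, 3))
  pairs <- data.frame(treated_id = c("L1", "L2"),
                      control_id = c("L3", "L4"))
  e <- dm_att(pairs, coh, "body_structures", n_boot = 200)
  expect_equal(e$effect, 3)  # pair effects 2 and 4
  expect_equal(e$model, "DM")
  expect_equal(e$sample, "matched")

  # equal changes in both arms: exact zero
  coh0 <- toy_cohort(c(2, 4), c(2, 4))
  e0 <- dm_att(data.frame(treated_id = c("L1", "L2"),
                          control_id = c("L3", "L4")),
               coh0, "body_structures", n_boot = 200)
  expect_equal(e0$effect, 0)
  expect_error(dm_att(data.frame()[0, ], coh, "body_structures"), "empty")
})

test_that("Cohen's d divides by the change SD of the analysis sample", {
  coh <- toy_cohort(c(0, 10), c(20, 10))  # changes 0,10,20,10: sd known
  s <- sd(c(0, 10, 20, 10))
  expect_equal(cohens_d(5, coh, "body_structures"), 5 / s)
  expect_equal(cohens_d(0, coh, "body_structures"), 0)
  # exact textbook case: effect 5 over change-SD 10
  coh2 <- toy_cohort(c(0, 10), c(20, 30))  # sd(c(0,10,20,30)) != 10
  coh3 <- toy_cohort(c(0, 10, 20), numeric(0))  # sd = 10 exactly
  expect_equal(cohens_d(5, coh3, "body_structures"), 0.5)
  con <- toy_cohort(c(1, 1), c(1, 1))
  expect_error(cohens_d(5, con, "body_structures"), "zero change SD")
})

test_that("bootstrap intervals behave on degenerate and analytic cases", {
  # all effects identical: zero-width interval at the value
  b <- bootstrap_att(rep(4, 30), n_boot = 500, seed = 1)
  expect_equal(unname(b), c(4, 4, 4))
  # analytic oracle: half-width ~ 1.96/sqrt(n) for unit-variance effects
  set.seed(2)
  e <- rnorm(400)
  b2 <- bootstrap_att(e, n_boot = 2000, seed = 3)
  half <- (b2["ci_hi"] - b2["ci_lo"]) / 2
  expect_lt(abs(half - 1.96 / 20), 0.2 * 1.96 / 20)
  # determinism under an explicit seed
  b3 <- bootstrap_att(e, n_boot = 500, seed = 7)
  b4 <- bootstrap_att(e, n_boot = 500, seed = 7)
  expect_identical(b3, b4)
  expect_warning(bootstrap_att(e, n_boot = 50), "unstable")
  # constant posterior-draw matrix collapses the same way
  b5 <- bootstrap_att(rep(2, 10), n_boot = 200, seed = 1,
                      draws = matrix(2, 50, 10))
  expect_equal(unname(b5), c(2, 2, 2))
  expect_error(bootstrap_att(3), "at least 2")
})

test_that("virtual twins match the randomized difference in means", {
  # homogeneous additive effect under randomization
  cfg <- synthetic_config(n_subjects = 250, delta = c(0.5, 0.2, 0.1, 0),
                          het_strength = 0, lambda = 0, seed = 41)
  g <- generate_cohort(cfg)
  coh <- prep_cohort(g$cohort)
  trt <- attr(coh, "index_treatment")
  e <- vt_att(coh, trt, "body_structures", "all", params = fast_bart(),
              n_boot = 300)
  csd <- change_sd(coh, "body_structures")
  d_true <- g$truth$att[1] / csd
  # randomization leaves severity-driven selection only; wide MC bound
  expect_lt(abs(e$d - d_true), 0.2)
  expect_equal(e$n_treated, sum(coh[[paste0("ivl_", trt)]]))
})

test_that("matched and all-treated samples agree for homogeneous effects", {
  cfg <- synthetic_config(n_subjects = 250, delta = c(0.5, 0.2, 0.1, 0),
                          het_strength = 0, lambda = 1, seed = 43)
  g <- generate_cohort(cfg)
  coh <- prep_cohort(g$cohort)
  trt <- attr(coh, "index_treatment")
  z <- coh[[paste0("ivl_", trt)]]
  spec <- match_spec(default_distance_covs)
  mr <- direct_match(coh, z, spec, index_treatment = trt)
  pi0 <- rep(mean(z), nrow(coh))
  em <- bcf_att(coh, trt, "body_structures", "matched", pi0,
                pairs = mr$pairs, params = fast_bcf(), n_boot = 300)
  ea <- bcf_att(coh, trt, "body_structures", "all", pi0,
                params = fast_bcf(), n_boot = 300)
  half <- (ea$ci["hi"] - ea$ci["lo"]) / 2
  expect_lt(abs(em$d - ea$d), unname(half))
})
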