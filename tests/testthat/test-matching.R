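test_that("rank distance behaves on hand-checkable cases", {
  t1 <- data.frame(a = 1, b = 2)
  c1 <- data.frame(a = c(1, 5), b = c(2, 9))
  D <- mahalanobis_rank_distance(t1, c1, c("a", "b"))
  expect_equal(unname(D[1, 1]), 0)    # identical rows are distance zero
  expect_gt(D[1, 2], 0)

  # monotone in rank gap for a single covariate
  t2 <- data.frame(a = 1)
  c2 <- data.frame(a = c(2, 3))
  D2 <- mahalanobis_rank_distance(t2, c2, "a")
  expect_lt(D2[1, 1], D2[1, 2])

  # constant covariate is dropped with a warning
  t3 <- data.frame(a = c(1, 2), k = 1)
  c3 <- data.frame(a = c(3, 4), k = 1)
  expect_warning(D3 <- mahalanobis_rank_distance(t3, c3, c("a", "k")),
                 "constant")
  expect_equal(dim(D3), c(2, 2))
})

test_that("rank distance equals an independent hand computation", {
  # 2 covariates, 5 pooled rows: oracle does its own ranks and covariance
  tr <- data.frame(u = c(3, 1), v = c(10, 40))
  co <- data.frame(u = c(2, 5, 4), v = c(30, 20, 50))
  D <- mahalanobis_rank_distance(tr, co, c("u", "v"))
  ranks_u <- rank(c(tr$u, co$u))
  ranks_v <- rank(c(tr$v, co$v))
  R <- cbind(ranks_u, ranks_v)
  S <- stats::cov(R)
  Si <- solve(S)
  oracle <- matrix(0, 2, 3)
  for (i in 1:2) for (j in 1:3) {
    dv <- R[i, ] - R[2 + j, ]
    oracle[i, j] <- sqrt(drop(t(dv) %*% Si %*% dv))
  }
  expect_equal(unname(D), oracle, tolerance = 1e-12)
})

test_that("trivial matching instances solve as expected", {
  sp <- match_spec("x", subset_weight = 1)
  one <- matrix(0, 1, 1, dimnames = list("t1", "c1"))
  res <- solve_match(one, sp)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$objective, 0)
  expect_equal(res$status, "optimal")

  # subset weight zero: the empty matching is already optimal
  sp0 <- match_spec("x", subset_weight = 0)
  D <- matrix(c(1, 2, 3, 4), 2, 2)
  res0 <- solve_match(D, sp0)
  expect_equal(res0$objective, 0)
})

test_that("solver equals exhaustive enumeration on a printed toy", {
  D <- matrix(c(1, 4, 7, 9,
                6, 2, 8, 3,
                5, 9, 1, 2), nrow = 3, byrow = TRUE)
  sp <- match_spec("x", subset_weight = 3)
  res <- solve_match(D, sp)
  oracle <- enumerate_match_optimum(D, 3)
  expect_equal(res$objective, oracle)
  expect_equal(res$status, "optimal")
})

test_that("adding a perfect control never increases the objective", {
  set.seed(31)
  D <- matrix(runif(5 * 4, 1, 10), 5, 4)
  sp <- match_spec("x", subset_weight = 2)
  before <- solve_match(D, sp)$objective
  D2 <- cbind(D, c(10, 10, 10, 10, 0))  # exact duplicate of treated 5
  after <- solve_match(D2, sp)$objective
  expect_lte(after, before)
})

test_that("match quality summarizes SMD reduction on a synthetic cohort", {
  cfg <- synthetic_config(n_subjects = 150, seed = 33)
  g <- generate_cohort(cfg)
  coh <- prep_cohort(inject_missingness(g$cohort, cfg))
  trt <- attr(coh, "index_treatment")
  z <- coh[[paste0("ivl_", trt)]]
  spec <- match_spec(default_distance_covs,
                     near_fine = setdiff(
                       c(grep("^prior_", names(coh), value = TRUE),
                         grep("^ivl_", names(coh), value = TRUE)),
                       paste0("ivl_", trt)))
  res <- direct_match(coh, z, spec, index_treatment = trt)
  q <- match_quality(res)
  expect_lt(q$mean_smd_matched, q$mean_smd_raw)
  expect_gt(q$matched_pct, 30)
  # empty matching errors out
  res0 <- res; res0$pairs <- res$pairs[0, ]
  expect_error(match_quality(res0), "empty")
})

test_that("duplicated-control fixture gives perfect quality", {
  cfg <- synthetic_config(n_subjects = 30, seed = 35)
  coh <- generate_cohort(cfg)$cohort
  nt <- 25
  treated <- coh[1:nt, ]
  dup <- treated
  dup$limb_id <- paste0("dup_", dup$limb_id)
  both <- rbind(treated, dup)
  attr(both, "treatments") <- attr(coh, "treatments")
  attr(both, "index_treatment") <- attr(coh, "index_treatment")
  z <- rep(c(1, 0), each = nt)
  spec <- match_spec(c("age", "anteversion", "pop_angle"))
  res <- direct_match(both, z, spec)
  expect_equal(res$matched_frac, 1)
  q <- match_quality(res)
  expect_equal(q$mean_smd_matched, 0)
  expect_equal(q$prior_rate_diff_pct, 0)
})
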