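# Shared fixtures and oracles, all built in code at test time.

fast_bart <- function() bart_params(n_burn = 100, n_keep = 200)
fast_bcf <- function() bcf_params(n_burn = 100, n_keep = 200)
calib_bart <- function() bart_params(n_burn = 250, n_keep = 500)
calib_bcf <- function() bcf_params(n_burn = 250, n_keep = 500)

# standard preprocessing chain used by the calibration studies
prep_cohort <- function(coh) {
  coh <- filter_eligible(coh)
  coh <- encode_missing_categorical(coh)
  coh <- impute_faqt(coh)
  num <- names(coh)[vapply(coh, is.numeric, logical(1))]
  num <- setdiff(num, c(outcome_levels()$follow, outcome_levels()$base,
                        grep("^faq_q", names(coh), value = TRUE)))
  coh[stats::complete.cases(coh[, num, drop = FALSE]), , drop = FALSE]
}

default_distance_covs <- c("age", "ank_dors", "anteversion", "pop_angle",
                           "hip_ext", "bimal", "out1_base", "out2_base",
                           "out3_base")

# one replicate of the three-estimator battery at the body-structures
# level; returns point estimates, CIs, truths and the naive contrast
run_estimator_battery <- function(cfg, seed,
                                  estimators = c("dm", "vt", "bcf")) {
  cfg$seed <- seed
  g <- generate_cohort(cfg)
  coh <- prep_cohort(inject_missingness(g$cohort, cfg))
  trt <- attr(coh, "index_treatment")
  zcol <- paste0("ivl_", trt)
  z <- coh[[zcol]]
  X <- coh[, setdiff(names(coh),
                     c("subject_id", "limb_id", outcome_levels()$follow,
                       grep("^faq_q", names(coh), value = TRUE), zcol)),
           drop = FALSE]
  pihat <- fit_bart_probit(X, z, calib_bart(),
                           keep_forest = FALSE)$yhat_train
  csd <- change_sd(coh, "body_structures")
  gen_ids <- attr(g$truth, "limb_ids")
  d_true_all <- mean(g$truth$tau[match(coh$limb_id[z == 1], gen_ids), 1]) /
    csd
  ch <- coh$out1_follow - coh$out1_base
  out <- list(naive = (mean(ch[z == 1]) - mean(ch[z == 0])) / csd,
              d_true_all = d_true_all)
  if ("dm" %in% estimators) {
    spec <- match_spec(default_distance_covs,
                       near_fine = setdiff(
                         c(grep("^prior_", names(coh), value = TRUE),
                           grep("^ivl_", names(coh), value = TRUE)), zcol))
    mr <- direct_match(coh, z, spec, propensity = pihat,
                       index_treatment = trt)
    e <- dm_att(mr$pairs, coh, "body_structures", trt)
    out$dm <- e$d
    out$dm_ci <- unname(e$ci)
    out$d_true_matched <-
      mean(g$truth$tau[match(mr$pairs$treated_id, gen_ids), 1]) / csd
    out$match <- mr
  }
  if ("vt" %in% estimators) {
    e <- vt_att(coh, trt, "body_structures", "all", params = calib_bart())
    out$vt <- e$d
    out$vt_ci <- unname(e$ci)
  }
  if ("bcf" %in% estimators) {
    e <- bcf_att(coh, trt, "body_structures", "all", pihat,
                 params = calib_bcf())
    out$bcf <- e$d
    out$bcf_ci <- unname(e$ci)
  }
  out
}

# exhaustive-enumeration oracle for the matching objective: tries every
# one-to-one assignment (including leaving any treated unmatched) and
# returns the minimum of the full penalized objective.  Independent of
# the solver's branch-and-bound and local search.
enumerate_match_optimum <- function(cost, subsetw, balT = NULL,
                                    balC = NULL, slack = NULL, pen = NULL) {
  Tn <- nrow(cost); Cn <- ncol(cost)
  if (is.null(balT)) balT <- matrix(0, Tn, 0)
  if (is.null(balC)) balC <- matrix(0, Cn, 0)
  K <- ncol(balT)
  best <- Inf
  assign <- integer(Tn)
  recur <- function(i, used, total) {
    if (i > Tn) {
      penalty <- 0
      if (K > 0) {
        mi <- which(assign > 0)
        dT <- colSums(balT[mi, , drop = FALSE])
        dC <- colSums(balC[assign[mi], , drop = FALSE])
        viol <- pmax(0, abs(dT - dC) - slack)
        penalty <- sum(pen * viol)
      }
      best <<- min(best, total + penalty)
      return(invisible())
    }
    for (j in seq_len(Cn)) {
      if (used[j]) next
      assign[i] <<- j
      used[j] <- TRUE
      recur(i + 1, used, total + cost[i, j])
      used[j] <- FALSE
    }
    assign[i] <<- 0L
    recur(i + 1, used, total + subsetw)
  }
  recur(1L, rep(FALSE, Cn), 0)
  best
}

# small hand-made cohort for estimator arithmetic tests
toy_cohort <- function(changes_t, changes_c) {
  n <- length(changes_t) + length(changes_c)
  data.frame(limb_id = paste0("L", seq_len(n)),
             out1_base = rep(0, n),
             out1_follow = c(changes_t, changes_c),
             stringsAsFactors = FALSE)
}
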