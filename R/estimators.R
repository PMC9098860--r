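#' Outcome level metadata
#'
#' Maps the four outcome levels of the causal chain to their baseline
#' and follow-up columns in a cohort.
#' @return data.frame with columns level, base, follow.
#' @export
outcome_levels <- function() {
  data.frame(level = c("body_structures", "specific_kinematic",
                       "overall_kinematic", "functional_mobility"),
             base = c("out1_base", "out2_base", "out3_base", "faqt_base"),
             follow = c("out1_follow", "out2_follow", "out3_follow",
                        "faqt_follow"),
             stringsAsFactors = FALSE)
}

#' Cohen's d standardizer for an ATT
#'
#' Divides a raw ATT by the SD of the outcome change (follow-up minus
#' baseline) among all analysis limbs, treated and control alike.
#'
#' @param raw_effect raw ATT in outcome units.
#' @param cohort analysis cohort.
#' @param outcome outcome level name (see [outcome_levels()]).
#' @return effect size d.
#' @export
cohens_d <- function(raw_effect, cohort, outcome) {
  s <- change_sd(cohort, outcome)
  raw_effect / s
}

#' SD of the outcome change in a cohort
#' @inheritParams cohens_d
#' @return positive scalar.
#' @export
change_sd <- function(cohort, outcome) {
  lv <- outcome_levels()
  i <- match(outcome, lv$level)
  if (is.na(i)) stop("unknown outcome level: ", outcome)
  ch <- cohort[[lv$follow[i]]] - cohort[[lv$base[i]]]
  ch <- ch[!is.na(ch)]
  if (length(ch) < 2) stop("need at least 2 analysis rows")
  s <- sd(ch)
  if (!is.finite(s) || s == 0) stop("zero change SD")
  s
}

#' Limb-level bootstrap for an ATT
#'
#' Resamples limbs with replacement and takes the percentile 2.5/97.5
#' interval of the resampled mean effect.  Limbs -- not individuals --
#' are the resampling unit, which avoids assumptions about the
#' correlation between limbs of the same person.  When a posterior-draw
#' matrix is supplied (virtual twins, BCF), each replicate also samples
#' one posterior draw so the interval reflects model uncertainty as well
#' as sampling variability.
#'
#' @param per_limb_effects numeric vector of per-limb effect estimates.
#' @param n_boot bootstrap replicates (1000 in the reference analysis).
#' @param seed optional seed applied before resampling.
#' @param draws optional matrix (posterior draws x limbs) of per-limb
#'   effect draws.
#' @return named vector: mean, ci_lo, ci_hi.
#' @export
bootstrap_att <- function(per_limb_effects, n_boot = 1000, seed = NULL,
                          draws = NULL) {
  n <- length(per_limb_effects)
  if (n < 2) stop("need at least 2 per-limb effects")
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(draws)) {
    reps <- vapply(seq_len(n_boot), function(b)
      mean(per_limb_effects[sample.int(n, n, replace = TRUE)]),
      numeric(1))
  } else {
    stopifnot(ncol(draws) == n)
    nd <- nrow(draws)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      mean(draws[sample.int(nd, 1), idx])
    }, numeric(1))
  }
  ci <- unname(quantile(reps, c(0.025, 0.975), type = 7))
  c(mean = mean(per_limb_effects), ci_lo = ci[1], ci_hi = ci[2])
}

.att_estimate <- function(treatment, outcome, model, sample, effect,
                          cohort, per_limb, draws = NULL, n_boot = 1000) {
  d_scale <- change_sd(cohort, outcome)
  bt <- bootstrap_att(per_limb, n_boot = n_boot, draws = draws)
  structure(list(treatment = treatment, outcome = outcome, model = model,
                 sample = sample, effect = effect,
                 d = effect / d_scale,
                 ci = c(lo = unname(bt["ci_lo"]) / d_scale,
                        hi = unname(bt["ci_hi"]) / d_scale),
                 n_treated = length(per_limb),
                 category = categorize_effect(effect / d_scale),
                 standardizer = "change-SD, all analysis limbs"),
            class = "att_estimate")
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf("%s / %s [%s, %s]: d = %.3f (%.3f, %.3f) '%s', n = %d\n",
              x$treatment, x$outcome, x$model, x$sample, x$d, x$ci["lo"],
              x$ci["hi"], x$category, x$n_treated))
  invisible(x)
}

#' Direct-matching ATT estimate
#'
#' Per-pair effect is the difference in outcome change between the
#' treated limb and its matched control; the ATT is the mean over pairs,
#' standardized by the change SD over all matched limbs.
#'
#' @param pairs data.frame (`treated_id`, `control_id`) from
#'   [solve_match()].
#' @param cohort cohort data.frame.
#' @param outcome outcome level name.
#' @param treatment treatment label for the record.
#' @param n_boot bootstrap replicates.
#' @return an `att_estimate` (sample is always "matched").
#' @export
dm_att <- function(pairs, cohort, outcome, treatment = "treatment",
                   n_boot = 1000) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("empty pair set")
  lv <- outcome_levels()
  i <- match(outcome, lv$level)
  ch <- cohort[[lv$follow[i]]] - cohort[[lv$base[i]]]
  names(ch) <- cohort$limb_id
  pe <- ch[pairs$treated_id] - ch[pairs$control_id]
  dropped <- sum(is.na(pe))
  if (dropped > 0)
    message("dm_att: dropping ", dropped, " pairs with missing outcome")
  pe <- pe[!is.na(pe)]
  if (length(pe) < 2) stop("too few pairs with observed outcomes")
  sub <- cohort[cohort$limb_id %in% c(pairs$treated_id,
                                      pairs$control_id), ]
  .att_estimate(treatment, outcome, "DM", "matched", mean(pe), sub,
                unname(pe), n_boot = n_boot)
}

# covariate columns used by every outcome/propensity model: everything
# observable at baseline plus all treatment flags, minus identifiers,
# follow-up outcomes and raw FAQ items
analysis_covariates <- function(cohort, drop = character(0)) {
  lv <- outcome_levels()
  excl <- c("subject_id", "limb_id", lv$follow,
            grep("^faq_q", names(cohort), value = TRUE), drop)
  setdiff(names(cohort), excl)
}

#' Virtual-twins ATT estimate
#'
#' Fits BART to the follow-up outcome on all covariates and treatment
#' flags (the baseline outcome always included), then flips the index
#' treatment flag of each treated limb to construct its untreated
#' virtual twin; the per-limb effect is the posterior mean gap between
#' the actual and twin predictions.
#'
#' @param cohort analysis cohort (complete covariates).
#' @param treatment treatment name (its flag column is `ivl_<name>`).
#' @param outcome outcome level name.
#' @param sample "all" treated limbs or the "matched" subset.
#' @param pairs matched pairs (required when `sample = "matched"`).
#' @param params [bart_params()].
#' @param n_boot bootstrap replicates.
#' @return an `att_estimate`.
#' @export
vt_att <- function(cohort, treatment, outcome, sample = c("all", "matched"),
                   pairs = NULL, params = bart_params(), n_boot = 1000) {
  sample <- match.arg(sample)
  lv <- outcome_levels()
  i <- match(outcome, lv$level)
  zcol <- paste0("ivl_", treatment)
  if (!zcol %in% names(cohort)) stop("no flag column ", zcol)
  keep <- !is.na(cohort[[lv$follow[i]]]) & !is.na(cohort[[lv$base[i]]])
  coh <- cohort[keep, , drop = FALSE]
  y <- coh[[lv$follow[i]]]
  X <- coh[, analysis_covariates(coh), drop = FALSE]
  tsel <- which(coh[[zcol]] == 1)
  if (sample == "matched") {
    if (is.null(pairs)) stop("matched sample requires pairs")
    tsel <- which(coh$limb_id %in% pairs$treated_id & coh[[zcol]] == 1)
  }
  if (length(tsel) == 0) stop("empty treated sample")
  Xt <- X[tsel, , drop = FALSE]
  Xtwin <- Xt
  Xtwin[[zcol]] <- 0
  fit <- fit_bart(X, y, params, X_test = rbind(Xt, Xtwin),
                  keep_forest = FALSE)
  nt <- length(tsel)
  gap <- fit$test_draws[, seq_len(nt), drop = FALSE] -
    fit$test_draws[, nt + seq_len(nt), drop = FALSE]
  per_limb <- colMeans(gap)
  .att_estimate(treatment, outcome, "VT", sample, mean(per_limb), coh,
                per_limb, draws = gap, n_boot = n_boot)
}

# fit VT once and return both the matched-subset and all-treated
# estimates (the fitted model is sample-independent)
.vt_both <- function(cohort, treatment, outcome, pairs,
                     params = bart_params(), n_boot = 1000) {
  lv <- outcome_levels()
  i <- match(outcome, lv$level)
  zcol <- paste0("ivl_", treatment)
  keep <- !is.na(cohort[[lv$follow[i]]]) & !is.na(cohort[[lv$base[i]]])
  coh <- cohort[keep, , drop = FALSE]
  y <- coh[[lv$follow[i]]]
  X <- coh[, analysis_covariates(coh), drop = FALSE]
  tall <- which(coh[[zcol]] == 1)
  Xt <- X[tall, , drop = FALSE]
  Xtwin <- Xt
  Xtwin[[zcol]] <- 0
  fit <- fit_bart(X, y, params, X_test = rbind(Xt, Xtwin),
                  keep_forest = FALSE)
  nt <- length(tall)
  gap <- fit$test_draws[, seq_len(nt), drop = FALSE] -
    fit$test_draws[, nt + seq_len(nt), drop = FALSE]
  sub <- which(coh$limb_id[tall] %in% pairs$treated_id)
  mk <- function(cols, sample) {
    g <- gap[, cols, drop = FALSE]
    pl <- colMeans(g)
    .att_estimate(treatment, outcome, "VT", sample, mean(pl), coh, pl,
                  draws = g, n_boot = n_boot)
  }
  list(matched = mk(sub, "matched"), all = mk(seq_len(nt), "all"))
}

# likewise for BCF: one fit, two sample averages
.bcf_both <- function(cohort, treatment, outcome, pihat, pairs,
                      params = bcf_params(), n_boot = 1000) {
  lv <- outcome_levels()
  i <- match(outcome, lv$level)
  zcol <- paste0("ivl_", treatment)
  keep <- !is.na(cohort[[lv$follow[i]]]) & !is.na(cohort[[lv$base[i]]])
  coh <- cohort[keep, , drop = FALSE]
  y <- coh[[lv$follow[i]]]
  z <- coh[[zcol]]
  X <- coh[, analysis_covariates(coh, drop = zcol), drop = FALSE]
  fit <- fit_bcf(X, z, pmin(pmax(pihat[keep], 1e-4), 1 - 1e-4), y, params)
  tall <- which(z == 1)
  sub <- tall[coh$limb_id[tall] %in% pairs$treated_id]
  mk <- function(rows, sample) {
    dr <- bcf_tau_draws(fit, rows)
    pl <- colMeans(dr)
    .att_estimate(treatment, outcome, "BCF", sample, mean(pl), coh, pl,
                  draws = dr, n_boot = n_boot)
  }
  list(matched = mk(sub, "matched"), all = mk(tall, "all"))
}

#' Bayesian-causal-forest ATT estimate
#'
#' Fits the two-forest decomposition to the follow-up outcome (index
#' treatment as `z`, all other covariates and co-treatment flags in the
#' forests, estimated propensity feeding the prognostic forest) and
#' averages the posterior moderating-forest draws over the treated limbs
#' in the requested sample.
#'
#' @inheritParams vt_att
#' @param pihat propensity estimates aligned with `cohort`.
#' @param params [bcf_params()].
#' @return an `att_estimate`.
#' @export
bcf_att <- function(cohort, treatment, outcome, sample = c("all", "matched"),
                    pihat, pairs = NULL, params = bcf_params(),
                    n_boot = 1000) {
  sample <- match.arg(sample)
  lv <- outcome_levels()
  i <- match(outcome, lv$level)
  zcol <- paste0("ivl_", treatment)
  keep <- !is.na(cohort[[lv$follow[i]]]) & !is.na(cohort[[lv$base[i]]])
  coh <- cohort[keep, , drop = FALSE]
  ph <- pihat[keep]
  y <- coh[[lv$follow[i]]]
  z <- coh[[zcol]]
  X <- coh[, analysis_covariates(coh, drop = zcol), drop = FALSE]
  fit <- fit_bcf(X, z, pmin(pmax(ph, 1e-4), 1 - 1e-4), y, params)
  tsel <- which(z == 1)
  if (sample == "matched") {
    if (is.null(pairs)) stop("matched sample requires pairs")
    tsel <- which(coh$limb_id %in% pairs$treated_id & z == 1)
  }
  if (length(tsel) == 0) stop("empty treated sample")
  draws <- bcf_tau_draws(fit, tsel)
  per_limb <- colMeans(draws)
  .att_estimate(treatment, outcome, "BCF", sample, mean(per_limb), coh,
                per_limb, draws = draws, n_boot = n_boot)
}
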