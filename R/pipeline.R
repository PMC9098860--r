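#' Effect-size category
#'
#' Conventional thresholds on |d|: small >= 0.2, medium >= 0.5,
#' large >= 0.8, very large >= 1.2; below 0.2 is "none".  Boundaries are
#' inclusive upward.
#'
#' @param d effect size (finite).
#' @return character vector of categories.
#' @export
categorize_effect <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, Inf), right = FALSE,
      labels = c("none", "small", "medium", "large", "very large")) |>
    as.character()
}

#' Analysis configuration for the full pipeline
#'
#' @param treatments treatment names to analyze (their `ivl_` flags must
#'   exist in the cohort).
#' @param distance_covariates covariates for the matching distance;
#'   defaults to age, the continuous exam measures and the baseline
#'   outcomes.
#' @param moment_covariates optional moment-balance covariates.
#' @param bart_params,bcf_params estimator settings.  The default uses a
#'   reduced MCMC budget (250 burn-in / 500 kept); set
#'   `paper_fidelity = TRUE` for the full 1000 / 1000 budget.
#' @param n_boot bootstrap replicates per estimate.
#' @param paper_fidelity restore the full MCMC budget.
#' @param seed integer seed for the whole run.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(treatments = NULL,
                            distance_covariates = c("age", "ank_dors",
                              "anteversion", "pop_angle", "hip_ext",
                              "bimal", "out1_base", "out2_base",
                              "out3_base"),
                            moment_covariates = character(0),
                            bart_params = NULL, bcf_params = NULL,
                            n_boot = 1000, paper_fidelity = FALSE,
                            seed = 1L) {
  if (paper_fidelity) {
    bart_params <- bart_params %||% cpcausal::bart_params(n_burn = 1000,
                                                          n_keep = 1000)
    bcf_params <- bcf_params %||% cpcausal::bcf_params(n_burn = 1000,
                                                       n_keep = 1000)
  } else {
    bart_params <- bart_params %||% cpcausal::bart_params(n_burn = 250,
                                                          n_keep = 500)
    bcf_params <- bcf_params %||% cpcausal::bcf_params(n_burn = 250,
                                                       n_keep = 500)
  }
  structure(list(treatments = treatments,
                 distance_covariates = distance_covariates,
                 moment_covariates = moment_covariates,
                 bart_params = bart_params, bcf_params = bcf_params,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Median and IQR of effect sizes per outcome level
#'
#' Pools the effect sizes of all treatments and all five estimates
#' (DM-matched, VT-matched, VT-all, BCF-matched, BCF-all) within each
#' outcome level.
#'
#' @param estimates data.frame of estimates (from
#'   [run_full_analysis()]) with columns `outcome` and `d`.
#' @return data.frame: level, n, median_d, q25, q75.
#' @export
aggregate_summary <- function(estimates) {
  if (nrow(estimates) == 0) stop("no estimates to aggregate")
  lvs <- outcome_levels()$level
  miss <- setdiff(unique(estimates$outcome), lvs)
  if (length(miss) > 0) stop("unknown outcome level: ", miss[1])
  out <- do.call(rbind, lapply(intersect(lvs, unique(estimates$outcome)),
                               function(l) {
    d <- estimates$d[estimates$outcome == l]
    data.frame(level = l, n = length(d), median_d = median(d),
               q25 = unname(quantile(d, 0.25, type = 7)),
               q75 = unname(quantile(d, 0.75, type = 7)))
  }))
  rownames(out) <- NULL
  out
}

# one row per att_estimate
.estimate_row <- function(e, true_att = NA_real_, d_true = NA_real_) {
  data.frame(treatment = e$treatment, outcome = e$outcome,
             model = e$model, sample = e$sample, effect = e$effect,
             d = e$d, ci_lo = e$ci["lo"], ci_hi = e$ci["hi"],
             n_treated = e$n_treated, category = e$category,
             ci_covers_zero = e$ci["lo"] <= 0 & e$ci["hi"] >= 0,
             true_att = true_att, d_true = d_true,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full three-estimator analysis
#'
#' Per treatment: eligibility filtering, "Miss" recoding, FAQt
#' imputation, listwise deletion of rows with missing numeric
#' covariates, probit-BART propensity fit, direct matching, then five
#' ATT estimates per outcome level (DM on the matched pairs; VT and BCF
#' each on the matched subset and on all treated limbs), with limb-level
#' bootstrap intervals and effect-size categories.  A failing treatment
#' is logged and skipped; the others continue.
#'
#' @param cohort limb-level cohort (e.g. from [generate_cohort()] after
#'   [inject_missingness()]).
#' @param config an [analysis_config()].
#' @param truth optional `synth_truth` for recovery reporting (valid for
#'   the generator's index treatment; co-treatments get their
#'   homogeneous true effects).
#' @return list of class `cp_analysis`: `estimates` (tidy data.frame),
#'   `summary` (per-level median/IQR), `balance` (per treatment),
#'   `propensity_fit` (per-treatment metrics), `errors`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config(),
                              truth = NULL) {
  set.seed(config$seed)
  coh <- filter_eligible(cohort)
  coh <- encode_missing_categorical(coh)
  coh <- impute_faqt(coh)
  trts <- config$treatments %||% attr(cohort, "treatments") %||%
    sub("^ivl_", "", grep("^ivl_", names(cohort), value = TRUE))
  # listwise deletion on numeric covariates (categoricals carry "Miss")
  num <- names(coh)[vapply(coh, is.numeric, logical(1))]
  num <- setdiff(num, c(outcome_levels()$follow, outcome_levels()$base,
                        grep("^faq_q", names(coh), value = TRUE)))
  coh <- coh[complete.cases(coh[, num, drop = FALSE]), , drop = FALSE]

  idx_trt <- attr(cohort, "index_treatment")
  rows <- list(); bal <- list(); prop <- list(); errors <- character(0)
  for (trt in trts) {
    res <- tryCatch({
      zcol <- paste0("ivl_", trt)
      z <- coh[[zcol]]
      X <- coh[, analysis_covariates(coh, drop = zcol), drop = FALSE]
      pfit <- fit_bart_probit(X, z, config$bart_params,
                              keep_forest = FALSE)
      pihat <- pfit$yhat_train
      nf <- setdiff(c(grep("^prior_", names(coh), value = TRUE),
                      grep("^ivl_", names(coh), value = TRUE)), zcol)
      spec <- match_spec(config$distance_covariates, near_fine = nf,
                         moment_covariates = config$moment_covariates)
      mres <- direct_match(coh, z, spec, propensity = pihat,
                           index_treatment = trt)
      trt_rows <- list()
      for (lvl in outcome_levels()$level) {
        tr_att <- .true_att(truth, coh, trt, lvl, idx_trt, mres$pairs)
        vt2 <- .vt_both(coh, trt, lvl, mres$pairs,
                        params = config$bart_params,
                        n_boot = config$n_boot)
        bc2 <- .bcf_both(coh, trt, lvl, pihat, mres$pairs,
                         params = config$bcf_params,
                         n_boot = config$n_boot)
        ests <- list(
          dm_att(mres$pairs, coh, lvl, treatment = trt,
                 n_boot = config$n_boot),
          vt2$matched, vt2$all, bc2$matched, bc2$all)
        names(tr_att) <- NULL
        trt_rows <- c(trt_rows, lapply(seq_along(ests), function(i) {
          ta <- tr_att[[c(1, 1, 2, 1, 2)[i]]]
          .estimate_row(ests[[i]], ta,
                        ta / change_sd(coh, lvl))
        }))
      }
      list(rows = trt_rows, balance = mres$balance,
           prop = evaluate_propensity(pihat, z))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(trt, ": ", conditionMessage(res)))
      next
    }
    rows <- c(rows, res$rows)
    bal[[trt]] <- res$balance
    prop[[trt]] <- res$prop
  }
  estimates <- do.call(rbind, rows)
  structure(list(estimates = estimates,
                 summary = if (!is.null(estimates))
                   aggregate_summary(estimates) else NULL,
                 balance = bal, propensity_fit = prop, errors = errors,
                 config = config),
            class = "cp_analysis")
}

# true ATT (outcome units) for treatment trt at level lvl, over the
# matched subset and over all treated rows of the analysis cohort;
# returns c(matched, all) or NAs when no truth is available
.true_att <- function(truth, coh, trt, lvl, idx_trt, pairs) {
  if (is.null(truth)) return(c(NA_real_, NA_real_))
  k <- match(lvl, outcome_levels()$level)
  trts <- truth$config$treatments
  if (!is.null(idx_trt) && trt == idx_trt) {
    # heterogeneous: average tau over the relevant limbs
    tau_all <- truth$tau[, k]
    names(tau_all) <- NULL
    # row alignment: truth rows follow the generated cohort order
    ids_all <- coh$limb_id[coh[[paste0("ivl_", trt)]] == 1]
    gen_ids <- .truth_limb_ids(truth)
    c(mean(tau_all[match(intersect(pairs$treated_id, ids_all), gen_ids)]),
      mean(tau_all[match(ids_all, gen_ids)]))
  } else {
    co <- truth$co_eff[match(trt, trts), k]
    c(co, co)
  }
}

.truth_limb_ids <- function(truth) {
  attr(truth, "limb_ids") %||%
    stop("truth object lacks limb ids; regenerate with generate_cohort()")
}

#' @export
print.cp_analysis <- function(x, ...) {
  cat("Three-estimator ATT analysis\n")
  if (!is.null(x$estimates))
    cat("  estimates:", nrow(x$estimates), "rows over",
        length(unique(x$estimates$treatment)), "treatments\n")
  if (!is.null(x$summary)) {
    cat("  median d by level:\n")
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf("    %-20s %.2f [%.2f, %.2f]\n", x$summary$level[i],
                  x$summary$median_d[i], x$summary$q25[i],
                  x$summary$q75[i]))
  }
  if (length(x$errors) > 0)
    cat("  failed treatments:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}
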