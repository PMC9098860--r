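#' Default treatment names for synthetic cohorts
#'
#' Thirteen common orthopedic and neurological treatments for ambulatory
#' cerebral palsy, used to label prior/interval co-treatment flags.
#' @return character vector of length 13.
#' @export
cp_treatments <- function() {
  c("sdr", "neurotoxin", "rectus_transfer", "fdo", "tdo",
    "psoas_release", "adductor_release", "hams_lengthening",
    "calf_lengthening", "dfeo", "patellar_advance",
    "foot_bone", "foot_soft")
}

#' Default FAQ item difficulty weights
#' @return positive numeric vector of length 23.
#' @export
faq_weights_default <- function() seq(0.5, 2, length.out = 23)

#' Configuration for the synthetic limb-level cohort generator
#'
#' The generator emulates the statistical structure of a clinical gait
#' analysis database: limbs nested in individuals through a shared latent
#' severity factor, mixed covariate types loading on that factor,
#' treatment assignment that depends on both severity (prognosis) and the
#' expected benefit (targeted selection, strength `lambda`), co-occurring
#' prior and interval treatments, and outcomes at four levels of a causal
#' chain (body structures, specific kinematic deviation, overall
#' kinematic deviation, functional mobility) whose treatment effect
#' attenuates along the chain.
#'
#' `delta` gives the index-treatment effect per outcome level in units of
#' the untreated change SD at that level, so `delta = c(0.4, 0.2, 0.1, 0)`
#' means a treated limb improves by 0.4 change-SD at the body-structures
#' level and not at all in functional mobility.  `het_strength` scales a
#' severity-linear effect modifier: tau_k(x) = delta_k * S_k *
#' (1 + het_strength * severity).
#'
#' @param n_subjects number of individuals.
#' @param limbs_per_subject limbs contributed per individual.
#' @param within_subject_corr correlation of limb severities within an
#'   individual, in \[0, 1).
#' @param n_treatments number of treatment categories (first
#'   `n_treatments` names of [cp_treatments()]).
#' @param index_treatment which treatment carries the configured effect
#'   profile (name or index); the others act as co-treatments.
#' @param lambda targeted-selection strength: weight of the standardized
#'   expected benefit in the assignment logit.
#' @param base_rate marginal index-treatment probability at average
#'   severity.
#' @param delta effect profile (4 values, change-SD units).
#' @param het_strength severity-linear effect heterogeneity multiplier.
#' @param co_effect co-treatment effect size at level 1 (change-SD
#'   units), attenuated along the chain like `delta`'s shape.  A scalar
#'   applies to every co-treatment; the default NULL spreads effects
#'   over 0.05--0.45 across treatments, mimicking the wide range of
#'   real treatment effectiveness.
#' @param noise_sd outcome change noise SD per level (outcome units).
#' @param missingness named list of rates in \[0, 1\]: `gmfcs`,
#'   `motor_control`, `spasticity`, `strength`, `ank_dors`, `faq_item`
#'   (item-level non-response), `faq_block` (whole-questionnaire
#'   non-response, which leaves the FAQt undefined); plus logical
#'   `severity_dependent`.
#' @param followup_years_range uniform range of follow-up interval.
#' @param faq_weights difficulty weights for the 23 FAQ items.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return list of class `synth_config`.
#' @export
synthetic_config <- function(n_subjects = 400, limbs_per_subject = 2,
                             within_subject_corr = 0.6, n_treatments = 13,
                             index_treatment = 1, lambda = 1,
                             base_rate = 0.3,
                             delta = c(0.4, 0.2, 0.1, 0.0),
                             het_strength = 0.5, co_effect = NULL,
                             noise_sd = c(5, 4, 4, 0.25),
                             missingness = list(gmfcs = 0.20,
                                                motor_control = 0.05,
                                                spasticity = 0.03,
                                                strength = 0.03,
                                                ank_dors = 0.03,
                                                faq_item = 0.05,
                                                faq_block = 0.08,
                                                severity_dependent = TRUE),
                             followup_years_range = c(0.9, 2.5),
                             faq_weights = faq_weights_default(),
                             seed = 1L) {
  if (n_subjects <= 0) stop("n_subjects must be positive")
  if (length(delta) != 4) stop("delta profile must have length 4")
  stopifnot(within_subject_corr >= 0, within_subject_corr < 1,
            n_treatments >= 1, n_treatments <= 13,
            all(noise_sd > 0), length(noise_sd) == 4,
            length(faq_weights) == 23, all(faq_weights > 0),
            followup_years_range[1] > 0,
            followup_years_range[1] < followup_years_range[2])
  rates <- missingness[setdiff(names(missingness), "severity_dependent")]
  if (any(unlist(rates) < 0) || any(unlist(rates) > 1))
    stop("missingness rates must lie in [0, 1]")
  trts <- cp_treatments()[seq_len(n_treatments)]
  if (is.character(index_treatment)) {
    index_treatment <- match(index_treatment, trts)
    if (is.na(index_treatment)) stop("unknown index treatment")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 limbs_per_subject = as.integer(limbs_per_subject),
                 within_subject_corr = within_subject_corr,
                 treatments = trts,
                 index_treatment = as.integer(index_treatment),
                 lambda = lambda, base_rate = base_rate, delta = delta,
                 het_strength = het_strength, co_effect = co_effect,
                 noise_sd = noise_sd, missingness = missingness,
                 followup_years_range = followup_years_range,
                 faq_weights = faq_weights, seed = as.integer(seed)),
            class = "synth_config")
}

# per-level outcome model constants: baseline intercept, severity loading
# (negative: severe limbs score worse on all "higher is better" scales),
# baseline noise SD, drift intercept and severity slope (natural history
# worsens faster in severe limbs -- the confounding the estimators must
# remove).  Drift also carries an age slope of -0.3 * d1 per
# standardized age unit: younger children worsen faster (rapid
# contracture progression during growth) and are also treated more
# often, so age confounds in the same direction as severity.
.age_drift <- -0.3

.level_pars <- function(noise_sd) {
  data.frame(level = c("body_structures", "specific_kinematic",
                       "overall_kinematic", "functional_mobility"),
             b0 = c(50, 20, 85, 2.5), b1 = c(-10, -6, -7, -0.6),
             sb = c(5, 4, 5, 0.3), d0 = c(-1, -0.5, -0.5, 0),
             d1 = c(-2, -1.5, -1.2, -0.08), se = noise_sd,
             stringsAsFactors = FALSE)
}

#' Untreated change SD per outcome level
#'
#' Closed-form SD of the no-treatment outcome change implied by the
#' generator (severity-driven drift plus level noise); the scale in which
#' the `delta` effect profile is expressed.
#' @param config a [synthetic_config()].
#' @return numeric vector of length 4.
#' @export
change_sd_true <- function(config) {
  lp <- .level_pars(config$noise_sd)
  vz <- (14^2 / 12) / 16  # variance of standardized age, age ~ U(4, 18)
  sqrt(lp$d1^2 * (1 + .age_drift^2 * vz) + lp$se^2)
}

#' Generate a synthetic limb-level cohort with ground truth
#'
#' Draws a cohort under the configured targeted-selection design and
#' returns both the observable table and a truth object holding every
#' limb's individual treatment effect and the realized ATT per outcome
#' level (the oracle for parameter-recovery tests).
#'
#' @param config a [synthetic_config()].
#' @return list with elements `cohort` (data.frame, one row per limb) and
#'   `truth` (class `synth_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  lps <- config$limbs_per_subject
  n <- ns * lps
  rho <- config$within_subject_corr

  # latent severity: shared subject factor plus limb-level deviation
  sev_subj <- rnorm(ns)
  sev <- sqrt(rho) * rep(sev_subj, each = lps) +
    sqrt(1 - rho) * rnorm(n)

  subject_id <- rep(sprintf("S%04d", seq_len(ns)), each = lps)
  side <- rep_len(c("L", "R"), lps)[rep(seq_len(lps), ns)]
  limb_id <- paste0(subject_id, "_", side,
                    ave(seq_len(n), paste(subject_id, side),
                        FUN = seq_along))
  age <- rep(runif(ns, 4, 18), each = lps)
  sex <- rep(sample(c("M", "F"), ns, replace = TRUE,
                    prob = c(0.58, 0.42)), each = lps)
  fu <- rep(runif(ns, config$followup_years_range[1],
                  config$followup_years_range[2]), each = lps)

  ordcut <- function(latent, probs) {
    cuts <- qnorm(cumsum(probs)[-length(probs)])
    findInterval(latent, cuts) + 1L
  }
  gmfcs_lv <- ordcut(rep(0.9 * sev_subj, each = lps) + 0.45 * rnorm(n),
                     c(0.25, 0.35, 0.25, 0.15))
  gmfcs <- factor(c("I", "II", "III", "IV")[gmfcs_lv],
                  levels = c("I", "II", "III", "IV"))
  topo_lv <- ordcut(rep(0.7 * sev_subj, each = lps) + 0.7 * rnorm(n),
                    c(0.08, 0.62, 0.18, 0.12))
  topography <- factor(c("hemiplegia", "diplegia", "triplegia",
                         "quadriplegia")[topo_lv],
                       levels = c("hemiplegia", "diplegia", "triplegia",
                                  "quadriplegia"))
  # limb-level physical exam measures loading on severity
  ank_dors <- 10 - 4 * sev + rnorm(n, 0, 3)
  anteversion <- 30 + 5 * sev + rnorm(n, 0, 5)
  pop_angle <- 40 + 8 * sev + rnorm(n, 0, 6)
  hip_ext <- 5 - 3 * sev + rnorm(n, 0, 3)
  bimal <- 15 + 4 * sev + rnorm(n, 0, 4)
  # ordinal exam scores kept as factors so a "Miss" level can be added
  spasticity <- factor(ordcut(0.8 * sev + 0.6 * rnorm(n),
                              c(0.2, 0.3, 0.3, 0.15, 0.05)) - 1L,
                       levels = 0:4)
  strength <- factor(5L - (ordcut(0.8 * sev + 0.6 * rnorm(n),
                                  c(0.05, 0.15, 0.3, 0.3, 0.2)) - 1L),
                     levels = 0:5)
  motor_control <- factor(c("typical", "diminished",
                            "absent")[ordcut(0.7 * sev + 0.7 * rnorm(n),
                                             c(0.45, 0.4, 0.15))],
                          levels = c("absent", "diminished", "typical"))
  kvv_rom <- 6 + 2.5 * abs(rnorm(n)) + 1.5 * pmax(sev, 0)

  trts <- config$treatments
  Tn <- length(trts)
  idx <- config$index_treatment
  lp <- .level_pars(config$noise_sd)
  S <- change_sd_true(config)

  # individual index-treatment effect per level (change-SD units -> units)
  hmod <- 1 + config$het_strength * sev
  tau <- sapply(seq_len(4), function(k) config$delta[k] * S[k] * hmod)
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = n)

  # prior treatments: severity-dependent, modest base rates
  p0 <- 0.05 + 0.15 * (seq_len(Tn) - 1) / max(1, Tn - 1)
  prior <- sapply(seq_len(Tn), function(t)
    rbinom(n, 1, plogis(qlogis(p0[t]) + 0.5 * sev)))
  colnames(prior) <- paste0("prior_", trts)

  # index treatment assigned from the OBSERVED clinical picture, not the
  # latent severity: clinicians decide from the chart, which is what
  # makes treatment ignorable given the measured covariates (the
  # framework's identifying assumption)
  zage <- (age - 11) / 4
  sev_obs <- drop(scale(scale(anteversion) + scale(pop_angle) -
                          scale(ank_dors) - scale(hip_ext) +
                          scale(bimal) + scale(as.numeric(gmfcs_lv))))
  # expected benefit as judged from observables (targeted selection),
  # in change-SD units; deliberately NOT centered, so a uniformly
  # beneficial treatment is also used more often as lambda grows
  benefit_std <- config$delta[1] * (1 + config$het_strength * sev_obs)
  pi_x <- plogis(qlogis(config$base_rate) + 0.8 * sev_obs - 0.3 * zage +
                   config$lambda * benefit_std)
  z_index <- rbinom(n, 1, pi_x)
  ivl <- sapply(seq_len(Tn), function(t) {
    if (t == idx) return(z_index)
    rbinom(n, 1, plogis(qlogis(p0[Tn + 1 - t]) + 0.5 * sev))
  })
  colnames(ivl) <- paste0("ivl_", trts)

  # co-treatment effects attenuate along the chain like delta's shape;
  # effect sizes spread across treatments unless a scalar is given
  shape <- if (config$delta[1] > 0) config$delta / config$delta[1]
           else c(1, 0.5, 0.25, 0.1)
  co1 <- config$co_effect %||%
    (0.05 + 0.4 * (seq_len(Tn) - 1) / max(1, Tn - 1))
  co_eff <- outer(rep_len(co1, Tn), shape * S)  # Tn x 4, outcome units

  out <- list()
  for (k in seq_len(4)) {
    base_k <- lp$b0[k] + lp$b1[k] * sev + rnorm(n, 0, lp$sb[k]) +
      prior %*% rep(0.3 * lp$sb[k], Tn)
    drift <- lp$d0[k] + lp$d1[k] * (sev + .age_drift * zage)
    co_sum <- drop(ivl[, -idx, drop = FALSE] %*% co_eff[-idx, k])
    follow_k <- base_k + drift + z_index * tau[, k] + co_sum +
      rnorm(n, 0, lp$se[k])
    out[[k]] <- cbind(base_k, follow_k)
  }

  cohort <- data.frame(subject_id, limb_id, side, age, sex,
                       follow_up_years = fu, gmfcs, topography,
                       ank_dors, anteversion, pop_angle, hip_ext, bimal,
                       spasticity, strength, motor_control, kvv_rom,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(prior), as.data.frame(ivl))
  cohort$out1_base <- drop(out[[1]][, 1])
  cohort$out1_follow <- drop(out[[1]][, 2])
  cohort$out2_base <- drop(out[[2]][, 1])
  cohort$out2_follow <- drop(out[[2]][, 2])
  cohort$out3_base <- drop(out[[3]][, 1])
  cohort$out3_follow <- drop(out[[3]][, 2])
  cohort$faqt_base <- drop(out[[4]][, 1]) + rnorm(n, 0, 0.1)

  # follow-up FAQ items: graded versions of the functional latent; the
  # follow-up FAQt column is derived from these by impute_faqt()
  Ff <- drop(out[[4]][, 2])
  offs <- seq(-0.8, 0.8, length.out = 23)
  items <- sapply(seq_len(23), function(i)
    pmin(pmax(round(Ff - offs[i] + rnorm(n, 0, 0.35)), 0), 4))
  colnames(items) <- paste0("faq_q", seq_len(23))
  cohort <- cbind(cohort, as.data.frame(items))
  cohort$faqt_follow <- NA_real_

  attr(cohort, "treatments") <- trts
  attr(cohort, "faq_weights") <- config$faq_weights
  attr(cohort, "index_treatment") <- trts[idx]

  att <- colMeans(tau[z_index == 1, , drop = FALSE])
  truth <- structure(list(tau = tau, att = setNames(att, lp$level),
                          co_eff = co_eff, z_index = z_index,
                          pi_x = pi_x, severity = sev,
                          change_sd = S, config = config),
                     class = "synth_truth")
  attr(truth, "limb_ids") <- limb_id
  list(cohort = cohort, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("Synthetic ground truth:", sum(x$z_index), "treated limbs of",
      length(x$z_index), "\n  true ATT per level:",
      paste(sprintf("%.3f", x$att), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV with its truth side-car
#'
#' One row per limb in the CSV; the ground truth (per-limb effects,
#' realized ATT per level, generating parameters) goes to a JSON file
#' next to it so downstream analyses can score themselves.
#'
#' @param cohort,truth output of [generate_cohort()].
#' @param csv_path path for the cohort CSV.
#' @param truth_path path for the truth JSON (default: same name with
#'   `_truth.json`).
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, truth, csv_path,
                         truth_path = sub("\\.csv$", "_truth.json",
                                          csv_path)) {
  utils::write.csv(cohort, csv_path, row.names = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write the truth side-car")
  tj <- list(att = as.list(truth$att),
             change_sd = truth$change_sd,
             tau = apply(truth$tau, 2, identity, simplify = FALSE),
             z_index = truth$z_index,
             limb_ids = attr(truth, "limb_ids"),
             delta = truth$config$delta,
             lambda = truth$config$lambda,
             seed = truth$config$seed)
  jsonlite::write_json(tj, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, truth_path))
}

#' Inject structured missingness into a synthetic cohort
#'
#' Blanks categorical/ordinal covariates, one continuous exam measure and
#' individual FAQ items at configured rates.  When
#' `missingness$severity_dependent` is TRUE the blanking probability for
#' the neurological measures rises with latent severity (informative
#' missingness: severely involved children often cannot follow the
#' examination instructions), using the severity ranking implied by GMFCS
#' and motor control.  Numeric outcome columns are never blanked.
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param config the same [synthetic_config()].
#' @return cohort with NA entries injected.
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(config, "synth_config"))
  ms <- config$missingness
  rates <- unlist(ms[setdiff(names(ms), "severity_dependent")])
  if (any(rates < 0) || any(rates > 1))
    stop("missingness rates must lie in [0, 1]")
  set.seed(config$seed + 1000003L)
  n <- nrow(cohort)
  # observable severity proxy for informative missingness
  sevp <- scale(as.integer(factor(cohort$gmfcs)) +
                  (3 - as.integer(cohort$motor_control)))[, 1]
  pshift <- if (isTRUE(ms$severity_dependent)) 0.7 * sevp else 0
  blank <- function(rate, informative = FALSE) {
    if (rate <= 0) return(rep(FALSE, n))
    if (rate >= 1) return(rep(TRUE, n))
    p <- if (informative) plogis(qlogis(rate) + pshift) else rep(rate, n)
    runif(n) < p
  }
  cohort$gmfcs[blank(ms$gmfcs %||% 0, TRUE)] <- NA
  cohort$motor_control[blank(ms$motor_control %||% 0, TRUE)] <- NA
  cohort$spasticity[blank(ms$spasticity %||% 0, TRUE)] <- NA
  cohort$strength[blank(ms$strength %||% 0, TRUE)] <- NA
  cohort$ank_dors[blank(ms$ank_dors %||% 0)] <- NA
  noresp <- blank(ms$faq_block %||% 0)  # whole questionnaire missing
  for (i in seq_len(23)) {
    col <- paste0("faq_q", i)
    cohort[[col]][noresp | blank(ms$faq_item %||% 0)] <- NA
  }
  cohort
}
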