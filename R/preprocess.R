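#' Eligibility rules for limb-level observations
#'
#' Defaults encode the study window: age under 25 years, two assessments
#' at least nine months (0.75 y) and less than 30 months (2.5 y) apart,
#' and removal of limbs whose knee varus-valgus range of motion exceeds
#' 15 degrees (a marker of unreliable transverse-plane kinematics).
#'
#' @param max_age,min_followup,max_followup,kvv_limit bounds (years,
#'   years, years, degrees).
#' @return list of class `eligibility_rules`.
#' @export
eligibility_rules <- function(max_age = 25, min_followup = 0.75,
                              max_followup = 2.5, kvv_limit = 15) {
  stopifnot(min_followup < max_followup, max_age > 0, min_followup > 0,
            kvv_limit > 0)
  structure(list(max_age = max_age, min_followup = min_followup,
                 max_followup = max_followup, kvv_limit = kvv_limit),
            class = "eligibility_rules")
}

#' Filter a cohort to eligible limbs
#'
#' Removes rows violating any rule; per-rule removal counts are attached
#' as the `"removed"` attribute.  Idempotent.
#'
#' @param cohort cohort data.frame with `age`, `follow_up_years`,
#'   `kvv_rom` columns.
#' @param rules an [eligibility_rules()] object.
#' @return filtered cohort.
#' @export
filter_eligible <- function(cohort, rules = eligibility_rules()) {
  need <- c("age", "follow_up_years", "kvv_rom")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad_age <- cohort$age >= rules$max_age
  bad_fu <- cohort$follow_up_years < rules$min_followup |
    cohort$follow_up_years >= rules$max_followup
  bad_kvv <- cohort$kvv_rom > rules$kvv_limit
  keep <- !(bad_age | bad_fu | bad_kvv)
  out <- cohort[keep, , drop = FALSE]
  for (a in c("treatments", "faq_weights", "index_treatment"))
    attr(out, a) <- attr(cohort, a)
  attr(out, "removed") <- c(age = sum(bad_age), followup = sum(bad_fu),
                            kvv = sum(bad_kvv))
  out
}

#' Recode missing categorical entries as an explicit "Miss" level
#'
#' Missingness in categorical clinical data is often informative (e.g.
#' neurological scores unobtainable in severely involved children), so a
#' blank is treated as its own level rather than imputed.  Numeric
#' columns are left untouched.
#'
#' @param cohort cohort data.frame.
#' @return cohort with "Miss" levels in factor/character columns.
#' @export
encode_missing_categorical <- function(cohort) {
  for (j in seq_along(cohort)) {
    v <- cohort[[j]]
    if (is.factor(v)) {
      if (anyNA(v)) {
        levels(v) <- c(levels(v), "Miss")
        v[is.na(v)] <- "Miss"
        cohort[[j]] <- v
      }
    } else if (is.character(v) && anyNA(v)) {
      v[is.na(v)] <- "Miss"
      cohort[[j]] <- v
    }
  }
  cohort
}

#' Difficulty-weighted FAQ average (FAQt)
#'
#' Weighted mean of mobility-skill item scores over the non-missing
#' items, defined only when enough items are present (18 of the 23 in
#' the full questionnaire).
#'
#' @param items numeric item scores (NA = non-response).
#' @param weights positive difficulty weights, same length.
#' @param min_items minimum answered items for the score to be defined;
#'   defaults to the 18-of-23 rule scaled to the item count.
#' @return the weighted average, or NA if too few items are present.
#' @export
compute_faqt <- function(items, weights = faq_weights_default(),
                         min_items = NULL) {
  if (length(items) != length(weights))
    stop("items and weights must have equal length")
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(min_items))
    min_items <- ceiling(length(weights) * 18 / 23)
  ok <- !is.na(items)
  if (sum(ok) < min_items) return(NA_real_)
  sum(weights[ok] * items[ok]) / sum(weights[ok])
}

# closed-form ridge coefficients of each item on all other items, fitted
# on complete rows; returns list(mu = item means, B = p x p matrix with
# B[j, ] the coefficients for item j (diagonal 0))
.ridge_imputer <- function(M, lambda = 1) {
  p <- ncol(M)
  mu <- colMeans(M)
  Z <- sweep(M, 2, mu)
  B <- matrix(0, p, p)
  for (j in seq_len(p)) {
    Xo <- Z[, -j, drop = FALSE]
    A <- crossprod(Xo) + lambda * diag(p - 1)
    B[j, -j] <- drop(solve(A, crossprod(Xo, Z[, j])))
  }
  list(mu = mu, B = B)
}

#' Impute FAQ items and build the follow-up FAQt column
#'
#' Rows with at least `min_items` answered items have their missing
#' items filled by a single-pass ridge regression of each missing item
#' on the observed items (coefficients estimated from complete rows),
#' after which the FAQt is computed from all items.  Rows below the
#' threshold keep a missing FAQt and are excluded from
#' functional-mobility analyses.  Rows with complete items are never
#' altered.
#'
#' @param cohort cohort data.frame with `faq_q1` .. `faq_q23` columns.
#' @param weights difficulty weights.
#' @param min_items answered-item threshold (default 18).
#' @param ridge ridge penalty for the imputer.
#' @return cohort with `faqt_follow` filled in.
#' @export
impute_faqt <- function(cohort, weights = NULL, min_items = 18,
                        ridge = 1) {
  cols <- paste0("faq_q", seq_len(23))
  if (!all(cols %in% names(cohort))) stop("FAQ item columns not found")
  if (is.null(weights))
    weights <- attr(cohort, "faq_weights") %||% faq_weights_default()
  M <- as.matrix(cohort[, cols])
  npres <- rowSums(!is.na(M))
  faqt <- rep(NA_real_, nrow(M))
  complete <- npres == 23
  faqt[complete] <- apply(M[complete, , drop = FALSE], 1, compute_faqt,
                          weights = weights, min_items = min_items)
  fill <- npres >= min_items & !complete
  if (any(fill)) {
    if (sum(complete) < 30)
      stop("too few complete rows to train the item imputer")
    imp <- .ridge_imputer(M[complete, , drop = FALSE], lambda = ridge)
    for (i in which(fill)) {
      x <- M[i, ]
      xs <- ifelse(is.na(x), imp$mu, x)  # mean-start for missing predictors
      for (j in which(is.na(x)))
        x[j] <- imp$mu[j] + sum(imp$B[j, ] * (xs - imp$mu))
      faqt[i] <- compute_faqt(x, weights, min_items)
    }
  }
  cohort$faqt_follow <- faqt
  cohort
}

#' Standardized mean difference between treated and control samples
#'
#' Continuous: absolute mean difference over the pooled SD
#' (sqrt of the average group variance).  Factor with K levels: the
#' multivariate Yang--Dalton form sqrt(d' S^-1 d), with d the vector of
#' level-proportion differences over K-1 levels and S the average of the
#' two multinomial covariance matrices (Moore-Penrose pseudo-inverse
#' when singular).  Symmetric in group labels.
#'
#' @param x_treated,x_control samples (numeric, or factor/character).
#' @param kind "continuous", "factor", or "auto" (by type).
#' @return non-negative SMD.
#' @export
compute_smd <- function(x_treated, x_control, kind = c("auto",
                        "continuous", "factor")) {
  kind <- match.arg(kind)
  if (kind == "auto")
    kind <- if (is.numeric(x_treated) && is.numeric(x_control))
      "continuous" else "factor"
  x_treated <- x_treated[!is.na(x_treated)]
  x_control <- x_control[!is.na(x_control)]
  if (length(x_treated) < 2 || length(x_control) < 2)
    stop("need at least 2 observations per group")
  if (kind == "continuous") {
    s2 <- (var(x_treated) + var(x_control)) / 2
    if (s2 <= 0) {
      warning("zero pooled variance; SMD set to 0")
      return(0)
    }
    return(abs(mean(x_treated) - mean(x_control)) / sqrt(s2))
  }
  lev <- sort(unique(c(as.character(x_treated), as.character(x_control))))
  if (length(lev) < 2) {
    warning("factor with a single level; SMD set to 0")
    return(0)
  }
  pt <- as.vector(table(factor(x_treated, levels = lev))) /
    length(x_treated)
  pc <- as.vector(table(factor(x_control, levels = lev))) /
    length(x_control)
  k <- length(lev) - 1
  d <- (pt - pc)[seq_len(k)]
  covm <- function(p) diag(p[seq_len(k)], k) -
    outer(p[seq_len(k)], p[seq_len(k)])
  S <- (covm(pt) + covm(pc)) / 2
  Sinv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  val <- drop(t(d) %*% Sinv %*% d)
  sqrt(max(val, 0))
}

#' Covariate balance before and after matching
#'
#' Raw SMDs compare all treated to all control limbs; matched SMDs
#' compare the paired subsets.  Prior and interval co-treatment rate
#' differences (treated minus control, as proportions) are reported per
#' treatment for the matched sets.
#'
#' @param cohort cohort data.frame (rows identified by `limb_id`).
#' @param z binary index-treatment indicator aligned with `cohort`.
#' @param pairs data.frame with `treated_id`, `control_id` columns
#'   (limb_ids), e.g. from [solve_match()].
#' @param covariates names of covariate columns to report SMDs for.
#' @param propensity optional propensity vector aligned with `cohort`.
#' @param index_treatment optional name of the index treatment; its own
#'   interval flag (identically 1 vs 0 by construction) is reported as
#'   NA rather than a 100% difference.
#' @return list of class `balance_report`: `smd` (covariate, raw,
#'   matched), `rate_diff` (treatment, prior_diff, interval_diff).
#' @export
balance_report <- function(cohort, z, pairs, covariates,
                           propensity = NULL, index_treatment = NULL) {
  if (nrow(pairs) == 0) stop("empty match set")
  if (!all(c(pairs$treated_id, pairs$control_id) %in% cohort$limb_id))
    stop("pairs reference unknown limb_ids")
  rowz <- match(pairs$treated_id, cohort$limb_id)
  rowc <- match(pairs$control_id, cohort$limb_id)
  coh <- cohort
  if (!is.null(propensity)) {
    coh$.propensity <- propensity
    covariates <- c(covariates, ".propensity")
  }
  smd <- data.frame(covariate = covariates,
                    raw = NA_real_, matched = NA_real_)
  for (i in seq_along(covariates)) {
    v <- coh[[covariates[i]]]
    smd$raw[i] <- compute_smd(v[z == 1], v[z == 0])
    smd$matched[i] <- compute_smd(v[rowz], v[rowc])
  }
  trts <- attr(cohort, "treatments") %||%
    sub("^prior_", "", grep("^prior_", names(cohort), value = TRUE))
  rate <- data.frame(treatment = trts, prior_diff = NA_real_,
                     interval_diff = NA_real_)
  for (i in seq_along(trts)) {
    pcol <- paste0("prior_", trts[i])
    icol <- paste0("ivl_", trts[i])
    if (pcol %in% names(cohort))
      rate$prior_diff[i] <- mean(cohort[[pcol]][rowz]) -
        mean(cohort[[pcol]][rowc])
    if (icol %in% names(cohort) &&
        !identical(trts[i], index_treatment))
      rate$interval_diff[i] <- mean(cohort[[icol]][rowz]) -
        mean(cohort[[icol]][rowc])
  }
  structure(list(smd = smd, rate_diff = rate,
                 n_matched = nrow(pairs)), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report over", x$n_matched, "pairs\n")
  cat(sprintf("  mean SMD raw %.3f -> matched %.3f\n",
              mean(x$smd$raw), mean(x$smd$matched)))
  cat(sprintf("  mean |rate diff| prior %.1f%%, interval %.1f%%\n",
              100 * mean(abs(x$rate_diff$prior_diff), na.rm = TRUE),
              100 * mean(abs(x$rate_diff$interval_diff), na.rm = TRUE)))
  invisible(x)
}
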