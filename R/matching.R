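#' Matching design specification
#'
#' One-to-one optimal-subset matching on Mahalanobis rank distance with a
#' soft propensity caliper, near-fine balance on co-treatment indicators,
#' and optional moment balance on selected means.  Balance requirements
#' enter the objective as per-unit penalties beyond a slack, which also
#' provides a graceful relaxation when exact balance is infeasible.
#'
#' @param distance_covariates covariate names for the rank distance.
#' @param caliper_width propensity caliper in pooled-SD units (pairs
#'   whose propensity gap exceeds it are penalized, not excluded).
#' @param caliper_penalty cost per caliper-width of excess; default
#'   twice the subset weight.
#' @param near_fine names of binary co-treatment columns to balance.
#' @param nf_slack_frac allowed count imbalance as a fraction of the
#'   matched-set size (default 3%, the balance the design targets).
#' @param nf_penalty cost per unit count imbalance beyond slack;
#'   default five times the subset weight.
#' @param moment_covariates covariate names for moment balance
#'   (standardized internally).
#' @param moment_tol allowed |matched mean difference| in pooled-SD
#'   units.
#' @param moment_penalty cost per unit excess; default 100 times the
#'   subset weight.
#' @param subset_weight cost of leaving a treated limb unmatched;
#'   default the median of the distance matrix.
#' @return list of class `match_spec`.
#' @export
match_spec <- function(distance_covariates, caliper_width = 0.2,
                       caliper_penalty = NULL, near_fine = character(0),
                       nf_slack_frac = 0.03, nf_penalty = NULL,
                       moment_covariates = character(0),
                       moment_tol = 0.05, moment_penalty = NULL,
                       subset_weight = NULL) {
  stopifnot(caliper_width > 0, nf_slack_frac >= 0, moment_tol >= 0)
  structure(list(distance_covariates = distance_covariates,
                 caliper_width = caliper_width,
                 caliper_penalty = caliper_penalty,
                 near_fine = near_fine, nf_slack_frac = nf_slack_frac,
                 nf_penalty = nf_penalty,
                 moment_covariates = moment_covariates,
                 moment_tol = moment_tol, moment_penalty = moment_penalty,
                 subset_weight = subset_weight), class = "match_spec")
}

#' Mahalanobis rank distance between treated and control limbs
#'
#' Each covariate is replaced by its rank over the pooled sample (ties
#' get the average rank); distances are Mahalanobis distances on the
#' rank scale using the pooled rank covariance (pseudo-inverse if
#' singular).  Rank transformation makes the distance robust to heavy
#' tails and measurement-scale choices.
#'
#' @param treated,control data.frames of the two groups.
#' @param covariates numeric or ordinal-coded covariate names.
#' @return matrix (treated x control) of distances.
#' @export
mahalanobis_rank_distance <- function(treated, control, covariates) {
  nt <- nrow(treated); nc <- nrow(control)
  if (nt + nc < 3) stop("need at least 3 pooled rows")
  keep <- character(0)
  R <- NULL
  for (v in covariates) {
    x <- c(as.numeric(treated[[v]]), as.numeric(control[[v]]))
    if (length(unique(x)) < 2) {
      warning("dropping constant covariate: ", v)
      next
    }
    keep <- c(keep, v)
    R <- cbind(R, rank(x))
  }
  if (is.null(R)) stop("no usable covariates")
  colnames(R) <- keep
  S <- stats::cov(R)
  Sinv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  Rt <- R[seq_len(nt), , drop = FALSE]
  Rc <- R[nt + seq_len(nc), , drop = FALSE]
  # (a-b)' Sinv (a-b) expanded for all pairs at once
  At <- rowSums((Rt %*% Sinv) * Rt)
  Ac <- rowSums((Rc %*% Sinv) * Rc)
  cross <- Rt %*% Sinv %*% t(Rc)
  D2 <- outer(At, Ac, "+") - 2 * cross
  out <- sqrt(pmax(D2, 0))
  rownames(out) <- rownames(treated)
  colnames(out) <- rownames(control)
  out
}

#' Solve the optimal-subset matching problem
#'
#' Minimizes total pair distance plus caliper penalties plus the subset
#' weight times the number of unmatched treated limbs, subject to soft
#' near-fine-balance and moment-balance penalties.  Small instances are
#' solved exactly by branch and bound; larger ones start from the exact
#' assignment optimum (Hungarian algorithm on a dummy-augmented cost
#' matrix) and are polished by deterministic local search.  The solution
#' is flagged `"optimal"` only when provably so.
#'
#' @param distance treated x control distance matrix (dimnames are used
#'   as limb ids when present).
#' @param spec a [match_spec()].
#' @param propensity optional list with numeric vectors `treated` and
#'   `control` for the caliper.
#' @param co_treatment optional list with 0/1 matrices `treated`,
#'   `control` (columns = co-treatment indicators) for near-fine
#'   balance.
#' @param moments optional list with numeric matrices `treated`,
#'   `control` for moment balance.
#' @return object of class `match_result`: `pairs` (treated_id,
#'   control_id, distance), `objective`, `status`, `matched_frac`,
#'   `subset_weight`.
#' @export
solve_match <- function(distance, spec, propensity = NULL,
                        co_treatment = NULL, moments = NULL) {
  if (!all(is.finite(distance))) stop("distance must be finite")
  Tn <- nrow(distance); Cn <- ncol(distance)
  tid <- rownames(distance) %||% as.character(seq_len(Tn))
  cid <- colnames(distance) %||% as.character(seq_len(Cn))
  subsetw <- spec$subset_weight %||% median(distance)
  cost <- distance
  if (!is.null(propensity)) {
    sdp <- sd(c(propensity$treated, propensity$control))
    if (is.finite(sdp) && sdp > 0) {
      gap <- abs(outer(propensity$treated, propensity$control, "-")) / sdp
      excess <- pmax(0, gap - spec$caliper_width) / spec$caliper_width
      cost <- cost + (spec$caliper_penalty %||% (2 * subsetw)) * excess
    }
  }
  # exact assignment warm start: dummy column per treated = leave unmatched
  big <- cbind(cost, matrix(subsetw, Tn, Tn))
  lsap <- clue::solve_LSAP(big)
  init <- ifelse(as.integer(lsap) <= Cn, as.integer(lsap) - 1L, -1L)
  nm0 <- sum(init >= 0)

  balT <- co_treatment$treated %||% matrix(0L, Tn, 0)
  balC <- co_treatment$control %||% matrix(0L, Cn, 0)
  K <- ncol(balT)
  slack <- rep(ceiling(spec$nf_slack_frac * max(nm0, 1)), K)
  pen <- rep(spec$nf_penalty %||% (5 * subsetw), K)
  momT <- moments$treated %||% matrix(0, Tn, 0)
  momC <- moments$control %||% matrix(0, Cn, 0)
  if (ncol(momT) > 0) {  # standardize to pooled-SD units
    sds <- sapply(seq_len(ncol(momT)), function(j)
      sd(c(momT[, j], momC[, j])))
    sds[!is.finite(sds) | sds == 0] <- 1
    momT <- sweep(momT, 2, sds, "/")
    momC <- sweep(momC, 2, sds, "/")
  }
  mtol <- rep(spec$moment_tol, ncol(momT))
  mpen <- rep(spec$moment_penalty %||% (100 * subsetw), ncol(momT))

  exact <- Tn * log2(Cn + 1) <= 24
  sol <- .solve_match_cpp(cost, subsetw, storage_int(balT, Tn),
                          storage_int(balC, Cn), slack, pen, momT, momC,
                          mtol, mpen, init, exact, 2e7, 200L)
  status <- sol$status
  if (!exact) {
    # the warm start is the assignment optimum; if it already satisfies
    # every balance requirement it is provably globally optimal
    chk <- .solve_match_cpp(cost, subsetw, storage_int(balT, Tn),
                            storage_int(balC, Cn), slack, pen, momT,
                            momC, mtol, mpen, init, FALSE, 0, 0L)
    base_cost <- sum(cost[cbind(which(init >= 0), init[init >= 0] + 1)]) +
      subsetw * sum(init < 0)
    if (abs(chk$objective - base_cost) < 1e-9 &&
        abs(sol$objective - base_cost) < 1e-9)
      status <- "optimal"
  }
  assign <- sol$assign
  mi <- which(assign >= 0)
  pairs <- data.frame(treated_id = tid[mi], control_id = cid[assign[mi] + 1],
                      distance = distance[cbind(mi, assign[mi] + 1)],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, objective = sol$objective,
                 status = status, matched_frac = length(mi) / Tn,
                 subset_weight = subsetw, n_treated = Tn,
                 n_control = Cn, balance = NULL),
            class = "match_result")
}

# coerce a possibly empty matrix to integer storage with n rows
storage_int <- function(m, n) {
  m <- as.matrix(m)
  if (nrow(m) != n) m <- matrix(0L, n, 0)
  storage.mode(m) <- "integer"
  m
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "Match: %d/%d treated matched (%.0f%%), objective %.3f, status %s\n",
    nrow(x$pairs), x$n_treated, 100 * x$matched_frac, x$objective,
    x$status))
  invisible(x)
}

#' High-level direct-matching design for a cohort
#'
#' Builds the rank distance over the spec's covariates, applies the
#' propensity caliper, balances the prior/interval co-treatment flags,
#' solves, and attaches a [balance_report()].
#'
#' @param cohort cohort data.frame with `limb_id`.
#' @param z binary index-treatment vector aligned with `cohort`.
#' @param spec a [match_spec()].
#' @param propensity propensity vector aligned with `cohort`.
#' @param index_treatment optional treatment name, forwarded to
#'   [balance_report()].
#' @return `match_result` with the balance report filled in.
#' @export
direct_match <- function(cohort, z, spec, propensity = NULL,
                         index_treatment = NULL) {
  ti <- which(z == 1); ci <- which(z == 0)
  if (length(ti) == 0 || length(ci) == 0) stop("need both groups")
  tdf <- cohort[ti, , drop = FALSE]
  cdf <- cohort[ci, , drop = FALSE]
  D <- mahalanobis_rank_distance(tdf, cdf, spec$distance_covariates)
  rownames(D) <- cohort$limb_id[ti]
  colnames(D) <- cohort$limb_id[ci]
  prop <- if (!is.null(propensity))
    list(treated = propensity[ti], control = propensity[ci]) else NULL
  bal <- NULL
  nf <- intersect(spec$near_fine, names(cohort))
  if (length(nf) > 0)
    bal <- list(treated = as.matrix(tdf[, nf, drop = FALSE]),
                control = as.matrix(cdf[, nf, drop = FALSE]))
  mom <- NULL
  if (length(spec$moment_covariates) > 0)
    mom <- list(
      treated = as.matrix(tdf[, spec$moment_covariates, drop = FALSE]),
      control = as.matrix(cdf[, spec$moment_covariates, drop = FALSE]))
  res <- solve_match(D, spec, propensity = prop, co_treatment = bal,
                     moments = mom)
  if (nrow(res$pairs) > 0)
    res$balance <- balance_report(cohort, z, res$pairs,
                                  spec$distance_covariates,
                                  propensity = propensity,
                                  index_treatment = index_treatment)
  res
}

#' Summarize the quality of a matching
#'
#' @param result a `match_result` with its balance report attached.
#' @return list: matched percentage, mean raw/matched SMD, mean absolute
#'   prior/interval rate differences (percent).
#' @export
match_quality <- function(result) {
  stopifnot(inherits(result, "match_result"))
  if (nrow(result$pairs) == 0) stop("empty matching")
  b <- result$balance
  if (is.null(b)) stop("match_result carries no balance report")
  list(matched_pct = 100 * result$matched_frac,
       smd = b$smd,
       mean_smd_raw = mean(b$smd$raw),
       mean_smd_matched = mean(b$smd$matched),
       prior_rate_diff_pct = 100 * mean(abs(b$rate_diff$prior_diff),
                                        na.rm = TRUE),
       interval_rate_diff_pct =
         100 * mean(abs(b$rate_diff$interval_diff), na.rm = TRUE),
       status = result$status)
}
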