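#' BART sampler settings
#'
#' Hyperparameters of the sum-of-trees sampler.  The defaults are the
#' standard ones for this model family: 50 trees, depth prior
#' p(split at depth d) = alpha * (1 + d)^-beta with alpha = 0.95, beta = 2,
#' leaf-scale parameter k = 2 (leaf prior SD 0.5 / (k * sqrt(m)) on the
#' internally rescaled outcome), sigma^2 prior with nu = 3 degrees of
#' freedom calibrated so the prior puts probability `q` = 0.9 below the
#' marginal outcome SD, and a grow/prune/change proposal mix of
#' 0.28 / 0.28 / 0.44.
#'
#' @param n_trees number of trees in the ensemble.
#' @param alpha,beta depth-prior base and power.
#' @param k leaf-scale parameter; larger k shrinks leaves harder.
#' @param nu,q sigma^2 prior degrees of freedom and calibration quantile.
#' @param n_burn,n_keep burn-in and retained MCMC iterations.
#' @param prop_probs proposal probabilities for grow, prune, change.
#' @return list of class `bart_params`.
#' @export
bart_params <- function(n_trees = 50, alpha = 0.95, beta = 2, k = 2,
                        nu = 3, q = 0.90, n_burn = 250, n_keep = 1000,
                        prop_probs = c(grow = 0.28, prune = 0.28,
                                       change = 0.44)) {
  stopifnot(n_trees >= 1, alpha > 0, alpha < 1, beta > 0, n_keep >= 1,
            n_burn >= 0, length(prop_probs) == 3,
            abs(sum(prop_probs) - 1) < 1e-8)
  structure(list(n_trees = as.integer(n_trees), alpha = alpha, beta = beta,
                 k = k, nu = nu, q = q, n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep), prop_probs = prop_probs),
            class = "bart_params")
}

#' Fit a BART regression model
#'
#' Bayesian Additive Regression Trees for a continuous outcome.  The
#' outcome is internally rescaled to \[-0.5, 0.5\]; retained draws are
#' mapped back to the original scale.  Factor covariates are one-hot
#' encoded; a literal "Miss" level is an ordinary level.
#'
#' @param X data.frame of covariates (no missing numeric entries).
#' @param y numeric outcome vector, `length(y) == nrow(X)`.
#' @param params a [bart_params()] object.
#' @param X_test optional data.frame scored at every retained draw.
#' @param keep_forest keep the sampled forests so [predict.cp_bart()] can
#'   score new data later (needed unless `X_test` covers all prediction
#'   targets).
#' @return object of class `cp_bart`: retained draws (`sigma`,
#'   `fit_draws`, optionally `test_draws`), posterior mean `yhat_train`,
#'   the training-scale transform, the design schema, and the MH
#'   acceptance rate.
#' @export
fit_bart <- function(X, y, params = bart_params(), X_test = NULL,
                     keep_forest = TRUE) {
  stopifnot(is.data.frame(X), length(y) == nrow(X))
  if (anyNA(y)) stop("y contains missing values")
  des <- build_design(X)
  if (anyNA(des$X)) stop("X contains missing numeric entries")
  ymin <- min(y); ymax <- max(y)
  yrange <- ymax - ymin
  if (yrange <= 0) {  # zero-variance guard: constant y maps to 0 exactly
    yrange <- 1
    ymin <- ymin - 0.5
  }
  ys <- (y - ymin) / yrange - 0.5
  sighat <- sd(ys); if (!is.finite(sighat) || sighat <= 0) sighat <- 1e-6
  lambda <- sighat^2 * qchisq(1 - params$q, params$nu) / params$nu
  sigmu <- 0.5 / (params$k * sqrt(params$n_trees))
  Xt <- if (!is.null(X_test)) apply_design(des$schema, X_test) else NULL
  fit <- .fit_bart_cpp(des$X, ys, logical(nrow(des$X)), FALSE,
                       params$n_trees, params$alpha, params$beta, sigmu,
                       params$nu, lambda, params$n_burn, params$n_keep,
                       params$prop_probs[1], params$prop_probs[2],
                       params$prop_probs[3], Xt, keep_forest)
  back <- function(m) (m + 0.5) * yrange + ymin
  out <- list(sigma = fit$sigma * yrange,
              fit_draws = back(fit$fit),
              test_draws = if (!is.null(Xt)) back(fit$test) else NULL,
              yhat_train = colMeans(back(fit$fit)),
              yhat_test = if (!is.null(Xt)) colMeans(back(fit$test)) else NULL,
              forests = if (keep_forest) fit$forests else NULL,
              center = ymin, scale = yrange, probit = FALSE,
              schema = des$schema, params = params,
              accept_rate = fit$accept_rate)
  class(out) <- "cp_bart"
  out
}

#' Fit a probit BART model for a binary outcome
#'
#' Albert--Chib latent-normal augmentation: the latent outcome is a
#' sum-of-trees regression with sigma fixed at 1, and fitted values map to
#' probabilities through the normal CDF.  Used for propensity scores.
#'
#' @param X data.frame of covariates.
#' @param z binary 0/1 vector.
#' @inheritParams fit_bart
#' @return object of class `cp_bart` with `prob_draws` / `yhat_train` on
#'   the probability scale.
#' @export
fit_bart_probit <- function(X, z, params = bart_params(), X_test = NULL,
                            keep_forest = TRUE) {
  stopifnot(is.data.frame(X), length(z) == nrow(X))
  z <- as.integer(z)
  if (!all(z %in% c(0L, 1L))) stop("z must be binary 0/1")
  if (all(z == 1L) || all(z == 0L))
    stop("degenerate propensity: z is constant")
  des <- build_design(X)
  if (anyNA(des$X)) stop("X contains missing numeric entries")
  sigmu <- 3 / (params$k * sqrt(params$n_trees))
  Xt <- if (!is.null(X_test)) apply_design(des$schema, X_test) else NULL
  fit <- .fit_bart_cpp(des$X, numeric(length(z)), as.logical(z), TRUE,
                       params$n_trees, params$alpha, params$beta, sigmu,
                       params$nu, 1, params$n_burn, params$n_keep,
                       params$prop_probs[1], params$prop_probs[2],
                       params$prop_probs[3], Xt, keep_forest)
  out <- list(sigma = fit$sigma,
              fit_draws = fit$fit,
              prob_draws = pnorm(fit$fit),
              test_draws = if (!is.null(Xt)) pnorm(fit$test) else NULL,
              yhat_train = colMeans(pnorm(fit$fit)),
              yhat_test = if (!is.null(Xt)) colMeans(pnorm(fit$test)) else NULL,
              forests = if (keep_forest) fit$forests else NULL,
              center = 0, scale = 1, probit = TRUE,
              schema = des$schema, params = params,
              accept_rate = fit$accept_rate)
  class(out) <- "cp_bart"
  out
}

#' Posterior predictions from a fitted BART model
#'
#' Scores each retained forest draw on new data.  For probit fits the
#' returned values are probabilities.
#'
#' @param object a `cp_bart` fit with retained forests.
#' @param newdata data.frame matching the training schema.
#' @param ... unused.
#' @return list with `draws` (n_keep x nrow matrix) and `mean`.
#' @export
predict.cp_bart <- function(object, newdata, ...) {
  if (is.null(object$forests) || length(object$forests) == 0)
    stop("fit was run with keep_forest = FALSE")
  Xn <- apply_design(object$schema, newdata)
  draws <- .predict_forest_cpp(object$forests, Xn)
  draws <- if (object$probit) pnorm(draws)
           else (draws + 0.5) * object$scale + object$center
  list(draws = draws, mean = colMeans(draws))
}

#' @export
print.cp_bart <- function(x, ...) {
  cat(sprintf("BART %s fit: %d trees, %d retained draws, MH accept %.2f\n",
              if (x$probit) "probit" else "regression",
              x$params$n_trees, length(x$sigma), x$accept_rate))
  invisible(x)
}

#' Classification metrics for propensity scores
#'
#' Confusion-matrix metrics at a probability threshold plus the rank-based
#' AUC (equivalent to exhaustive counting of concordant
#' positive--negative pairs, ties counted one half).
#'
#' @param scores predicted treatment probabilities.
#' @param z observed binary treatment.
#' @param threshold classification cut-off.
#' @return named vector: accuracy, sensitivity, specificity, auc.
#' @export
evaluate_propensity <- function(scores, z, threshold = 0.5) {
  z <- as.integer(z)
  stopifnot(length(scores) == length(z), all(z %in% 0:1))
  n1 <- sum(z == 1); n0 <- sum(z == 0)
  if (n1 == 0 || n0 == 0) stop("held-out set contains a single class")
  pred <- as.integer(scores >= threshold)
  r <- rank(scores)  # average ranks resolve ties as half-concordant
  auc <- (sum(r[z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(accuracy = mean(pred == z),
    sensitivity = mean(pred[z == 1] == 1),
    specificity = mean(pred[z == 0] == 0),
    auc = auc)
}
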