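#' Weighted proportional-odds ordinal regression
#'
#' Maximizes the weight-multiplied proportional-odds log-likelihood
#' (cumulative logit with a single coefficient vector). Categories that are
#' not observed are merged into their neighbors with a warning, keeping the
#' likelihood well-defined on small cohorts; predictions use the observed
#' category values.
#'
#' @param design a \code{\link{build_design}} result.
#' @param y integer outcome (e.g. pain score 0-10) aligned to
#'   \code{design$rows}' source cohort; only the untrimmed rows are used.
#' @param exclude_intercept ignored columns; the proportional-odds model has
#'   thresholds instead of an intercept.
#' @return object of class \code{outcome_fit} with \code{family =
#'   "ordinal"}, coefficients per design column, thresholds \code{zeta}, and
#'   the observed category values.
#' @export
fit_ordinal <- function(design, y, exclude_intercept = TRUE) {
  yy <- y[design$rows]
  vals <- sort(unique(yy))
  if (length(vals) < 2L) stop_("ordinal outcome has fewer than 2 observed categories")
  full <- seq(min(vals), max(vals))
  if (length(setdiff(full, vals)) > 0)
    warning("unobserved interior categories merged: ",
            paste(setdiff(full, vals), collapse = ", "))
  f <- factor(yy, levels = vals, ordered = TRUE)
  X <- design$X[, -1L, drop = FALSE]   # polr supplies its own thresholds
  if (length(vals) == 2L) {
    # proportional odds with two categories is a plain logistic model
    gf <- stats::glm.fit(design$X, as.numeric(yy == vals[2L]),
                         weights = design$w,
                         family = stats::quasibinomial())
    if (!gf$converged) stop_("ordinal fit did not converge")
    coefs <- gf$coefficients
    zeta <- -coefs[["(Intercept)"]]
    names(zeta) <- paste(vals[1L], vals[2L], sep = "|")
    coefs[["(Intercept)"]] <- 0
    return(structure(list(family = "ordinal", coef = coefs, zeta = zeta,
                          values = vals, converged = TRUE),
                     class = "outcome_fit"))
  }
  df <- data.frame(.y = f, X, check.names = FALSE)
  # polr's internal starting fit uses binomial() and warns on non-integer
  # case weights; the final weighted likelihood is what we check
  fit <- suppressWarnings(
    MASS::polr(.y ~ ., data = df, weights = design$w, Hess = FALSE,
               method = "logistic"))
  if (fit$convergence != 0)
    stop_("ordinal fit did not converge (code %d)", fit$convergence)
  coefs <- c(`(Intercept)` = 0, fit$coefficients)
  structure(list(family = "ordinal", coef = coefs, zeta = fit$zeta,
                 values = vals, converged = TRUE),
            class = "outcome_fit")
}

#' Weighted two-part (hurdle) model for semicontinuous outcomes
#'
#' A weighted logistic regression for the probability of a positive outcome
#' and a weighted least-squares regression of the log outcome on the design
#' for positive values; the log-normal scale is the weighted residual
#' standard deviation (maximum-likelihood denominator). The two components
#' are reported separately and combined only for prediction.
#'
#' @param design a \code{\link{build_design}} result.
#' @param y nonnegative outcome with both zero and positive values among the
#'   untrimmed rows.
#' @return \code{outcome_fit} with \code{family = "hurdle"}: \code{zero_coef}
#'   (logit of P(Y > 0)), \code{pos_coef}, \code{sigma}.
#' @export
fit_hurdle <- function(design, y) {
  yy <- y[design$rows]
  pos <- yy > 0
  if (!any(pos) || all(pos)) stop_("degenerate hurdle: need both zero and positive outcomes")
  zf <- stats::glm.fit(design$X, as.numeric(pos), weights = design$w,
                       family = stats::quasibinomial())
  if (!zf$converged) stop_("hurdle zero-part did not converge")
  pf <- stats::lm.wfit(design$X[pos, , drop = FALSE], log(yy[pos]),
                       design$w[pos])
  wpos <- design$w[pos]
  sigma <- sqrt(sum(wpos * pf$residuals^2) / sum(wpos))
  structure(list(family = "hurdle", zero_coef = zf$coefficients,
                 pos_coef = pf$coefficients, sigma = sigma,
                 converged = TRUE),
            class = "outcome_fit")
}

#' Weighted Cox proportional-hazards fit with a constant-baseline profile
#'
#' Weighted partial likelihood with the Efron approximation for ties (via
#' \code{survival::coxph}). Alongside the semiparametric fit it stores the
#' constant-baseline-hazard profile estimate
#' \deqn{h_0 = \sum w_i d_i / \sum w_i t_i e^{x_i'\beta},}
#' used downstream for expected-event-time prediction.
#'
#' @param design a \code{\link{build_design}} result.
#' @param time positive event/censoring times.
#' @param event 0/1 event indicator; at least one event required.
#' @param ties tie-handling method passed to \code{survival::coxph};
#'   Efron by default. (Exact invariance to splitting rows into fractional
#'   weights holds under \code{"breslow"}; Efron treats the split copies as
#'   a genuine tie.)
#' @return \code{outcome_fit} with \code{family = "cox"}: \code{coef}
#'   (no intercept; proportional hazards), \code{h0}.
#' @export
fit_cox <- function(design, time, event, ties = "efron") {
  tt <- time[design$rows]; ev <- event[design$rows]
  if (any(tt <= 0)) stop_("event times must be positive")
  if (sum(ev) == 0) stop_("all observations censored")
  X <- design$X[, -1L, drop = FALSE]
  df <- data.frame(.t = tt, .e = ev, X, check.names = FALSE)
  fit <- survival::coxph(survival::Surv(.t, .e) ~ ., data = df,
                         weights = design$w, ties = ties)
  beta <- fit$coefficients
  eta <- as.numeric(X %*% beta)
  h0 <- sum(design$w * ev) / sum(design$w * tt * exp(eta))
  coefs <- c(`(Intercept)` = 0, beta)
  structure(list(family = "cox", coef = coefs, h0 = h0, converged = TRUE),
            class = "outcome_fit")
}

#' Weighted logistic regression for binary outcomes
#'
#' @param design a \code{\link{build_design}} result.
#' @param y 0/1 outcome with both classes present among untrimmed rows.
#' @return \code{outcome_fit} with \code{family = "logistic"} and
#'   coefficients per design column.
#' @export
fit_logistic <- function(design, y) {
  yy <- y[design$rows]
  if (length(unique(yy)) < 2L) stop_("binary outcome has a single class")
  fit <- stats::glm.fit(design$X, yy, weights = design$w,
                        family = stats::quasibinomial())
  if (!fit$converged) stop_("logistic fit did not converge")
  if (any(abs(fit$coefficients[-1L]) > 15)) {
    bad <- names(which.max(abs(fit$coefficients[-1L])))
    stop_("possible perfect separation on column '%s'", bad)
  }
  structure(list(family = "logistic", coef = fit$coefficients,
                 converged = TRUE),
            class = "outcome_fit")
}

#' Exponentiated-coefficient effect estimates for the exposure columns
#'
#' Returns exp(beta) per exposure column — an odds ratio per 1 SD of
#' exposure for logit-link families, a hazard ratio for Cox fits (greater
#' hazard predicts a shorter expected event time). Hurdle fits yield two
#' estimates per exposure: the binomial component (odds of a positive
#' outcome) and the log-normal component (multiplicative effect on the
#' positive-part mean). Confidence intervals come from the bootstrap in the
#' counterfactual module, not from Wald approximations.
#'
#' @param fit an \code{outcome_fit}.
#' @param exposures exposure column names (default: columns matching
#'   \code{mean_ce_}).
#' @param outcome optional outcome label carried into the output.
#' @param full report every design column, not only the exposures.
#'   Adjustment-covariate coefficients increase precision but are not
#'   causally interpretable, so they stay behind this flag.
#' @return data.frame: outcome, exposure, component, measure, ratio.
#' @export
effect_estimates <- function(fit, exposures = NULL, outcome = NA_character_,
                             full = FALSE) {
  pick <- function(coefs) {
    nm <- if (full) setdiff(names(coefs), "(Intercept)")
          else if (is.null(exposures))
            grep("^mean_ce_", names(coefs), value = TRUE)
          else exposures
    coefs[nm]
  }
  rows <- switch(fit$family,
    ordinal = {
      b <- pick(fit$coef)
      data.frame(exposure = names(b), component = "ordinal",
                 measure = "OR", ratio = exp(unname(b)))
    },
    logistic = {
      b <- pick(fit$coef)
      data.frame(exposure = names(b), component = "logistic",
                 measure = "OR", ratio = exp(unname(b)))
    },
    cox = {
      b <- pick(fit$coef)
      data.frame(exposure = names(b), component = "cox",
                 measure = "HR", ratio = exp(unname(b)))
    },
    hurdle = {
      bz <- pick(fit$zero_coef); bp <- pick(fit$pos_coef)
      rbind(
        data.frame(exposure = names(bz), component = "binomial",
                   measure = "OR", ratio = exp(unname(bz))),
        data.frame(exposure = names(bp), component = "log-normal",
                   measure = "ratio", ratio = exp(unname(bp))))
    },
    stop_("unknown family '%s'", fit$family))
  rows$outcome <- outcome
  rows[, c("outcome", "exposure", "component", "measure", "ratio")]
}

#' Predicted outcome expectation per patient for any fitted family
#'
#' The family-specific expectation used by g-computation: ordinal, the
#' probability-weighted mean of the observed category values; hurdle,
#' \eqn{P(Y>0) \exp(\mu + \sigma^2/2)}; logistic, the event probability;
#' Cox, the expected event time \eqn{1/(h_0 e^{x'\beta})} under a constant
#' baseline hazard.
#'
#' @param fit an \code{outcome_fit}.
#' @param X design matrix (with intercept column) on the fitted scale.
#' @return numeric vector of expectations.
#' @export
predict_expectation <- function(fit, X) {
  switch(fit$family,
    ordinal = as.numeric(predict_ordinal_probs(fit, X) %*% fit$values),
    hurdle = {
      p <- expit(as.numeric(X %*% fit$zero_coef))
      mu <- as.numeric(X %*% fit$pos_coef)
      p * exp(mu + fit$sigma^2 / 2)
    },
    logistic = expit(as.numeric(X %*% fit$coef)),
    cox = {
      eta <- as.numeric(X %*% fit$coef)
      1 / (fit$h0 * exp(eta))
    },
    stop_("unknown family '%s'", fit$family))
}

#' Predicted ordinal category probabilities
#'
#' @param fit an ordinal \code{outcome_fit}.
#' @param X design matrix with intercept column.
#' @return matrix n x K of category probabilities (rows sum to 1).
#' @export
predict_ordinal_probs <- function(fit, X) {
  stopifnot(fit$family == "ordinal")
  eta <- as.numeric(X %*% fit$coef)
  K <- length(fit$values)
  cum <- vapply(fit$zeta, function(z) expit(z - eta), numeric(length(eta)))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = length(eta))
  cum <- cbind(cum, 1)
  probs <- cum - cbind(0, cum[, -K, drop = FALSE])
  colnames(probs) <- as.character(fit$values)
  probs
}
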