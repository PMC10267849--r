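#' Fit two-part generalized propensity models for semicontinuous exposures
#'
#' Each exposure is bimodal with a point mass at zero, so its conditional
#' density given confounders is modeled in two parts: a logistic regression
#' for the zero indicator and an ordinary least-squares regression of the
#' log positive exposure, with residual standard deviation taken from the
#' residual mean square. Intercept-only marginal counterparts are fitted for
#' weight stabilization.
#'
#' @param cohort cohort data.frame containing the confounder and exposure
#'   columns.
#' @param confounders character vector of confounder column names (at least
#'   two).
#' @param exposures character vector of exposure column names (default the
#'   two \code{mean_ce_*} columns).
#' @return object of class \code{propensity_model}.
#' @export
fit_propensity <- function(cohort, confounders,
                           exposures = grep("^mean_ce_", names(cohort),
                                            value = TRUE)) {
  if (length(confounders) < 1L)
    stop_("at least one confounder is required")
  missing_cols <- setdiff(c(confounders, exposures), names(cohort))
  if (length(missing_cols) > 0)
    stop_("missing columns: %s", paste(missing_cols, collapse = ", "))
  X <- stats::model.matrix(
    stats::reformulate(confounders),
    data = cohort[, confounders, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_("singular confounder design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  fits <- lapply(exposures, function(ex) {
    E <- cohort[[ex]]
    n_zero <- sum(E == 0); n_pos <- sum(E > 0)
    if (n_zero == 0 || n_pos == 0)
      stop_("exposure '%s' must have both zero and positive values for a two-part model", ex)
    z <- as.numeric(E == 0)
    zero_fit <- stats::glm.fit(X, z, family = stats::quasibinomial())
    logE <- log(E[E > 0])
    Xp <- X[E > 0, , drop = FALSE]
    pos_fit <- stats::lm.fit(Xp, logE)
    df <- n_pos - pos_fit$rank
    sigma <- sqrt(sum(pos_fit$residuals^2) / df)
    list(
      exposure = ex,
      zero_coef = zero_fit$coefficients,
      pos_coef = pos_fit$coefficients,
      pos_sigma = sigma,
      marginal = list(
        p_zero = n_zero / length(E),
        mu = mean(logE),
        sd = stats::sd(logE)
      )
    )
  })
  names(fits) <- exposures
  structure(list(fits = fits, confounders = confounders,
                 exposures = exposures, terms = colnames(X)),
            class = "propensity_model")
}

#' Stabilized generalized-propensity weights with percentile trimming
#'
#' The per-exposure stabilized weight is the marginal likelihood of the
#' observed exposure divided by its conditional likelihood given the
#' confounders, where the likelihood is the zero-part probability for a zero
#' exposure and (1 - zero probability) times the log-normal density for a
#' positive one. The combined weight is the product over exposures
#' (appropriate when the exposures are close to independent). Rows whose raw
#' combined weight lies strictly above the empirical trim percentile are
#' flagged and excluded from all subsequent weighted computations.
#'
#' @param model a \code{\link{fit_propensity}} result.
#' @param cohort the cohort the model was fitted on (or a resample of it).
#' @param trim_quantile percentile above which raw weights are discarded
#'   (default 0.995).
#' @return data.frame of class \code{weight_vector} with columns
#'   \code{patient_id}, \code{raw_weight}, \code{weight}, \code{trimmed};
#'   the trim threshold is attached as attribute \code{threshold}.
#' @export
compute_weights <- function(model, cohort, trim_quantile = 0.995) {
  X <- stats::model.matrix(
    stats::reformulate(model$confounders),
    data = cohort[, model$confounders, drop = FALSE])
  X <- X[, model$terms, drop = FALSE]
  raw <- rep(1, nrow(cohort))
  for (ex in model$exposures) {
    f <- model$fits[[ex]]
    E <- cohort[[ex]]
    p_zero <- expit(as.numeric(X %*% f$zero_coef))
    mu_cond <- as.numeric(X %*% f$pos_coef)
    lik_cond <- ifelse(E == 0, p_zero,
                       (1 - p_zero) *
                         stats::dlnorm(pmax(E, .Machine$double.xmin),
                                       mu_cond, f$pos_sigma))
    lik_marg <- ifelse(E == 0, f$marginal$p_zero,
                       (1 - f$marginal$p_zero) *
                         stats::dlnorm(pmax(E, .Machine$double.xmin),
                                       f$marginal$mu, f$marginal$sd))
    if (any(lik_cond < .Machine$double.xmin)) {
      bad <- cohort$patient_id[lik_cond < .Machine$double.xmin]
      stop_("conditional exposure density underflow for patient(s): %s",
            paste(utils::head(bad, 5L), collapse = ", "))
    }
    raw <- raw * lik_marg / lik_cond
  }
  threshold <- stats::quantile(raw, trim_quantile, names = FALSE, type = 7)
  trimmed <- raw > threshold
  out <- data.frame(patient_id = cohort$patient_id, raw_weight = raw,
                    weight = ifelse(trimmed, NA_real_, raw),
                    trimmed = trimmed, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("weight_vector", class(out))
  out
}

#' Weighted Pearson correlation
#'
#' Uses weighted means, variances and covariance; with unit weights it is
#' identical to the unweighted Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param w nonnegative weights.
#' @return correlation in [-1, 1]; \code{NA} if either variable is constant.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw; vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  max(min(cxy / sqrt(vx * vy), 1), -1)
}

#' Weighted Kendall rank correlation (tau-b)
#'
#' Pairwise weights \eqn{w_i w_j} over concordant and discordant pairs, with
#' tau-b tie correction using weighted tie counts. With equal weights this
#' reduces to the standard tau-b.
#'
#' @param x,y numeric vectors.
#' @param w nonnegative weights.
#' @param chunk internal block size for the O(n^2) pair sums.
#' @return correlation in [-1, 1]; \code{NA} if either variable is constant.
#' @export
weighted_kendall <- function(x, y, w = rep(1, length(x)), chunk = 256L) {
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  num <- 0; P <- 0; Tx <- 0; Ty <- 0
  for (i0 in seq(1L, n - 1L, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n - 1L)
    for (i in i0:i1) {
      j <- (i + 1L):n
      ww <- w[i] * w[j]
      sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
      num <- num + sum(ww * sx * sy)
      P <- P + sum(ww)
      Tx <- Tx + sum(ww * (sx == 0))
      Ty <- Ty + sum(ww * (sy == 0))
    }
  }
  den <- sqrt((P - Tx) * (P - Ty))
  if (den <= 0) return(NA_real_)
  max(min(num / den, 1), -1)
}

#' Covariate balance before and after weighting
#'
#' For every covariate (categorical covariates expanded level by level) and
#' every exposure, reports the unweighted correlation over all rows and the
#' weighted correlation over untrimmed rows using final weights. Pearson
#' correlation is used for continuous and binary covariates (point-biserial
#' for binary), the Kendall rank correlation for ordinal ones.
#' Zero-variance covariates are reported as correlation 0 with a flag.
#'
#' @param cohort cohort data.frame (covariate kinds read from the
#'   \code{covariate_kinds} attribute unless supplied).
#' @param weights a \code{\link{compute_weights}} result aligned to
#'   \code{cohort}.
#' @param covariates character vector of covariate columns to report
#'   (default: names of the kinds vector).
#' @param kinds named character vector of covariate kinds.
#' @return data.frame of class \code{balance_table}: columns
#'   \code{covariate}, \code{exposure}, \code{type}, \code{unweighted},
#'   \code{weighted}, \code{zero_variance}.
#' @export
balance_diagnostics <- function(cohort, weights,
                                covariates = names(kinds),
                                kinds = attr(cohort, "covariate_kinds")) {
  if (is.null(kinds)) stop_("covariate kinds are required")
  exposures <- grep("^mean_ce_", names(cohort), value = TRUE)
  keep <- !weights$trimmed
  w <- weights$weight[keep]
  rows <- list()
  add_row <- function(name, xall, type) {
    for (ex in exposures) {
      Eall <- cohort[[ex]]
      zero_var <- stats::var(xall) == 0
      if (zero_var) {
        un <- 0; we <- 0
      } else if (type == "kendall") {
        un <- weighted_kendall(xall, Eall)
        we <- weighted_kendall(xall[keep], Eall[keep], w)
      } else {
        un <- weighted_pearson(xall, Eall)
        we <- weighted_pearson(xall[keep], Eall[keep], w)
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        covariate = name, exposure = ex, type = type,
        unweighted = un, weighted = we, zero_variance = zero_var,
        stringsAsFactors = FALSE)
    }
  }
  for (cv in covariates) {
    kind <- kinds[[cv]]
    if (kind == "categorical") {
      for (lev in levels(factor(cohort[[cv]]))) {
        add_row(paste0(cv, ":", lev),
                as.numeric(as.character(cohort[[cv]]) == lev), "pearson")
      }
    } else if (kind == "ordinal") {
      add_row(cv, as.numeric(cohort[[cv]]), "kendall")
    } else {
      add_row(cv, as.numeric(cohort[[cv]]), "pearson")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("balance_table", class(out))
  out
}
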