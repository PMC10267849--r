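#' Synthetic cohort generator configuration
#'
#' Returns the full ground-truth configuration used by the synthetic-cohort
#' generator: covariate specifications (kind, role, distribution), the
#' two-part exposure model per drug (zero-probability logit, positive-part
#' log-linear dose model, bolus-timing profile), the exposure-window
#' distribution, PK parameter sets, and the outcome truth for all four
#' outcome families. All coefficients are on the raw covariate scale.
#'
#' The defaults emulate the reported structure of a large perioperative
#' cohort: bimodal exposures with a point mass at zero (7.3\% zero fentanyl,
#' 36.4\% zero hydromorphone), near-independent dual exposures, front-loaded
#' fentanyl versus uniformly timed hydromorphone boluses, and outcomes from
#' ordinal, hurdle, time-to-event and binary families. The
#' \code{"strong"} confounding preset narrows the confounder set to three
#' continuous/binary covariates and amplifies their effects on both
#' exposures, for diagnostics that require severe baseline imbalance.
#'
#' @param confounding \code{"moderate"} (default, realistic) or
#'   \code{"strong"}.
#' @return a list; see fields in source. Pass to
#'   \code{\link{generate_cohort}}.
#' @export
generator_config <- function(confounding = c("moderate", "strong")) {
  confounding <- match.arg(confounding)

  covariates <- list(
    list(name = "age", kind = "continuous", role = "confounder",
         dist = "normal", args = list(mean = 55.44, sd = 17.08,
                                      min = 18, max = 95)),
    list(name = "bmi", kind = "continuous", role = "confounder",
         dist = "lognormal", args = list(meanlog = log(27.26), sdlog = 0.21,
                                         min = 14, max = 60)),
    list(name = "female", kind = "binary", role = "confounder",
         dist = "bernoulli", args = list(p = 0.535)),
    list(name = "asa", kind = "ordinal", role = "confounder",
         dist = "ordinal", args = list(probs = c(0.1135, 0.5880, 0.2842,
                                                 0.0144))),
    list(name = "service", kind = "categorical", role = "confounder",
         dist = "categorical",
         args = list(levels = c("other", "orthopedic", "general", "urology",
                                "gynecology", "plastic"),
                     probs = c(0.2773, 0.2291, 0.1721, 0.1403, 0.1009,
                               0.0803))),
    list(name = "opioid_naive", kind = "binary", role = "adjustment",
         dist = "bernoulli", args = list(p = 0.807)),
    list(name = "morbidity_score", kind = "continuous", role = "adjustment",
         dist = "normal", args = list(mean = 33.45, sd = 19.02,
                                      min = 0, max = 100))
  )

  if (confounding == "moderate") {
    drugs <- list(
      fentanyl = list(
        zero = list(target = 0.073,
                    slopes = c(age = 0.012, asa = 0.25, female = 0.15)),
        pos = list(intercept = 4.70,
                   slopes = c(age = -0.006, bmi = 0.012, female = -0.12,
                              asa = -0.10, `service:orthopedic` = -0.10),
                   tau = 0.35),
        timing = "front", bolus_range = c(1L, 5L)),
      hydromorphone = list(
        zero = list(target = 0.364,
                    slopes = c(age = 0.018, asa = 0.30,
                               `service:orthopedic` = -0.60)),
        pos = list(intercept = 6.15,
                   slopes = c(age = -0.008, bmi = 0.010, asa = 0.12,
                              `service:orthopedic` = 0.25),
                   tau = 0.45),
        timing = "uniform", bolus_range = c(1L, 5L))
    )
  } else {
    # Severe confounding: age drives fentanyl, female drives hydromorphone,
    # each explaining ~15% of that drug's log-exposure variance. Keeping
    # the explained share well below half the marginal variance keeps the
    # stabilized weights at finite variance (the ratio of a wide marginal
    # to a narrow conditional normal density has infinite second moment
    # once sigma_marg^2 > 2 sigma_cond^2, and no sample size rescues the
    # balance diagnostics then); confounding each drug through its own
    # covariate avoids compounding weight tails in the per-drug product.
    # Bolus times sit at fixed quantiles of the timing profile so the
    # exposure stays conditionally log-normal; remaining covariates are
    # adjustment-only.
    covariates <- lapply(covariates, function(cv) {
      cv$role <- if (cv$name %in% c("age", "female")) "confounder"
                 else "adjustment"
      cv
    })
    drugs <- list(
      fentanyl = list(
        zero = list(target = 0.073,
                    slopes = c(age = 0.030)),
        pos = list(intercept = 4.70,
                   slopes = c(age = -0.0101),
                   tau = 0.40),
        timing = "front", timing_quantiles = TRUE,
        bolus_range = c(1L, 5L)),
      hydromorphone = list(
        zero = list(target = 0.364,
                    slopes = c(female = 1.4)),
        pos = list(intercept = 6.15,
                   slopes = c(female = -0.30),
                   tau = 0.40),
        timing = "uniform", timing_quantiles = TRUE,
        timing_range = c(0.05, 0.70), bolus_range = c(1L, 5L))
    )
  }

  window <- if (confounding == "strong") {
    # tight windows keep timing/duration noise a small share of the
    # conditional exposure variance
    list(meanlog = log(90), sdlog = 0.12, min = 20)
  } else {
    list(meanlog = log(90), sdlog = 0.40, min = 20)
  }

  outcomes <- list(
    pacu_max_pain = list(
      family = "ordinal",
      beta_exposure = c(fentanyl = -0.9, hydromorphone = -0.35),
      beta_cov = c(age = -0.012, female = 0.30, asa = 0.20,
                   opioid_naive = -0.25),
      thresholds = c(-2.4, -1.8, -1.3, -0.8, -0.3, 0.2, 0.8, 1.5, 2.3, 3.3)),
    pacu_total_mme = list(
      family = "hurdle",
      zero = list(intercept = -1.1,
                  beta_exposure = c(fentanyl = 0.5, hydromorphone = 0.3),
                  beta_cov = c(age = 0.010, asa = 0.10)),
      intercept = 2.0,
      beta_exposure = c(fentanyl = -0.30, hydromorphone = -0.20),
      beta_cov = c(age = -0.004, female = 0.10, opioid_naive = -0.15),
      sigma = 0.8),
    pacu_los_min = list(
      family = "cox",
      h0 = 1 / 90,
      beta_exposure = c(fentanyl = -0.10, hydromorphone = 0.10),
      beta_cov = c(age = -0.004, asa = -0.10),
      censor_horizon = 600),
    uncontrolled_pain_24h = list(
      family = "binary",
      intercept = -1.2,
      beta_exposure = c(fentanyl = -0.50, hydromorphone = 0.10),
      beta_cov = c(age = -0.006, female = 0.20, asa = 0.15,
                   opioid_naive = -0.20))
  )

  list(
    covariates = covariates,
    drugs = drugs,
    window = window,
    pk = default_pk_parameters(),
    dt = 0.5,
    outcomes = outcomes,
    confounding = confounding
  )
}

#' Names of covariates by declared role
#' @param config generator configuration.
#' @return character vector.
#' @export
confounder_names <- function(config) {
  vapply(Filter(function(cv) cv$role == "confounder", config$covariates),
         `[[`, character(1), "name")
}

#' @rdname confounder_names
#' @export
adjustment_names <- function(config) {
  vapply(Filter(function(cv) cv$role == "adjustment", config$covariates),
         `[[`, character(1), "name")
}

#' Declared covariate kinds
#' @param config generator configuration.
#' @return named character vector (continuous/binary/ordinal/categorical).
#' @export
covariate_kinds <- function(config) {
  kinds <- vapply(config$covariates, `[[`, character(1), "kind")
  names(kinds) <- vapply(config$covariates, `[[`, character(1), "name")
  kinds
}

#' Generate baseline covariates
#'
#' Draws each covariate from its declared distribution. Reproducible given
#' the seed; the same seed yields the identical table.
#'
#' @param n number of patients.
#' @param config generator configuration.
#' @param seed integer seed.
#' @return data.frame with \code{patient_id} and one column per covariate.
#' @export
generate_covariates <- function(n, config, seed) {
  set.seed(seed)
  out <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (cv in config$covariates) {
    a <- cv$args
    x <- switch(cv$dist,
      normal = {
        v <- stats::rnorm(n, a$mean, a$sd)
        pmin(pmax(v, a$min %||% -Inf), a$max %||% Inf)
      },
      lognormal = {
        v <- stats::rlnorm(n, a$meanlog, a$sdlog)
        pmin(pmax(v, a$min %||% 0), a$max %||% Inf)
      },
      bernoulli = stats::rbinom(n, 1L, a$p),
      ordinal = sample.int(length(a$probs), n, replace = TRUE,
                           prob = a$probs),
      categorical = factor(sample(a$levels, n, replace = TRUE,
                                  prob = a$probs), levels = a$levels),
      stop_("unknown distribution '%s' for covariate '%s'", cv$dist, cv$name)
    )
    out[[cv$name]] <- x
  }
  attr(out, "covariate_kinds") <- covariate_kinds(config)
  out
}

# Solve the zero-part intercept so the average zero probability over the
# realized covariate sample equals the target marginal fraction.
calibrate_zero_intercept <- function(z, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(c0) mean(expit(c0 + z)) - target,
                 interval = c(-40, 40), tol = 1e-10)$root
}

#' Generate intraoperative dosing records
#'
#' Per patient and drug: no dose with probability
#' \code{expit(c0 + x'gamma0)} (the intercept \code{c0} calibrated so the
#' marginal zero fraction matches the configured target); otherwise a total
#' dose drawn log-normally from the covariate-dependent location, split into
#' 1-5 equal boluses whose times follow the drug's timing profile
#' (Beta(1,3)-scaled for front-loaded drugs, uniform otherwise). Exposure
#' windows are log-normal in length and start at minute 0.
#'
#' @param covariates covariate table from \code{\link{generate_covariates}}.
#' @param config generator configuration.
#' @param seed integer seed.
#' @return list with \code{records} (list of \code{\link{dosing_record}}),
#'   \code{windows} (data.frame), and \code{zero_intercepts} (calibrated
#'   values per drug).
#' @export
generate_dosing <- function(covariates, config, seed) {
  set.seed(seed)
  n <- nrow(covariates)
  wl <- pmax(config$window$min,
             stats::rlnorm(n, config$window$meanlog, config$window$sdlog))
  windows <- data.frame(patient_id = covariates$patient_id,
                        window_start_min = 0, window_end_min = wl,
                        stringsAsFactors = FALSE)
  ev_list <- replicate(n, list(time = numeric(0), dose = numeric(0),
                               drug = character(0)), simplify = FALSE)
  zero_intercepts <- numeric(0)
  for (drug in names(config$drugs)) {
    m <- config$drugs[[drug]]
    z0 <- linear_predictor(covariates, m$zero$slopes)
    c0 <- if (!is.null(m$zero$intercept)) m$zero$intercept
          else calibrate_zero_intercept(z0, m$zero$target)
    zero_intercepts[drug] <- c0
    p_zero <- expit(c0 + z0)
    is_zero <- stats::rbinom(n, 1L, p_zero) == 1L
    mu <- m$pos$intercept + linear_predictor(covariates, m$pos$slopes)
    total <- stats::rlnorm(n, mu, m$pos$tau)
    nb <- sample(seq.int(m$bolus_range[1L], m$bolus_range[2L]), n,
                 replace = TRUE)
    rng <- m$timing_range %||% c(0.05, 0.85)
    deterministic <- isTRUE(m$timing_quantiles)
    for (i in seq_len(n)) {
      if (is_zero[i]) next
      k <- nb[i]
      frac <- if (deterministic) {
        # bolus times at fixed quantiles of the profile: removes timing
        # noise from the exposure while keeping the profile's shape
        q <- (seq_len(k) - 0.5) / k
        if (identical(m$timing, "front")) stats::qbeta(q, 1, 3)
        else rng[1L] + diff(rng) * q
      } else if (identical(m$timing, "front")) {
        stats::rbeta(k, 1, 3)
      } else {
        rng[1L] + diff(rng) * stats::runif(k)
      }
      tms <- sort(frac * wl[i])
      ev_list[[i]]$time <- c(ev_list[[i]]$time, tms)
      ev_list[[i]]$dose <- c(ev_list[[i]]$dose, rep(total[i] / k, k))
      ev_list[[i]]$drug <- c(ev_list[[i]]$drug, rep(drug, k))
    }
  }
  records <- lapply(seq_len(n), function(i) {
    ev <- data.frame(time = ev_list[[i]]$time, dose = ev_list[[i]]$dose,
                     drug = ev_list[[i]]$drug, stringsAsFactors = FALSE)
    dosing_record(covariates$patient_id[i], ev, 0, wl[i])
  })
  list(records = records, windows = windows,
       zero_intercepts = zero_intercepts)
}

#' Generate outcomes from known ground truth
#'
#' Conditions on window-mean effect-site exposures (not raw traces) and the
#' covariates. Families: ordinal (latent-logistic score cut at strictly
#' increasing thresholds), hurdle (zero with its own logit probability, else
#' log-normal), time-to-event (exponential with rate \code{h0 exp(eta)},
#' administrative censoring at the configured horizon), binary (Bernoulli
#' with logit link).
#'
#' @param covariates covariate table.
#' @param exposures data.frame with \code{mean_ce_<drug>} columns.
#' @param config generator configuration.
#' @param seed integer seed.
#' @return data.frame of outcome columns (time-to-event outcomes add an
#'   \code{_event} flag column).
#' @export
generate_outcomes <- function(covariates, exposures, config, seed) {
  set.seed(seed)
  n <- nrow(covariates)
  exposure_eta <- function(beta_exposure) {
    eta <- numeric(n)
    for (drug in names(beta_exposure)) {
      col <- paste0("mean_ce_", drug)
      if (!col %in% names(exposures)) stop_("missing exposure column '%s'", col)
      eta <- eta + beta_exposure[[drug]] * exposures[[col]]
    }
    eta
  }
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(config$outcomes)) {
    o <- config$outcomes[[nm]]
    if (is.null(o$family)) stop_("outcome '%s' lacks a family", nm)
    eta <- exposure_eta(o$beta_exposure) +
      linear_predictor(covariates, o$beta_cov)
    if (o$family == "ordinal") {
      if (is.null(o$thresholds) || is.unsorted(o$thresholds, strictly = TRUE))
        stop_("ordinal outcome '%s' needs strictly increasing thresholds", nm)
      latent <- eta + stats::rlogis(n)
      out[[nm]] <- rowSums(outer(latent, o$thresholds, `>`))
    } else if (o$family == "hurdle") {
      if (is.null(o$zero) || is.null(o$sigma))
        stop_("hurdle outcome '%s' needs zero-part truth and sigma", nm)
      eta0 <- (o$zero$intercept %||% 0) + exposure_eta(o$zero$beta_exposure) +
        linear_predictor(covariates, o$zero$beta_cov)
      is_zero <- stats::rbinom(n, 1L, expit(eta0)) == 1L
      y <- exp(stats::rnorm(n, (o$intercept %||% 0) + eta, o$sigma))
      y[is_zero] <- 0
      out[[nm]] <- y
    } else if (o$family == "cox") {
      if (is.null(o$h0) || o$h0 <= 0) stop_("cox outcome '%s' needs h0 > 0", nm)
      tt <- stats::rexp(n) / (o$h0 * exp(eta))
      horizon <- o$censor_horizon %||% Inf
      out[[nm]] <- pmin(tt, horizon)
      out[[paste0(nm, "_event")]] <- as.integer(tt <= horizon)
    } else if (o$family == "binary") {
      out[[nm]] <- stats::rbinom(n, 1L, expit((o$intercept %||% 0) + eta))
    } else {
      stop_("unknown outcome family '%s'", o$family)
    }
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Chains covariate, dosing, exposure and outcome generation: exposures in
#' the returned cohort table are computed from the generated dosing records
#' through the PK module, so they round-trip exactly. Fully deterministic
#' given the master seed.
#'
#' @param n number of patients.
#' @param config generator configuration from \code{\link{generator_config}}.
#' @param seed master integer seed.
#' @return list with \code{cohort} (covariates + exposures + outcomes, with
#'   covariate kinds and roles attached as attributes), \code{records},
#'   \code{windows}, \code{truth} (config echo including calibrated
#'   zero intercepts).
#' @export
generate_cohort <- function(n, config = generator_config(), seed = 1L) {
  covariates <- generate_covariates(n, config, seed)
  dosing <- generate_dosing(covariates, config, seed + 1L)
  exposures <- compute_exposures(dosing$records, config$pk, dt = config$dt)
  outcomes <- generate_outcomes(covariates, exposures, config, seed + 2L)
  cohort <- cbind(covariates,
                  exposures[match(covariates$patient_id,
                                  exposures$patient_id), -1, drop = FALSE],
                  outcomes)
  rownames(cohort) <- NULL
  attr(cohort, "covariate_kinds") <- covariate_kinds(config)
  attr(cohort, "confounders") <- confounder_names(config)
  attr(cohort, "adjustment") <- adjustment_names(config)
  truth <- config
  truth$zero_intercepts <- dosing$zero_intercepts
  list(cohort = cohort, records = dosing$records, windows = dosing$windows,
       truth = truth)
}
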