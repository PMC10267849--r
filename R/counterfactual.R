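#' An incremental-dose intervention
#'
#' @param drug drug label to intervene on.
#' @param dose incremental bolus dose in micrograms; must be positive.
#' @param time_policy where the counterfactual bolus is inserted:
#'   \code{"window-start"} (default), \code{"window-mid"}, or a numeric time
#'   in minutes.
#' @return object of class \code{intervention}.
#' @export
intervention <- function(drug, dose, time_policy = "window-start") {
  if (!is.numeric(dose) || dose <= 0) stop_("intervention dose must be positive")
  structure(list(drug = drug, dose = dose, time_policy = time_policy),
            class = "intervention")
}

insertion_time <- function(policy, ws, we) {
  t <- if (identical(policy, "window-start")) ws
       else if (identical(policy, "window-mid")) (ws + we) / 2
       else as.numeric(policy)
  if (t < ws || t > we)
    stop_("insertion time %g outside exposure window [%g, %g]", t, ws, we)
  t
}

#' Observed and counterfactual exposures under an incremental dose
#'
#' For each patient, adds one bolus of the intervention dose at the policy
#' time, re-runs the effect-site simulation and window averaging, and
#' returns the (observed, counterfactual) exposure pair for the intervened
#' drug. By linearity of the PK system the added bolus's contribution is
#' computed by simulating it alone on the patient's window; the
#' counterfactual exposure is the observed exposure plus that increment, so
#' it is never below the observed value and the other drug is untouched.
#'
#' @param records list of \code{\link{dosing_record}}.
#' @param intv an \code{\link{intervention}}.
#' @param pk named list of PK parameter sets.
#' @param dt simulation grid interval (min).
#' @param observed optional precomputed exposure data.frame (from
#'   \code{\link{compute_exposures}}); recomputed if omitted.
#' @return data.frame: patient_id, observed, counterfactual, increment.
#' @export
apply_intervention <- function(records, intv, pk, dt = 0.1, observed = NULL) {
  if (!intv$drug %in% names(pk))
    stop_("no PK parameters for drug '%s'", intv$drug)
  col <- paste0("mean_ce_", intv$drug)
  if (is.null(observed)) observed <- compute_exposures(records, pk, dt = dt)
  obs <- observed[[col]][match(vapply(records, `[[`, character(1),
                                      "patient_id"),
                               observed$patient_id)]
  basis <- pk_impulse_basis(pk[[intv$drug]])
  inc <- vapply(records, function(r) {
    t_ins <- insertion_time(intv$time_policy, r$window_start, r$window_end)
    if (basis$analytic) {
      times <- pk_time_grid(r$window_end, dt)
      Ce <- state_on_grid(times, t_ins, intv$dose, basis$lam, basis$r4)
      window_mean_on_grid(times, Ce, r$window_start, r$window_end)
    } else {
      one <- dosing_record(r$patient_id,
                           bolus_event(t_ins, intv$dose, intv$drug),
                           r$window_start, r$window_end)
      tr <- simulate_effect_site(one, pk[[intv$drug]], dt = dt)
      mean_window_concentration(tr, r$window_start, r$window_end)
    }
  }, numeric(1))
  data.frame(patient_id = vapply(records, `[[`, character(1), "patient_id"),
             observed = obs, counterfactual = obs + inc, increment = inc,
             stringsAsFactors = FALSE)
}

#' Population-mean expected outcome change under an intervention
#'
#' g-computation on the unweighted study population: every patient's outcome
#' expectation is predicted under the observed and the counterfactual
#' exposure with all other covariates fixed, and the difference is averaged
#' over all patients (including trimmed ones). Binary outcomes are reported
#' per 1000 patients. Counterfactual exposures beyond an extrapolation guard
#' (default 1.5 times the observed maximum) trigger a warning.
#'
#' @param fit an \code{outcome_fit}.
#' @param meta design metadata from \code{\link{build_design}}.
#' @param pairs exposure pairs from \code{\link{apply_intervention}}.
#' @param cohort the full cohort (all rows).
#' @param intv the \code{\link{intervention}} (for labeling).
#' @param outcome outcome label.
#' @param guard extrapolation guard multiplier.
#' @return one-row data.frame of class \code{counterfactual_result}:
#'   outcome, family, drug, dose, mean change (absolute, outcome units; per
#'   1000 for binary), baseline predicted mean, percent change.
#' @export
predict_mean_change <- function(fit, meta, pairs, cohort, intv,
                                outcome = NA_character_, guard = 1.5) {
  col <- paste0("mean_ce_", intv$drug)
  stopifnot(col %in% names(meta$columns))
  cf <- pairs$counterfactual[match(cohort$patient_id, pairs$patient_id)]
  if (anyNA(cf)) stop_("exposure pairs do not cover the cohort")
  if (max(cf) > guard * max(cohort[[col]]))
    warning("counterfactual exposure exceeds ", guard,
            "x the observed maximum; extrapolation beyond support")
  X_obs <- apply_design(meta, cohort)
  X_cf <- apply_design(meta, cohort,
                       exposure_override = stats::setNames(list(cf), col))
  mu_obs <- predict_expectation(fit, X_obs)
  mu_cf <- predict_expectation(fit, X_cf)
  scale <- if (fit$family == "logistic") 1000 else 1
  baseline <- mean(mu_obs) * scale
  change <- mean(mu_cf - mu_obs) * scale
  pct <- if (baseline != 0) 100 * change / baseline else NA_real_
  out <- data.frame(outcome = outcome, family = fit$family,
                    drug = intv$drug, dose = intv$dose,
                    change = change, baseline = baseline, percent = pct,
                    stringsAsFactors = FALSE)
  class(out) <- c("counterfactual_result", class(out))
  out
}

fit_one_outcome <- function(design, cohort_rows, spec) {
  y <- cohort_rows[[spec$column]]
  switch(spec$family,
    ordinal = fit_ordinal(design, y),
    hurdle = fit_hurdle(design, y),
    logistic = ,
    binary = fit_logistic(design, y),
    cox = fit_cox(design, y, cohort_rows[[paste0(spec$column, "_event")]]),
    stop_("unknown family '%s'", spec$family))
}

#' Full counterfactual analysis with percentile bootstrap CIs
#'
#' Runs the complete inference chain — propensity fitting, stabilized
#' weights with trimming, design standardization, weighted outcome fits,
#' and g-computation — on the cohort, then repeats it on \code{B}
#' patient-level resamples with replacement to form percentile 2.5/97.5
#' confidence bounds for both the absolute and the percent change.
#' Replicates whose model fits fail are dropped and counted; more than 10
#' percent failures aborts. Deterministic given the seed.
#'
#' @param cohort cohort data.frame (with kind/role attributes).
#' @param pairs exposure pairs from \code{\link{apply_intervention}} for the
#'   intervention of interest (patient-level; resamples reuse them).
#' @param outcomes named list of outcome specs: each
#'   \code{list(column, family)}.
#' @param intv the \code{\link{intervention}}.
#' @param confounders confounder column names.
#' @param adjustment adjustment covariate names entered into outcome models.
#' @param B bootstrap replicates (default 200); \code{B = 0} disables the
#'   bootstrap and returns point estimates with degenerate CIs.
#' @param seed integer seed for the resampling.
#' @param trim_quantile weight-trimming percentile.
#' @return data.frame, one row per outcome: point estimates plus CI bounds
#'   (\code{change_lo}, \code{change_hi}, \code{percent_lo},
#'   \code{percent_hi}), \code{n_boot} successful replicates.
#' @export
bootstrap_counterfactual <- function(cohort, pairs, outcomes, intv,
                                     confounders = attr(cohort, "confounders"),
                                     adjustment = attr(cohort, "adjustment"),
                                     B = 200L, seed = 1L,
                                     trim_quantile = 0.995) {
  kinds <- attr(cohort, "covariate_kinds")
  run_once <- function(co, prs) {
    pm <- fit_propensity(co, confounders)
    wt <- compute_weights(pm, co, trim_quantile = trim_quantile)
    des <- build_design(co, wt, adjustment_vars = c(confounders, adjustment),
                        kinds = kinds)
    do.call(rbind, lapply(names(outcomes), function(nm) {
      spec <- outcomes[[nm]]
      fit <- fit_one_outcome(des, co, spec)
      suppressWarnings(
        predict_mean_change(fit, des$meta, prs, co, intv, outcome = nm))
    }))
  }
  point <- run_once(cohort, pairs)

  if (B < 1) {
    point$change_lo <- point$change; point$change_hi <- point$change
    point$percent_lo <- point$percent; point$percent_hi <- point$percent
    point$n_boot <- 0L
    return(point)
  }
  set.seed(seed)
  n <- nrow(cohort)
  boots <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    co_b <- cohort[idx, , drop = FALSE]
    co_b$patient_id <- sprintf("B%07d", seq_len(n))
    attributes(co_b)$covariate_kinds <- kinds
    prs_b <- pairs[idx, , drop = FALSE]
    prs_b$patient_id <- co_b$patient_id
    boots[[b]] <- tryCatch(run_once(co_b, prs_b),
                           error = function(e) NULL)
    if (is.null(boots[[b]])) failed <- failed + 1L
  }
  if (failed > 0.10 * B)
    stop_("bootstrap failure rate %.0f%% exceeds 10%%", 100 * failed / B)
  ok <- Filter(Negate(is.null), boots)
  for (i in seq_len(nrow(point))) {
    ch <- vapply(ok, function(b) b$change[i], numeric(1))
    pc <- vapply(ok, function(b) b$percent[i], numeric(1))
    qs <- stats::quantile(ch, c(0.025, 0.975), names = FALSE)
    qp <- stats::quantile(pc, c(0.025, 0.975), names = FALSE)
    point$change_lo[i] <- qs[1]; point$change_hi[i] <- qs[2]
    point$percent_lo[i] <- qp[1]; point$percent_hi[i] <- qp[2]
  }
  point$n_boot <- length(ok)
  point
}
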