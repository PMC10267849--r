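#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate (or load) -> exposures -> propensity weighting ->
#' weighted outcome fits -> counterfactual g-computation, and writes the
#' three headline tables plus a run manifest to \code{out_dir}:
#' \itemize{
#'   \item \code{cohort.csv}, \code{dosing.csv}, \code{windows.csv} — the
#'     analysis inputs (written when generated here);
#'   \item \code{balance.csv} — covariate/exposure correlations before and
#'     after weighting;
#'   \item \code{forest.csv} — exponentiated exposure coefficients per
#'     outcome and component;
#'   \item \code{table_counterfactual.csv} — mean expected outcome change
#'     (absolute and percent) per intervention with bootstrap CIs;
#'   \item \code{manifest.json} — seeds, sizes, trimmed and dropped-row
#'     counts, package version.
#' }
#' A rerun with the same configuration reproduces identical outputs.
#'
#' @param config list with elements: \code{n} (patients), \code{seed},
#'   \code{out_dir}; optional \code{confounding} preset, \code{generator}
#'   (full generator config overriding the preset), \code{B} (bootstrap
#'   replicates, default 200), \code{trim_quantile} (default 0.995),
#'   \code{interventions} (list of \code{\link{intervention}}; default
#'   fentanyl +100 ug and hydromorphone +500 ug), \code{row_filter}
#'   (character expression evaluated in the cohort for subgroup reruns,
#'   e.g. \code{"bmi > 30"}).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$n), !is.null(config$seed),
            !is.null(config$out_dir))
  trim_q <- config$trim_quantile %||% 0.995
  if (trim_q <= 0.5 || trim_q >= 1)
    stop_("trim percentile must be in (50, 100)")
  B <- config$B %||% 200L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gen_cfg <- config$generator %||%
    generator_config(config$confounding %||% "moderate")
  sim <- generate_cohort(config$n, gen_cfg, seed = config$seed)
  cohort <- sim$cohort
  records <- sim$records

  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  write_dosing_csv(records, file.path(out_dir, "dosing.csv"),
                   file.path(out_dir, "windows.csv"))

  # subgroup rerun support: keep only rows matching the filter expression
  n_filtered <- 0L
  if (!is.null(config$row_filter)) {
    keep <- eval(parse(text = config$row_filter), envir = cohort)
    n_filtered <- sum(!keep)
    atts <- attributes(cohort)
    cohort <- cohort[keep, , drop = FALSE]
    attr(cohort, "covariate_kinds") <- atts$covariate_kinds
    attr(cohort, "confounders") <- atts$confounders
    attr(cohort, "adjustment") <- atts$adjustment
    records <- records[keep]
  }

  # complete-case analysis: drop and count rows with missing analysis fields
  cc <- stats::complete.cases(cohort)
  n_incomplete <- sum(!cc)
  if (n_incomplete > 0) {
    atts <- attributes(cohort)
    cohort <- cohort[cc, , drop = FALSE]
    attr(cohort, "covariate_kinds") <- atts$covariate_kinds
    attr(cohort, "confounders") <- atts$confounders
    attr(cohort, "adjustment") <- atts$adjustment
    records <- records[cc]
  }

  confounders <- attr(cohort, "confounders")
  adjustment <- attr(cohort, "adjustment")
  pm <- fit_propensity(cohort, confounders)
  wt <- compute_weights(pm, cohort, trim_quantile = trim_q)
  bal <- balance_diagnostics(cohort, wt,
                             covariates = c(confounders, adjustment))
  utils::write.csv(bal, file.path(out_dir, "balance.csv"),
                   row.names = FALSE)

  des <- build_design(cohort, wt,
                      adjustment_vars = c(confounders, adjustment))
  outcome_specs <- lapply(names(gen_cfg$outcomes), function(nm)
    list(column = nm, family = gen_cfg$outcomes[[nm]]$family))
  names(outcome_specs) <- names(gen_cfg$outcomes)

  fits <- lapply(outcome_specs, function(spec)
    fit_one_outcome(des, cohort, spec))
  forest <- do.call(rbind, lapply(names(fits), function(nm)
    effect_estimates(fits[[nm]], outcome = nm)))
  utils::write.csv(forest, file.path(out_dir, "forest.csv"),
                   row.names = FALSE)

  intvs <- config$interventions %||% list(
    intervention("fentanyl", 100),
    intervention("hydromorphone", 500))
  observed <- cohort[, c("patient_id",
                         grep("^mean_ce_", names(cohort), value = TRUE))]
  cf_tables <- lapply(seq_along(intvs), function(k) {
    iv <- intvs[[k]]
    pairs <- apply_intervention(records, iv, gen_cfg$pk, dt = gen_cfg$dt,
                                observed = observed)
    bootstrap_counterfactual(cohort, pairs, outcome_specs, iv,
                             confounders = confounders,
                             adjustment = adjustment,
                             B = B, seed = config$seed + 1000L + k,
                             trim_quantile = trim_q)
  })
  cf <- do.call(rbind, cf_tables)
  utils::write.csv(cf, file.path(out_dir, "table_counterfactual.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("opioidcf")),
    seed = config$seed,
    n_requested = config$n,
    n_filtered_out = n_filtered,
    n_incomplete_dropped = n_incomplete,
    n_analyzed = nrow(cohort),
    n_trimmed = sum(wt$trimmed),
    trim_quantile = trim_q,
    trim_threshold = attr(wt, "threshold"),
    bootstrap_B = B,
    outcomes = names(outcome_specs),
    interventions = lapply(intvs, function(iv)
      list(drug = iv$drug, dose = iv$dose, time_policy = iv$time_policy))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
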