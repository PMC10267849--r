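#' Build a standardized design matrix for outcome models
#'
#' Rows are the untrimmed patients. Continuous covariates (and ordinal
#' covariates, entered as numeric scores) are rescaled to mean 0 and
#' standard deviation 1; binary covariates stay 0/1; categorical covariates
#' are one-hot encoded with the first level dropped as reference. Exposure
#' columns are standardized the same way. By default the scaling moments are
#' computed on the weighted untrimmed sample; set \code{weighted_scaling =
#' FALSE} for unweighted moments. The transformation metadata is stored so
#' the identical scaling can be replayed on counterfactual copies of the
#' cohort with \code{\link{apply_design}}.
#'
#' @param cohort cohort data.frame.
#' @param weights a \code{\link{compute_weights}} result aligned to
#'   \code{cohort} (or NULL for unit weights and no trimming).
#' @param adjustment_vars covariate columns to include alongside exposures.
#' @param exposures exposure column names.
#' @param kinds named covariate kinds vector (defaults to the cohort
#'   attribute).
#' @param weighted_scaling use weighted moments for standardization.
#' @return object of class \code{design_matrix}: list with \code{X} (matrix
#'   with intercept), \code{w} (final weights), \code{rows} (row indices of
#'   untrimmed patients), \code{meta} (replay metadata).
#' @export
build_design <- function(cohort, weights = NULL, adjustment_vars = character(),
                         exposures = grep("^mean_ce_", names(cohort),
                                          value = TRUE),
                         kinds = attr(cohort, "covariate_kinds"),
                         weighted_scaling = TRUE) {
  if (is.null(weights)) {
    rows <- seq_len(nrow(cohort))
    w <- rep(1, nrow(cohort))
  } else {
    rows <- which(!weights$trimmed)
    w <- weights$weight[rows]
  }
  sw <- if (weighted_scaling) w else rep(1, length(rows))
  sub <- cohort[rows, , drop = FALSE]

  meta <- list(columns = list(), exposures = exposures,
               adjustment_vars = adjustment_vars,
               weighted_scaling = weighted_scaling)
  cols <- list()
  add_scaled <- function(name, x_sub, x_name) {
    m <- sum(sw * x_sub) / sum(sw)
    s <- sqrt(sum(sw * (x_sub - m)^2) / sum(sw))
    if (s <= 0) stop_("zero-variance column '%s' in design", x_name)
    meta$columns[[name]] <<- list(type = "scaled", source = x_name,
                                  center = m, scale = s)
    cols[[name]] <<- (x_sub - m) / s
  }
  for (ex in exposures) add_scaled(ex, sub[[ex]], ex)
  for (v in adjustment_vars) {
    kind <- if (!is.null(kinds) && v %in% names(kinds)) kinds[[v]]
            else if (is.factor(cohort[[v]])) "categorical" else "continuous"
    if (kind == "categorical") {
      levs <- levels(factor(cohort[[v]]))
      for (lev in levs[-1L]) {
        nm <- paste0(v, ":", lev)
        meta$columns[[nm]] <- list(type = "indicator", source = v,
                                   level = lev)
        cols[[nm]] <- as.numeric(as.character(sub[[v]]) == lev)
      }
    } else if (kind == "binary") {
      meta$columns[[v]] <- list(type = "raw", source = v)
      cols[[v]] <- as.numeric(sub[[v]])
    } else {
      add_scaled(v, as.numeric(sub[[v]]), v)
    }
  }
  X <- cbind(`(Intercept)` = rep(1, length(rows)), do.call(cbind, cols))
  structure(list(X = X, w = w, rows = rows, meta = meta),
            class = "design_matrix")
}

#' Replay stored design-matrix scaling on a cohort copy
#'
#' Applies the transformation metadata captured by \code{\link{build_design}}
#' to all rows of \code{cohort} (including trimmed ones), so counterfactual
#' exposure values map onto the fitted scale. Optionally overrides exposure
#' columns with supplied vectors before scaling.
#'
#' @param meta the \code{meta} element of a \code{design_matrix}.
#' @param cohort cohort data.frame (any rows).
#' @param exposure_override named list of replacement raw exposure vectors.
#' @return numeric matrix aligned to \code{meta}'s columns.
#' @export
apply_design <- function(meta, cohort, exposure_override = list()) {
  n <- nrow(cohort)
  cols <- list()
  for (nm in names(meta$columns)) {
    cs <- meta$columns[[nm]]
    x <- if (cs$source %in% names(exposure_override))
      exposure_override[[cs$source]] else cohort[[cs$source]]
    cols[[nm]] <- switch(cs$type,
      scaled = (as.numeric(x) - cs$center) / cs$scale,
      indicator = as.numeric(as.character(x) == cs$level),
      raw = as.numeric(x))
  }
  cbind(`(Intercept)` = rep(1, n), do.call(cbind, cols))
}
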