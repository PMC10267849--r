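#' @keywords internal
"_PACKAGE"

# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

expit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate a named linear predictor on raw covariate columns
#'
#' Coefficients are named after covariate columns; entries for categorical
#' covariates use the `column:level` convention (e.g. `service:orthopedic`).
#' Ordinal covariates contribute their integer scores. Missing names raise an
#' error so silent zero-contributions cannot occur.
#'
#' @param data data.frame of covariates.
#' @param coefs named numeric vector; may be NULL or empty (returns zeros).
#' @return numeric vector of length `nrow(data)`.
#' @keywords internal
linear_predictor <- function(data, coefs) {
  eta <- numeric(nrow(data))
  if (is.null(coefs) || length(coefs) == 0L) return(eta)
  for (nm in names(coefs)) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      col <- parts[1L]; lev <- parts[2L]
      if (!col %in% names(data)) stop_("unknown covariate '%s' in coefficients", col)
      eta <- eta + coefs[[nm]] * as.numeric(as.character(data[[col]]) == lev)
    } else {
      if (!nm %in% names(data)) stop_("unknown covariate '%s' in coefficients", nm)
      eta <- eta + coefs[[nm]] * as.numeric(data[[nm]])
    }
  }
  eta
}

# trapezoidal rule on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
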