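#' Compartmental PK parameters with an effect site
#'
#' Describes a linear mammillary pharmacokinetic model (two or three
#' compartments) coupled to an effect compartment by a first-order
#' equilibration rate \code{ke0}. Plasma concentration is the central
#' compartment amount divided by \code{V1}; with doses in micrograms and
#' \code{V1} in litres, concentrations are in ng/mL.
#'
#' @param drug drug label the parameters apply to.
#' @param V1 central volume of distribution (L); must be positive.
#' @param k10,k12,k21,k13,k31 first-order inter-compartment rate constants
#'   (1/min); all nonnegative. For a two-compartment model \code{k13} and
#'   \code{k31} must be zero.
#' @param ke0 plasma-effect-site equilibration rate (1/min); must be positive.
#' @param n_compartments 2 or 3.
#' @return object of class \code{pk_model_parameters}.
#' @export
pk_model_parameters <- function(drug, V1, k10, k12 = 0, k21 = 0, k13 = 0,
                                k31 = 0, ke0, n_compartments = 3L) {
  rates <- c(k10 = k10, k12 = k12, k21 = k21, k13 = k13, k31 = k31)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_("all rate constants must be finite and nonnegative")
  if (!is.finite(V1) || V1 <= 0) stop_("V1 must be positive")
  if (!is.finite(ke0) || ke0 <= 0) stop_("ke0 must be positive")
  if (!n_compartments %in% c(2L, 3L))
    stop_("n_compartments must be 2 or 3")
  if (n_compartments == 2L && (k13 != 0 || k31 != 0))
    stop_("two-compartment model requires k13 = k31 = 0")
  structure(
    list(drug = drug, V1 = V1, k10 = k10, k12 = k12, k21 = k21,
         k13 = k13, k31 = k31, ke0 = ke0,
         n_compartments = as.integer(n_compartments)),
    class = "pk_model_parameters"
  )
}

# System matrix of the 4-state linear system
# x = (A1, A2, A3, Ce); amounts in ug, Ce in ng/mL.
# The block is lower-triangular in (compartments, effect): the effect row
# reads A1 but feeds nothing back, so eig(A) = eig(mammillary) + {-ke0}.
pk_system_matrix <- function(p) {
  rbind(
    c(-(p$k10 + p$k12 + p$k13), p$k21,  p$k31,  0),
    c(p$k12,                   -p$k21,  0,      0),
    c(p$k13,                    0,     -p$k31,  0),
    c(p$ke0 / p$V1,             0,      0,     -p$ke0)
  )
}

# Eigendecomposition-based impulse response of the system to a unit bolus
# in the central compartment: x_i(t) = sum_j V[i,j] Vinv[j,1] exp(lam_j t).
# analytic = FALSE flags a (measure-zero) defective/ill-conditioned case,
# e.g. ke0 colliding with a disposition eigenvalue; callers then fall back
# to stepwise matrix-exponential propagation.
pk_impulse_basis <- function(p) {
  A <- pk_system_matrix(p)
  eg <- eigen(A)
  V <- eg$vectors
  ok <- is.double(eg$values) ||
    all(abs(Im(eg$values)) < 1e-12 * max(abs(eg$values), 1))
  if (ok) {
    kap <- tryCatch(kappa(V, exact = FALSE), error = function(e) Inf)
    ok <- is.finite(kap) && kap < 1e10
  }
  if (!ok) return(list(analytic = FALSE, A = A))
  Vinv <- solve(V)
  list(analytic = TRUE, A = A, lam = Re(eg$values),
       r1 = Re(V[1L, ] * Vinv[, 1L]), r4 = Re(V[4L, ] * Vinv[, 1L]))
}

# Superposed bolus response of one state on a sorted time grid.
# r is the residue vector (basis$r1 for central amount, basis$r4 for Ce).
state_on_grid <- function(times, ev_time, ev_dose, lam, r) {
  out <- numeric(length(times))
  nt <- length(times)
  for (b in seq_along(ev_time)) {
    i0 <- findInterval(ev_time[b] * (1 - 1e-15) - 1e-15, times) + 1L
    if (i0 > nt) next
    dtb <- times[i0:nt] - ev_time[b]
    out[i0:nt] <- out[i0:nt] +
      ev_dose[b] * as.numeric(exp(outer(dtb, lam)) %*% r)
  }
  pmax(out, 0)
}

# trapezoidal window mean on a sorted grid with interpolated endpoints
window_mean_on_grid <- function(times, Ce, window_start, window_end) {
  inside <- times > window_start & times < window_end
  pts <- c(window_start, times[inside], window_end)
  vals <- stats::approx(times, Ce, xout = pts, rule = 2)$y
  max(trapz(pts, vals) / (window_end - window_start), 0)
}

pk_time_grid <- function(t_end, dt) {
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  times
}

#' A single IV bolus event
#'
#' @param time minutes from the record origin; nonnegative.
#' @param dose micrograms; nonnegative.
#' @param drug drug label.
#' @return one-row data.frame.
#' @export
bolus_event <- function(time, dose, drug) {
  if (any(time < 0)) stop_("bolus time must be nonnegative")
  if (any(dose < 0)) stop_("bolus dose must be nonnegative")
  data.frame(time = time, dose = dose, drug = drug,
             stringsAsFactors = FALSE)
}

#' A per-patient dosing record
#'
#' Bundles the patient's timestamped bolus events (possibly several drugs)
#' with the exposure window over which mean effect-site concentrations are
#' averaged.
#'
#' @param patient_id patient identifier.
#' @param events data.frame with columns \code{time}, \code{dose},
#'   \code{drug}; may have zero rows.
#' @param window_start,window_end exposure window in minutes;
#'   \code{window_start < window_end}.
#' @return object of class \code{dosing_record}.
#' @export
dosing_record <- function(patient_id, events, window_start, window_end) {
  if (window_start >= window_end) stop_("window_start must precede window_end")
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), dose = numeric(0),
                         drug = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("time", "dose", "drug") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$time < 0)) stop_("bolus times must be nonnegative")
    if (any(events$dose < 0)) stop_("bolus doses must be nonnegative")
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(
    list(patient_id = patient_id, events = events,
         window_start = window_start, window_end = window_end),
    class = "dosing_record"
  )
}

#' Simulate plasma and effect-site concentrations for one drug
#'
#' Solves the linear compartmental system exactly: each bolus is an
#' instantaneous jump of the central-compartment amount, and the response is
#' the superposition of per-bolus impulse responses obtained from the
#' eigendecomposition of the system matrix. The trace covers
#' \code{[0, window_end]} sampled every \code{dt} minutes (the endpoint is
#' always included). Values at grid points are exact up to floating point;
#' there is no step-size truncation error. If the eigendecomposition is
#' ill-conditioned (e.g. \code{ke0} coinciding with a disposition
#' eigenvalue), the solver falls back to stepwise matrix-exponential
#' propagation.
#'
#' @param record a \code{\link{dosing_record}}; all events must be for
#'   \code{params$drug}.
#' @param params \code{\link{pk_model_parameters}}.
#' @param dt sampling interval in minutes (default 0.1).
#' @return object of class \code{concentration_trace}: list with
#'   \code{times}, \code{Ce}, \code{Cp}, \code{drug}.
#' @export
simulate_effect_site <- function(record, params, dt = 0.1) {
  if (!inherits(params, "pk_model_parameters")) stop_("invalid PK parameters")
  if (!is.finite(dt) || dt <= 0) stop_("dt must be positive")
  events <- record$events
  if (nrow(events) > 0 && any(events$drug != params$drug))
    stop_("record contains events for drug(s) other than '%s': %s",
          params$drug,
          paste(unique(setdiff(events$drug, params$drug)), collapse = ", "))

  t_end <- record$window_end
  times <- pk_time_grid(t_end, dt)

  keep <- events$time <= t_end & events$dose > 0
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0) {
    return(structure(list(times = times, Ce = numeric(length(times)),
                          Cp = numeric(length(times)), drug = params$drug),
                     class = "concentration_trace"))
  }

  basis <- pk_impulse_basis(params)
  if (basis$analytic) {
    Ce <- state_on_grid(times, events$time, events$dose, basis$lam, basis$r4)
    Cp <- state_on_grid(times, events$time, events$dose, basis$lam,
                        basis$r1) / params$V1
  } else {
    A <- basis$A
    # stepwise expm propagation with boluses as state jumps
    tt <- sort(unique(c(times, events$time[events$time <= t_end])))
    x <- c(0, 0, 0, 0)
    n <- length(tt)
    A1v <- numeric(n); Cev <- numeric(n)
    cache <- new.env(parent = emptyenv())
    step <- function(h) {
      key <- sprintf("%.15g", h)
      if (is.null(cache[[key]]))
        cache[[key]] <- as.matrix(Matrix::expm(A * h))
      cache[[key]]
    }
    add_dose <- function(x, t) {
      hit <- events$time == t
      if (any(hit)) x[1L] <- x[1L] + sum(events$dose[hit])
      x
    }
    x <- add_dose(x, tt[1L])
    A1v[1L] <- x[1L]; Cev[1L] <- x[4L]
    for (i in 2:n) {
      x <- as.numeric(step(tt[i] - tt[i - 1L]) %*% x)
      x <- add_dose(x, tt[i])
      A1v[i] <- x[1L]; Cev[i] <- x[4L]
    }
    keep <- match(times, tt)
    A1 <- A1v[keep]; Ce <- Cev[keep]
    Cp <- A1 / params$V1
  }

  structure(list(times = times, Ce = pmax(Ce, 0), Cp = pmax(Cp, 0),
                 drug = params$drug),
            class = "concentration_trace")
}

#' Time-averaged effect-site concentration over a window
#'
#' Trapezoidal quadrature of \code{Ce} over \code{[window_start,
#' window_end]} on the trace grid, with linear interpolation at the window
#' boundaries, divided by the window length.
#'
#' @param trace a \code{\link{concentration_trace}}.
#' @param window_start,window_end window in minutes; must lie within the
#'   trace support.
#' @return mean concentration (ng/mL), nonnegative.
#' @export
mean_window_concentration <- function(trace, window_start, window_end) {
  tmin <- trace$times[1L]; tmax <- trace$times[length(trace$times)]
  if (window_start >= window_end) stop_("window_start must precede window_end")
  if (window_start < tmin - 1e-9 || window_end > tmax + 1e-9)
    stop_("window [%g, %g] outside trace support [%g, %g]",
          window_start, window_end, tmin, tmax)
  if (all(trace$Ce == 0)) return(0)
  window_mean_on_grid(trace$times, trace$Ce, window_start, window_end)
}

#' Morphine milligram equivalent conversion table
#'
#' Factors map micrograms administered to MME. The defaults are conventional
#' equianalgesic conversions (fentanyl 100 ug ~ 10 mg morphine IV-equivalent;
#' hydromorphone ~4x morphine potency per mg) and are configuration, not
#' fixed constants; supply your own factors to override.
#'
#' @param factors named numeric vector, MME per microgram; all positive.
#' @return object of class \code{mme_table}.
#' @export
mme_conversion_table <- function(factors = c(fentanyl = 0.1,
                                             hydromorphone = 0.004,
                                             morphine = 0.001)) {
  if (any(factors <= 0)) stop_("MME conversion factors must be positive")
  structure(as.list(factors), class = "mme_table")
}

#' Total morphine milligram equivalents of a dosing record
#'
#' Sums dose times conversion factor over events inside the record's
#' exposure window.
#'
#' @param record a \code{\link{dosing_record}}.
#' @param table an \code{\link{mme_conversion_table}}.
#' @return total MME, nonnegative.
#' @export
total_mme <- function(record, table = mme_conversion_table()) {
  ev <- record$events
  if (nrow(ev) == 0) return(0)
  ev <- ev[ev$time >= record$window_start & ev$time <= record$window_end, ,
           drop = FALSE]
  if (nrow(ev) == 0) return(0)
  missing <- setdiff(unique(ev$drug), names(table))
  if (length(missing) > 0)
    stop_("no MME conversion factor for drug(s): %s",
          paste(missing, collapse = ", "))
  sum(ev$dose * unlist(table)[ev$drug])
}

#' Default PK parameter sets
#'
#' Literature-style three-compartment parameterizations for fentanyl and
#' hydromorphone shipped as configuration (see
#' \code{inst/extdata/pk_defaults.yaml}); the code treats the numbers as
#' opaque inputs and any drug can be reparameterized via
#' \code{\link{read_pk_config}} or by constructing
#' \code{\link{pk_model_parameters}} directly.
#'
#' @return named list of \code{pk_model_parameters}.
#' @export
default_pk_parameters <- function() {
  path <- system.file("extdata", "pk_defaults.yaml", package = "opioidcf")
  read_pk_config(path)
}

#' Read PK parameters from a YAML configuration
#'
#' @param path YAML file keyed by drug name; each entry carries V1, k10,
#'   k12, k21, k13, k31, ke0, n_compartments.
#' @return named list of \code{pk_model_parameters}.
#' @export
read_pk_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(drug) {
    p <- cfg[[drug]]
    pk_model_parameters(drug = drug, V1 = p$V1, k10 = p$k10,
                        k12 = p$k12 %||% 0, k21 = p$k21 %||% 0,
                        k13 = p$k13 %||% 0, k31 = p$k31 %||% 0,
                        ke0 = p$ke0,
                        n_compartments = p$n_compartments %||% 3L)
  })
  names(out) <- names(cfg)
  out
}

#' Window-mean effect-site exposures for a set of dosing records
#'
#' For each patient and each drug in \code{pk}, subsets the record's events
#' to that drug, simulates the effect-site trace and averages it over the
#' exposure window. Patients with no boluses of a drug before
#' \code{window_end} get exposure exactly 0.
#'
#' @param records list of \code{\link{dosing_record}}.
#' @param pk named list of \code{\link{pk_model_parameters}} keyed by drug.
#' @param dt sampling interval (min).
#' @return data.frame with \code{patient_id} and one \code{mean_ce_<drug>}
#'   column per drug.
#' @export
compute_exposures <- function(records, pk, dt = 0.1) {
  n <- length(records)
  out <- data.frame(patient_id = vapply(records, function(r) r$patient_id,
                                        character(1)),
                    stringsAsFactors = FALSE)
  for (drug in names(pk)) {
    basis <- pk_impulse_basis(pk[[drug]])
    vals <- numeric(n)
    for (i in seq_len(n)) {
      r <- records[[i]]
      sel <- r$events$drug == drug & r$events$time <= r$window_end &
        r$events$dose > 0
      if (!any(sel)) next
      if (basis$analytic) {
        times <- pk_time_grid(r$window_end, dt)
        Ce <- state_on_grid(times, r$events$time[sel], r$events$dose[sel],
                            basis$lam, basis$r4)
        vals[i] <- window_mean_on_grid(times, Ce, r$window_start,
                                       r$window_end)
      } else {
        sub <- dosing_record(r$patient_id,
                             r$events[sel, , drop = FALSE],
                             r$window_start, r$window_end)
        tr <- simulate_effect_site(sub, pk[[drug]], dt = dt)
        vals[i] <- mean_window_concentration(tr, r$window_start,
                                             r$window_end)
      }
    }
    out[[paste0("mean_ce_", drug)]] <- vals
  }
  out
}
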