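# Shared fixtures: small PK parameter sets and cached synthetic cohorts.

# one-compartment degenerate parameters with a closed-form solution
pk_one_compartment <- function(V1 = 10, k10 = 0.1, ke0 = 0.25,
                               drug = "testdrug") {
  pk_model_parameters(drug = drug, V1 = V1, k10 = k10, k12 = 0, k21 = 0,
                      k13 = 0, k31 = 0, ke0 = ke0, n_compartments = 2L)
}

# generic three-compartment synthetic parameters
pk_three_compartment <- function(drug = "testdrug", ke0 = 0.12) {
  pk_model_parameters(drug = drug, V1 = 12, k10 = 0.08, k12 = 0.3,
                      k21 = 0.07, k13 = 0.02, k31 = 0.004, ke0 = ke0,
                      n_compartments = 3L)
}

# closed-form plasma/effect-site response to a bolus D at t = 0 for
# one-compartment kinetics (independent oracle for the solver)
one_compartment_closed_form <- function(t, D, V1, k10, ke0) {
  Cp <- (D / V1) * exp(-k10 * t)
  Ce <- (D / V1) * ke0 / (ke0 - k10) * (exp(-k10 * t) - exp(-ke0 * t))
  list(Cp = Cp, Ce = Ce)
}

# analytic time-average of the closed-form Ce over [0, T]
one_compartment_mean_ce <- function(T, D, V1, k10, ke0) {
  (D / V1) * ke0 / (ke0 - k10) *
    ((1 - exp(-k10 * T)) / k10 - (1 - exp(-ke0 * T)) / ke0) / T
}

# cached cohorts so expensive generations run once per test session
.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, n, confounding, seed) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_cohort(n, generator_config(confounding),
                                             seed = seed)
  .fixture_cache[[key]]
}

big_moderate <- function() cached_cohort("mod20k", 20000L, "moderate", 421L)
strong5k <- function() cached_cohort("strong5k", 5000L, "strong", 1L)

# exhaustive O(n^2) pair-loop oracle for the weighted Kendall tau-b
kendall_pair_oracle <- function(x, y, w) {
  n <- length(x)
  num <- 0; P <- 0; Tx <- 0; Ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ww <- w[i] * w[j]
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    num <- num + ww * sx * sy
    P <- P + ww
    if (sx == 0) Tx <- Tx + ww
    if (sy == 0) Ty <- Ty + ww
  }
  num / sqrt((P - Tx) * (P - Ty))
}

# direct optimisation oracle for the weighted proportional-odds likelihood
po_loglik_oracle <- function(X, y, w) {
  vals <- sort(unique(y))
  K <- length(vals)
  p <- ncol(X)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    zeta <- cumsum(c(par[p + 1], exp(par[(p + 2):(p + K - 1)])))
    eta <- as.numeric(X %*% beta)
    cum <- cbind(vapply(zeta, function(z) plogis(z - eta),
                        numeric(length(eta))), 1)
    pr <- cum - cbind(0, cum[, -K, drop = FALSE])
    idx <- match(y, vals)
    -sum(w * log(pmax(pr[cbind(seq_along(y), idx)], 1e-300)))
  }
  start <- c(rep(0, p), qlogis(cumsum(rep(1 / K, K - 1))[1]),
             rep(0, K - 2))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par[seq_len(p)]
  zeta <- cumsum(c(opt$par[p + 1], exp(opt$par[(p + 2):(p + K - 1)])))
  list(beta = beta, zeta = zeta, value = opt$value)
}
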