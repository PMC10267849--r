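unit_design <- function(cohort, adjustment = character(),
                        exposures = grep("^mean_ce_", names(cohort),
                                         value = TRUE), ...) {
  build_design(cohort, weights = NULL, adjustment_vars = adjustment,
               exposures = exposures, ...)
}

test_that("design standardization, encoding and replay behave as specified", {
  set.seed(6)
  n <- 200
  co <- data.frame(patient_id = as.character(1:n),
                   mean_ce_a = rlnorm(n),
                   z = rnorm(n),                   # will standardize
                   b = rbinom(n, 1, 0.4),
                   g = factor(sample(c("u", "v", "w"), n, TRUE)))
  kinds <- c(z = "continuous", b = "binary", g = "categorical")
  d <- unit_design(co, adjustment = c("z", "b", "g"), kinds = kinds)
  expect_equal(unname(colMeans(d$X)[["z"]]), 0, tolerance = 1e-12)
  expect_equal(sd(d$X[, "z"]) * sqrt((n - 1) / n), 1, tolerance = 1e-12)
  # binary column untouched; 3-level categorical -> exactly 2 indicators
  expect_identical(d$X[, "b"], as.numeric(co$b))
  expect_identical(sum(grepl("^g:", colnames(d$X))), 2L)
  # an already-standardized column passes through unchanged
  co2 <- co; co2$z <- (co$z - mean(co$z)) / (sd(co$z) * sqrt((n - 1) / n))
  d2 <- unit_design(co2, adjustment = c("z", "b", "g"), kinds = kinds)
  expect_equal(d2$X[, "z"], co2$z, tolerance = 1e-12)
  expect_equal(d2$meta$columns$z$center, 0, tolerance = 1e-12)
  expect_equal(d2$meta$columns$z$scale, 1, tolerance = 1e-12)
  # replaying stored metadata reproduces the matrix bit for bit
  expect_identical(apply_design(d$meta, co), d$X)
  # zero-variance columns are rejected by name
  co$flat <- 5
  expect_error(unit_design(co, adjustment = "flat",
                           kinds = c(kinds, flat = "continuous")), "flat")
})

test_that("two-category ordinal fit collapses to weighted logistic", {
  set.seed(8)
  n <- 500
  co <- data.frame(patient_id = as.character(1:n), mean_ce_a = rlnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * scale(co$mean_ce_a)))
  d <- unit_design(co)
  fo <- fit_ordinal(d, y)
  ref <- glm(y ~ d$X[, -1], family = binomial())
  expect_equal(unname(fo$coef["mean_ce_a"]),
               unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(unname(fo$zeta[1]), -unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("weighted proportional-odds fit matches a direct optimizer", {
  set.seed(9)
  n <- 400
  co <- data.frame(patient_id = as.character(1:n), mean_ce_a = rlnorm(n))
  eta <- 0.7 * (co$mean_ce_a - mean(co$mean_ce_a)) / sd(co$mean_ce_a)
  y <- rowSums(outer(eta + rlogis(n), c(-1, 0, 1, 2), `>`))
  w <- runif(n, 0.5, 2)
  d <- unit_design(co)
  d$w <- w
  fo <- fit_ordinal(d, y)
  oracle <- po_loglik_oracle(d$X[, -1, drop = FALSE], y, w)
  expect_equal(unname(fo$coef["mean_ce_a"]), oracle$beta[1],
               tolerance = 1e-4)
  expect_equal(unname(fo$zeta), oracle$zeta, tolerance = 1e-3)
})

test_that("ordinal probabilities sum to one and shift with coefficients", {
  set.seed(10)
  co <- data.frame(patient_id = as.character(1:300),
                   mean_ce_a = rlnorm(300))
  y <- sample(0:5, 300, TRUE)
  d <- unit_design(co)
  f <- fit_ordinal(d, y)
  pr <- predict_ordinal_probs(f, d$X)
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-10)
  # increasing the exposure coefficient shifts mass to higher categories
  f_up <- f; f_up$coef["mean_ce_a"] <- f$coef["mean_ce_a"] + 1
  x_hi <- d$X[d$X[, "mean_ce_a"] > 0, , drop = FALSE]
  e0 <- mean(predict_expectation(f, x_hi))
  e1 <- mean(predict_expectation(f_up, x_hi))
  expect_gt(e1, e0)
})

test_that("hurdle closed forms hold for the intercept-only model", {
  set.seed(11)
  n <- 600
  co <- data.frame(patient_id = as.character(1:n))
  y <- ifelse(rbinom(n, 1, 0.35) == 1, 0, rlnorm(n, 1.2, 0.7))
  w <- runif(n, 0.5, 2)
  d <- build_design(co, weights = NULL, adjustment_vars = character(),
                    exposures = character())
  d$w <- w
  f <- fit_hurdle(d, y)
  pos <- y > 0
  p_hat <- sum(w * pos) / sum(w)
  expect_equal(unname(f$zero_coef[1]), qlogis(p_hat), tolerance = 1e-8)
  mu_hat <- sum(w[pos] * log(y[pos])) / sum(w[pos])
  expect_equal(unname(f$pos_coef[1]), mu_hat, tolerance = 1e-10)
  # fitted mean reproduces the weighted sample mean within Monte Carlo error
  pred <- predict_expectation(f, d$X[1, , drop = FALSE])
  wmean <- sum(w * y) / sum(w)
  se <- sqrt(sum(w^2 * (y - wmean)^2)) / sum(w)
  expect_lt(abs(pred - wmean), 3 * se)
  expect_error(fit_hurdle(d, rep(1, n)), "degenerate")
  expect_error(fit_hurdle(d, rep(0, n)), "degenerate")
})

test_that("cox fit recovers the exponential rate and a hand-table beta", {
  set.seed(12)
  n <- 10000
  co <- data.frame(patient_id = as.character(1:n), mean_ce_a = rlnorm(n))
  lambda <- 0.02
  tt <- rexp(n, lambda)
  d <- unit_design(co)
  f <- fit_cox(d, tt, rep(1L, n))
  # with no covariate effect the profile h0 is the exponential MLE
  expect_lt(abs(f$h0 - lambda), 3 * lambda / sqrt(n))
  expect_lt(abs(f$coef[["mean_ce_a"]]), 3 / sqrt(n) * 3)
  # small table with one binary covariate vs exhaustive partial likelihood
  ht <- data.frame(patient_id = as.character(1:6),
                   x = c(1, 0, 1, 0, 1, 0))
  times <- c(1.1, 2.3, 3.2, 4.8, 6.4, 7.9)
  dh <- build_design(ht, weights = NULL, adjustment_vars = "x",
                     exposures = character(),
                     kinds = c(x = "binary"))
  fh <- fit_cox(dh, times, rep(1L, 6))
  pl <- function(b) {
    eta <- b * ht$x
    risk <- exp(eta)
    ll <- 0
    for (i in order(times)) {
      at_risk <- times >= times[i]
      ll <- ll + eta[i] - log(sum(risk[at_risk]))
    }
    ll
  }
  grid <- optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(unname(fh$coef["x"]), grid, tolerance = 1e-4)
})

test_that("cox fits are invariant to splitting rows into half weights", {
  set.seed(13)
  n <- 150
  co <- data.frame(patient_id = as.character(1:n), mean_ce_a = rlnorm(n))
  tt <- rexp(n, 0.05 * exp(0.3 * log(co$mean_ce_a + 1)))
  ev <- rbinom(n, 1, 0.9)
  # duplication creates exact ties between the copies; Breslow's tie
  # handling makes the weight-splitting invariance exact
  d1 <- unit_design(co)
  f1 <- fit_cox(d1, tt, ev, ties = "breslow")
  co2 <- rbind(co, co); tt2 <- c(tt, tt); ev2 <- c(ev, ev)
  d2 <- unit_design(co2)
  d2$w <- rep(0.5, 2 * n)
  f2 <- fit_cox(d2, tt2, ev2, ties = "breslow")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_equal(f1$h0, f2$h0, tolerance = 1e-8)
})

test_that("logistic fit matches closed forms and rejects degeneracies", {
  set.seed(14)
  n <- 500
  co <- data.frame(patient_id = as.character(1:n))
  y <- rbinom(n, 1, 0.3)
  w <- runif(n, 0.5, 2)
  d <- build_design(co, weights = NULL, adjustment_vars = character(),
                    exposures = character())
  d$w <- w
  f <- fit_logistic(d, y)
  expect_equal(unname(f$coef[1]), qlogis(sum(w * y) / sum(w)),
               tolerance = 1e-8)
  # 2x2 table: coefficient equals the log odds ratio
  tb <- data.frame(patient_id = as.character(1:40),
                   x = rep(c(0, 1), each = 20))
  yt <- c(rep(1, 5), rep(0, 15), rep(1, 12), rep(0, 8))
  dt <- build_design(tb, weights = NULL, adjustment_vars = "x",
                     exposures = character(), kinds = c(x = "binary"))
  ft <- fit_logistic(dt, yt)
  expect_equal(unname(ft$coef["x"]), log((12 / 8) / (5 / 15)),
               tolerance = 1e-8)
  expect_error(fit_logistic(d, rep(1, n)), "single class")
})

test_that("unit-weight fits agree with reference unweighted fits", {
  set.seed(15)
  n <- 200
  co <- data.frame(patient_id = as.character(1:n),
                   mean_ce_a = rlnorm(n), z = rnorm(n))
  kinds <- c(z = "continuous")
  d <- unit_design(co, adjustment = "z", kinds = kinds)
  X <- d$X[, -1]
  # logistic
  yb <- rbinom(n, 1, plogis(0.4 * X[, 1] - 0.2 * X[, 2]))
  fl <- fit_logistic(d, yb)
  rl <- glm(yb ~ X, family = binomial())
  expect_lt(max(abs(fl$coef - coef(rl))), 1e-6)
  # cox
  tt <- rexp(n, 0.05 * exp(0.3 * X[, 1]))
  fc <- fit_cox(d, tt, rep(1L, n))
  rc <- survival::coxph(survival::Surv(tt, rep(1, n)) ~ X, ties = "efron")
  expect_lt(max(abs(fc$coef[-1] - coef(rc))), 1e-6)
  # hurdle components
  yh <- ifelse(rbinom(n, 1, 0.3) == 1, 0, rlnorm(n, 0.5 + 0.3 * X[, 1], 0.6))
  fh <- fit_hurdle(d, yh)
  rz <- glm((yh > 0) ~ X, family = binomial())
  expect_lt(max(abs(fh$zero_coef - coef(rz))), 1e-6)
  rp <- lm(log(yh[yh > 0]) ~ X[yh > 0, ])
  expect_lt(max(abs(fh$pos_coef - coef(rp))), 1e-6)
  # ordinal: unit-weight polr vs the unweighted call
  yo <- rowSums(outer(0.5 * X[, 1] + rlogis(n), c(-1, 0, 1), `>`))
  fo <- fit_ordinal(d, yo)
  ro <- suppressWarnings(
    MASS::polr(factor(yo, ordered = TRUE) ~ X, method = "logistic"))
  expect_lt(max(abs(fo$coef[-1] - coef(ro))), 1e-6)
})

test_that("all four families recover generator truth on a large cohort", {
  g <- big_moderate()
  co <- g$cohort
  truth <- g$truth$outcomes
  kinds <- attr(co, "covariate_kinds")
  adj <- c(attr(co, "confounders"), attr(co, "adjustment"))
  d <- build_design(co, weights = NULL, adjustment_vars = adj,
                    kinds = kinds)
  sf <- d$meta$columns$mean_ce_fentanyl$scale
  sh <- d$meta$columns$mean_ce_hydromorphone$scale

  # ordinal pain: fitted standardized slope / exposure SD ~ raw truth
  fo <- fit_ordinal(d, co$pacu_max_pain)
  ro <- suppressWarnings(MASS::polr(
    factor(co$pacu_max_pain, ordered = TRUE) ~ d$X[, -1],
    method = "logistic", Hess = TRUE))
  se_o <- sqrt(diag(vcov(ro)))[1:2]
  expect_lt(abs(fo$coef[["mean_ce_fentanyl"]] / sf -
                  truth$pacu_max_pain$beta_exposure[["fentanyl"]]),
            3 * se_o[1] / sf)
  expect_lt(abs(fo$coef[["mean_ce_hydromorphone"]] / sh -
                  truth$pacu_max_pain$beta_exposure[["hydromorphone"]]),
            3 * se_o[2] / sh)

  # hurdle MME: the fitted zero part models P(Y>0) = -P(Y=0) truth
  fh <- fit_hurdle(d, co$pacu_total_mme)
  rz <- glm((co$pacu_total_mme > 0) ~ d$X[, -1], family = binomial())
  se_z <- sqrt(diag(vcov(rz)))[2]
  expect_lt(abs(fh$zero_coef[["mean_ce_fentanyl"]] / sf -
                  -truth$pacu_total_mme$zero$beta_exposure[["fentanyl"]]),
            3 * se_z / sf)
  pos <- co$pacu_total_mme > 0
  rp <- lm(log(co$pacu_total_mme[pos]) ~ d$X[pos, -1])
  se_p <- sqrt(diag(vcov(rp)))[2]
  expect_lt(abs(fh$pos_coef[["mean_ce_fentanyl"]] / sf -
                  truth$pacu_total_mme$beta_exposure[["fentanyl"]]),
            3 * se_p / sf)

  # cox length of stay
  fc <- fit_cox(d, co$pacu_los_min, co$pacu_los_min_event)
  rc <- survival::coxph(
    survival::Surv(co$pacu_los_min, co$pacu_los_min_event) ~ d$X[, -1],
    ties = "efron")
  se_c <- sqrt(diag(vcov(rc)))[1]
  expect_lt(abs(fc$coef[["mean_ce_fentanyl"]] / sf -
                  truth$pacu_los_min$beta_exposure[["fentanyl"]]),
            3 * se_c / sf)

  # logistic uncontrolled pain
  fb <- fit_logistic(d, co$uncontrolled_pain_24h)
  rb <- glm(co$uncontrolled_pain_24h ~ d$X[, -1], family = binomial())
  se_b <- sqrt(diag(vcov(rb)))[2]
  expect_lt(abs(fb$coef[["mean_ce_fentanyl"]] / sf -
                  truth$uncontrolled_pain_24h$beta_exposure[["fentanyl"]]),
            3 * se_b / sf)
})

test_that("effect estimates exponentiate exposure coefficients per family", {
  f <- structure(list(family = "logistic",
                      coef = c(`(Intercept)` = -1, mean_ce_a = log(2),
                               mean_ce_b = 0)),
                 class = "outcome_fit")
  ee <- effect_estimates(f, outcome = "o")
  expect_equal(ee$ratio, c(2, 1))
  expect_true(all(ee$measure == "OR"))
  h <- structure(list(family = "hurdle",
                      zero_coef = c(`(Intercept)` = 0, mean_ce_a = 0.5),
                      pos_coef = c(`(Intercept)` = 1, mean_ce_a = -0.25),
                      sigma = 1),
                 class = "outcome_fit")
  eh <- effect_estimates(h, outcome = "o")
  expect_equal(nrow(eh), 2L)   # binomial and log-normal components
  expect_setequal(eh$component, c("binomial", "log-normal"))
  cx <- structure(list(family = "cox",
                       coef = c(`(Intercept)` = 0, mean_ce_a = 0.1),
                       h0 = 0.01),
                  class = "outcome_fit")
  expect_equal(effect_estimates(cx, outcome = "o")$measure, "HR")
})
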