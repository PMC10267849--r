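---
title: "Counterfactual modeling of intraoperative opioid exposure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual modeling of intraoperative opioid exposure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference chain

`opioidcf` implements a complete observational-inference chain from
intraoperative opioid bolus records to counterfactual predictions of
postoperative outcomes:

1. **Exposure construction.** Timestamped IV boluses are converted to
   effect-site concentration traces with linear mammillary pharmacokinetic
   models (two or three compartments) coupled to an effect compartment by a
   first-order equilibration rate $k_{e0}$. The treatment variable per drug
   is the time-averaged effect-site concentration $\bar{C}_e$ over the
   patient's exposure window (ng/mL).
2. **Generalized propensity weighting.** Each exposure is semicontinuous —
   a point mass at zero plus a continuous positive part — so its
   conditional density given confounders $x$ is modeled in two parts: a
   logistic model for $P(E = 0 \mid x)$ and a normal model for
   $\log E \mid E > 0, x$ fitted by least squares. The stabilized weight is
   the marginal likelihood of the observed exposure divided by this
   conditional likelihood, multiplied across the two drugs; weights above
   the empirical 99.5th percentile are discarded.
3. **Weighted outcome models.** Pain scores (0–10) use proportional-odds
   ordinal regression; opioid consumption (MME) uses a two-part hurdle
   model (logistic for $P(Y > 0)$, log-normal for $Y \mid Y > 0$);
   lengths of stay use weighted Cox proportional hazards with Efron ties;
   binary outcomes use logistic regression. Continuous covariates are
   standardized to mean 0, SD 1 on the untrimmed weighted sample;
   categorical covariates are one-hot encoded with a reference level
   dropped.
4. **g-computation.** For an intervention (an additional bolus, e.g. 100 µg
   fentanyl), each patient's exposure is re-simulated with the extra bolus,
   every patient's outcome expectation is predicted under observed and
   counterfactual exposure, and the difference is averaged over the whole
   unweighted population — including rows trimmed from the weighted fits,
   which are part of the population the prediction describes. Percentile
   confidence intervals come from patient-level bootstrap resamples that
   rerun the entire chain (weight fitting, trimming, standardization,
   outcome fits, prediction).

## PK solver

The state vector $(A_1, A_2, A_3, C_e)$ evolves linearly; the effect row
reads the central compartment but feeds nothing back, so the system matrix
is block-triangular and its eigenvalues are the mammillary disposition
rates plus $-k_{e0}$. Boluses are instantaneous jumps of the central
amount. The solver superposes per-bolus impulse responses obtained from
the eigendecomposition, so values at grid points are exact up to floating
point: linearity and superposition hold to machine precision, and grid
resolution affects only the trapezoidal window average (error quadratic in
`dt`). When the eigenvector matrix is ill-conditioned — $k_{e0}$ colliding
with a disposition eigenvalue, a measure-zero configuration — the solver
falls back to stepwise matrix-exponential propagation. The default grid is
`dt = 0.1` min for analysis of individual traces; the cohort generator
uses `dt = 0.5` min, which changes window means by well under $10^{-3}$
relative while keeping large simulations fast. PK parameter sets ship as
YAML configuration with literature-style values for fentanyl and
hydromorphone; the code treats them as opaque, and every test uses
synthetic parameters.

Exposure windows are carried on each dosing record, and the window average
includes all boluses up to the window end. The counterfactual bolus is
inserted at the window start by default: fentanyl administration is
front-loaded in practice, and an early bolus maximizes its contribution to
the window mean; the insertion policy (`window-start`, `window-mid`, or a
custom minute) is a first-class argument and a documented sensitivity
axis.

## The synthetic cohort generator

There is no public patient-level dataset for this design, so the generator
is a first-class module with known ground truth. Its defaults emulate the
reported statistical structure of a large perioperative cohort:

* covariates of the kinds found in an anesthesia record — age (normal,
  mean 55.4, SD 17.1 years), BMI (log-normal, median 27.3), sex (53.5%
  female), ASA physical status I–IV (ordinal), surgical service
  (categorical, six levels), opioid naivety and a comorbidity score as
  adjustment-only variables;
* two-part exposure models per drug: no fentanyl with probability 7.3% and
  no hydromorphone with probability 36.4% (the zero-part intercept is
  calibrated by root-finding against the realized covariate sample so the
  marginal fractions hit these targets even with nonzero slopes); positive
  total doses log-normal around ~110 µg fentanyl / ~470 µg hydromorphone,
  chosen so the window-mean exposure medians land near 0.5 ng/mL for both
  drugs;
* bolus timing: 1–5 equal boluses, fentanyl times Beta(1,3)-front-loaded,
  hydromorphone uniform over the 5–85% span of the window;
* exposure windows log-normal (median 90 min) and independent of the
  covariates;
* outcomes from all four families, conditioned on the window-mean
  exposures (matching the models, which use $\bar{C}_e$ as the regressor):
  a latent-logistic ordinal pain score cut at fixed thresholds, a hurdle
  MME outcome, an exponential length-of-stay with administrative censoring,
  and a Bernoulli uncontrolled-pain indicator, all with negative fentanyl
  coefficients on pain and consumption.

The generator does **not** emulate EHR messiness (unit errors, duplicated
rows, informative missingness), covariate joint structure beyond the
marginals, time-varying confounding, or interference between drugs, so
green tests certify the statistical machinery under a correctly specified
data-generating process, not robustness to real-data pathologies.

### The severe-confounding preset

Balance diagnostics need a scenario where confounding is severe enough to
matter, so `generator_config("strong")` confounds fentanyl through age and
hydromorphone through sex, each explaining about 15% of that drug's
log-exposure variance. Two structural constraints shaped this preset, and
they are worth recording because they are properties of the method, not of
the implementation:

* **Stabilized weights have infinite variance when confounders explain
  more than half the marginal log-exposure variance.** The weight is a
  ratio of a wide marginal to a narrow conditional normal density; its
  second moment diverges once
  $\sigma^2_{\mathrm{marg}} > 2\sigma^2_{\mathrm{cond}}$. Past that point
  no sample size yields stable weighted correlations, and the 99.5% trim
  removes exactly the corrective mass, leaving residual imbalance even
  with oracle weights. Spreading severe confounding across both drugs
  compounds the per-drug weight product; one driving confounder per drug
  keeps the product tails light (effective sample size ~3000 of 5000).
* **Random bolus timing makes the conditional exposure distribution
  non-log-normal.** A single bolus near the window end contributes a
  vanishing window mean, giving $\log \bar{C}_e$ an unbounded left tail
  that the two-part log-normal propensity family cannot represent; the
  resulting density-ratio weights explode. The strong preset therefore
  places boluses at fixed quantiles of the timing profile (keeping its
  shape, removing its noise). The realistic default keeps fully random
  timing — its weights are approximate, which is the realistic situation,
  and its confounding is moderate.

## Numerical and design choices

* **Trimming semantics.** "Discarded above the 99.5th percentile" is read
  strictly: rows with raw combined weight strictly above the empirical
  percentile (type-7 quantile) are dropped from all weighted fits and
  weighted balance columns, not capped. They re-enter the counterfactual
  averaging, which is a population quantity.
* **Joint weight = product of per-drug weights**, justified by the near
  independence of the two exposures; a joint-density alternative would
  need a bivariate model the data do not demand.
* **Hurdle location part** is least squares on $\log Y$, with the
  log-normal scale from the weighted mean squared residual, so the
  prediction identity $E[Y] = P(Y>0)\,e^{\mu + \sigma^2/2}$ holds with the
  fitted quantities.
* **Ordinal fits** use the weighted proportional-odds likelihood
  (`MASS::polr`); unobserved categories are merged into neighbors with a
  warning, and a two-category outcome collapses to weighted logistic
  regression, which is the same likelihood. Category values are retained
  so expected scores use the actual 0–10 scale.
* **Cox expected times** use the constant-baseline-hazard profile
  estimate $\hat h_0 = \sum w_i d_i / \sum w_i t_i e^{x_i'\hat\beta}$ only
  for prediction; the fit itself stays semiparametric (Efron ties).
  Splitting rows into fractional weights is exactly invariant under
  Breslow ties and only approximately under Efron, because the split
  copies constitute a genuine tie; `fit_cox` exposes the tie method.
* **Separation** in logistic fits is flagged (coefficient magnitude above
  15 on the standardized scale) and rejected with the offending column
  named — small subgroups with empty outcome cells fail loudly rather than
  silently.
* **Bootstrap**: percentile intervals, default $B = 200$, resampling
  patients with replacement and rerunning the full chain; replicates whose
  fits fail are dropped and counted, with more than 10% failures aborting
  the run.
* **Problem sizes.** The shipped analysis uses 4,000 patients with
  $B = 200$; validation uses cohorts up to 20,000 for moment checks,
  20 replicates of 10,000 for parameter recovery, and 100 replicates of
  2,000 (with $B = 100$) for bootstrap coverage. These sizes give
  Monte-Carlo error comfortably inside the tolerances they are checked
  against.

## Limitations

The weighting model is correctly specified for the generator only when
timing noise is controlled; under the realistic preset the weights are
approximate, which mirrors practice. Effect estimates are associational:
the chain adjusts for declared confounders only, and no attempt is made at
doubly-robust estimation or sensitivity analysis for unmeasured
confounding beyond swapping confounder sets. Infusions, patient-controlled
analgesia, and covariate-adjusted PK parameterizations are out of scope;
per-patient PK overrides are available through the configuration.
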