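# opioidcf

Counterfactual modeling of intraoperative opioid exposure and
postoperative pain, opioid-use, and recovery outcomes.

## The problem

Anesthesiologists titrate intraoperative fentanyl and hydromorphone
against surgical nociception, and observational cohorts suggest the amount
given during surgery is associated with postoperative pain, opioid
consumption, length of stay, and longer-term opioid use. Quantifying those
associations from records requires a full inference chain:

1. **Exposure construction** — timestamped IV boluses are converted to
   effect-site concentration traces with linear compartmental PK models
   (an effect compartment equilibrating with plasma at rate *k*<sub>e0</sub>),
   and each patient's exposure is the window mean *C̄*<sub>e</sub> (ng/mL).
2. **Generalized propensity weighting** — each semicontinuous exposure
   (point mass at zero plus a log-normal positive part) gets a two-part
   conditional density model given confounders *x*; the stabilized weight
   is *f(E)/f(E|x)*, multiplied across the two near-independent drugs,
   with weights above the empirical 99.5th percentile discarded.
3. **Weighted outcome models** — proportional-odds ordinal regression for
   pain scores 0–10, two-part hurdle models (logistic + log-normal) for
   opioid consumption in MME, Cox proportional hazards (Efron ties) for
   times to event, and logistic regression for binary outcomes, on
   standardized covariates with one-hot categorical encoding.
4. **g-computation** — for an intervention such as "+100 µg fentanyl at
   the start of the window", the added bolus is pushed through the PK
   model, each patient's expected outcome is predicted under observed and
   counterfactual exposure, and the difference is averaged over the whole
   unweighted population; Cox expected times use a constant-baseline-hazard
   profile estimate *ĥ*<sub>0</sub> = Σwᵢdᵢ / Σwᵢtᵢexp(xᵢ′β̂). Percentile
   confidence intervals come from bootstrap resamples that rerun the whole
   chain.

Because no patient-level data of this kind is public, the package ships a
first-class synthetic-cohort generator with known ground truth that
emulates the field's reported structure: bimodal exposures with a point
mass at zero (7.3% zero fentanyl, 36.4% zero hydromorphone),
near-independent dual exposures, front-loaded fentanyl versus uniformly
timed hydromorphone boluses, and outcomes from all four model families.
See the methods vignette (`vignettes/methods.Rmd`) for the model details
and design rationale.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers; each stage
reads the previous stage's files under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic cohort + dosing records
Rscript analysis/02_exposures.R       # PK exposure reconstruction
Rscript analysis/03_weighting.R       # propensity weights + balance table
Rscript analysis/04_fit_models.R      # weighted outcome fits + forest table
Rscript analysis/05_counterfactual.R  # g-computation + bootstrap CIs
```

A 4,000-patient run prints:

```
simulated 4000 patients: 7.5% zero fentanyl, 36.5% zero hydromorphone, exposure r = 0.075
exposures recomputed for 4000 patients (max round-trip error 1.3e-14); median MME 9.5
stabilized weights: mean 1.000, 20 of 4000 trimmed (> 3.836); max |confounder corr| 0.239 unweighted -> 0.042 weighted
```

The mean stabilized weight of 1 says the weight model is internally
consistent; 20 = 0.5% of rows sit above the trim threshold; weighting
shrinks the worst confounder–exposure correlation from 0.24 to 0.04.
Stage 4 prints exponentiated exposure coefficients per 1 SD of exposure
(the forest-table analogue) — e.g. OR 0.78 for fentanyl on PACU maximum
pain, OR 0.84 for fentanyl on the odds of receiving any PACU opioid —
and stage 5 the counterfactual table:

```
  -0.873 (-1.060 to -0.664)  pacu_max_pain under +100 ug fentanyl [ordinal]
  -0.908 (-1.163 to -0.651)  pacu_total_mme under +100 ug fentanyl [hurdle]
  -70.691 (-95.798 to -45.114)  uncontrolled_pain_24h under +100 ug fentanyl [logistic]
```

read as: an additional 100 µg of intraoperative fentanyl at the window
start corresponds to a 0.87-point lower expected PACU maximum pain score,
0.91 MME less PACU opioid, and 71 fewer uncontrolled-pain cases per 1000
patients, with 95% bootstrap CIs — all under the generator's known ground
truth, which is what the test suite validates the chain against.

`run_pipeline()` performs the same chain in one call and writes
`balance.csv`, `forest.csv`, `table_counterfactual.csv`, and a
`manifest.json` with seeds and row counts; subgroup reruns are a
`row_filter` expression (e.g. `"bmi > 30"`), and alternative confounder
sets are alternative generator configurations.

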