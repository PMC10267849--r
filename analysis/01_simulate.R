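#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a synthetic perioperative cohort with the realistic (moderate
# confounding) preset: covariates of the kinds found in an anesthesia EHR,
# per-patient intraoperative bolus records for two opioids, window-mean
# effect-site exposures computed through the PK module, and outcomes from
# all four modeled families with known ground truth. Writes the stage
# outputs that every later stage reads.

library(opioidcf)

seed <- 20260919L
n <- 4000L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config("moderate")
sim <- generate_cohort(n, cfg, seed = seed)

write.csv(sim$cohort, file.path(out, "cohort.csv"), row.names = FALSE)
write_dosing_csv(sim$records, file.path(out, "dosing.csv"),
                 file.path(out, "windows.csv"))
jsonlite::write_json(
  list(seed = seed, n = n,
       zero_fentanyl_pct = 100 * mean(sim$cohort$mean_ce_fentanyl == 0),
       zero_hydromorphone_pct =
         100 * mean(sim$cohort$mean_ce_hydromorphone == 0),
       exposure_pearson_r = cor(sim$cohort$mean_ce_fentanyl,
                                sim$cohort$mean_ce_hydromorphone)),
  file.path(out, "simulation_summary.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "simulated %d patients: %.1f%% zero fentanyl, %.1f%% zero hydromorphone, exposure r = %.3f\n",
  n, 100 * mean(sim$cohort$mean_ce_fentanyl == 0),
  100 * mean(sim$cohort$mean_ce_hydromorphone == 0),
  cor(sim$cohort$mean_ce_fentanyl, sim$cohort$mean_ce_hydromorphone)))
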