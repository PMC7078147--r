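#!/usr/bin/env Rscript

# Step 2 — read, preprocess and classify the lesions.
#
# Applies the exclusion rules (baseline-only patients; measurements after
# tumor surgery), classifies every lesion into an organ class by the shipped
# keyword ruleset, merges classes with fewer than 30 patients into "Other",
# and writes the per-class cTL/iTL summary in the conventional "cTL (iTL)"
# layout for the whole cohort and the KRAS wild-type subset.

library(lesiondyn)

records <- read_lesion_table("scratch/sim/lesion_records.csv")
covariates <- read_covariate_table("scratch/sim/covariates.csv")

pre <- preprocess_lesions(records, covariates)
write_preprocess_report(pre$report, "results/tables/02_preprocess_report.json")
cat(sprintf(paste0(
  "Preprocessing: %d of %d measurements kept; %d patient(s) excluded as\n",
  "baseline-only, %d post-surgery measurement(s) dropped.\n"),
  pre$report$n_records_out, pre$report$n_records_in,
  pre$report$n_patients_baseline_only +
    pre$report$n_patients_baseline_only_after_surgery,
  pre$report$n_records_post_surgery))

classified <- classify_lesions(lesion_metadata(pre$records))
merged <- merge_rare_classes(classified, min_patients = 30)
if (nrow(merged$report) > 0) {
  cat("Merged into Other (fewer than 30 patients):",
      paste(sprintf("%s (%d)", merged$report$class_name,
                    merged$report$n_patients), collapse = ", "), "\n")
} else cat("No class fell below the 30-patient merge threshold.\n")

kras_wt <- covariates$patient_id[covariates$kras == "wt"]
tab <- class_summary(merged$classified,
                     subsets = list(ALL = covariates$patient_id,
                                    KRASwt = kras_wt))
write.csv(tab, "results/tables/02_class_summary.csv", row.names = FALSE)
write.csv(merged$classified, "scratch/sim/classified.csv", row.names = FALSE)

cat("\nClass summary (cTL (iTL)):\n")
print(tab[, c("class_name", "ALL", "KRASwt")], row.names = FALSE)
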