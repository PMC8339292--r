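#!/usr/bin/env Rscript
# Call receptor status from the normalized receptor-probe intensities
# (ER: probe 205225_at > 500; ERBB2: probe 216836_s_at > 4800) and select
# the analysis cohorts by subtype and documented treatment. Writes one
# sample-id list per cohort plus a JSON count summary under
# results/cohorts/.

suppressPackageStartupMessages(library(survscan))

clinical <- read.table("results/data/clinical.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
em <- read_expr_matrix("results/preprocessed/expression_clean.tsv",
                       setNames(clinical$dataset_id, clinical$sample_id))
calls <- assign_receptor_status(em)
cat("receptor calls:\n")
print(table(ER = calls$er_status, ERBB2 = calls$erbb2_status))

clin <- clinical[clinical$sample_id %in% colnames(em$values), ]
cohorts <- list(
  erpos_chemo = c("er_pos_erbb2_neg", "chemo_documented"),
  erpos_any_systemic = c("er_pos_erbb2_neg",
                         "any_systemic_treatment_documented"),
  erpos_untreated = c("er_pos_erbb2_neg", "untreated_documented"),
  basal_chemo = c("basal", "chemo_documented"),
  basal_adjuvant_chemo = c("basal", "adjuvant_chemo_documented"),
  basal_untreated = c("basal", "untreated_documented"))

dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)
counts <- list()
for (nm in names(cohorts)) {
  ids <- select_cohort(clin, calls, subtype = cohorts[[nm]][1],
                       treatment_rule = cohorts[[nm]][2])
  counts[[nm]] <- length(ids)
  writeLines(ids, file.path("results/cohorts", paste0(nm, ".txt")))
  cat(sprintf("%-22s n = %d\n", nm, length(ids)))
}
jsonlite::write_json(counts, "results/cohorts/cohort_counts.json",
                     auto_unbox = TRUE)
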