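#!/usr/bin/env Rscript
# Preprocess the simulated cohort: anchor every array to a mean intensity
# of 1000 over all probes, classify arrays by the five QC parameters
# (excluding biased arrays), and drop re-published duplicate arrays.
# Writes the QC report, the duplicate log and the cleaned matrix under
# results/preprocessed/.

suppressPackageStartupMessages(library(survscan))

clinical <- read.table("results/data/clinical.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
em <- read_expr_matrix("results/data/expression.tsv",
                       setNames(clinical$dataset_id, clinical$sample_id))
qc <- read.table("results/data/qc.tsv", header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)

em <- scale_normalize(em, target_mean = 1000)
statuses <- classify_qc(qc)
cat("QC labels:\n")
print(table(statuses$label))
em <- exclude_biased(em, statuses)

dedup <- remove_redundant(em)
cat(sprintf("dropped %d duplicate array(s)\n", nrow(dedup$dropped)))
em <- dedup$matrix
cat(sprintf("analysis matrix: %d probes x %d samples\n",
            nrow(em$values), ncol(em$values)))

dir.create("results/preprocessed", recursive = TRUE, showWarnings = FALSE)
statuses$failed_parameters <- vapply(statuses$failed_parameters, paste, "",
                                     collapse = ",")
write.table(statuses, "results/preprocessed/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dedup$dropped, "results/preprocessed/dropped_duplicates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_expr_matrix(em, "results/preprocessed/expression_clean.tsv")
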