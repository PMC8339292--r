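#!/usr/bin/env Rscript
# Compare prognostic gene lists between treatment settings: scan the
# documented-untreated ER-positive/ERBB2-negative cohort and report the
# overlap of its significant genes with the chemotherapy-treated list.
# Output under results/overlap/.

suppressPackageStartupMessages(library(survscan))

clinical <- read.table("results/data/clinical.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
em <- read_expr_matrix("results/preprocessed/expression_clean.tsv",
                       setNames(clinical$dataset_id, clinical$sample_id))
probe_map <- read.table("results/data/probe_map.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)

ids <- readLines("results/cohorts/erpos_untreated.txt")
clin <- clinical[match(ids, clinical$sample_id), ]
cat(sprintf("untreated cohort: n = %d (%d events)\n", length(ids),
            sum(clin$rfs_event)))
res <- scan_transcriptome(em_subset(em, samples = ids), clin$rfs_months,
                          clin$rfs_event, probe_map)
fl <- apply_filters(res, probe_map)
untreated_genes <- unique(fl$ranked$gene_symbol)
chemo_genes <- readLines("results/scan/gene_list.txt")

ov <- list_overlap(chemo_genes, untreated_genes)
cat(sprintf("chemo-treated list: %d genes; untreated list: %d genes\n",
            ov$n_a, ov$n_b))
cat(sprintf("shared: %d of %d combined (%.1f%%); unique to one list: %.1f%%\n",
            ov$n_shared, ov$n_combined, ov$pct_shared_of_combined,
            ov$pct_unique_to_one))

dir.create("results/overlap", recursive = TRUE, showWarnings = FALSE)
writeLines(untreated_genes, "results/overlap/untreated_gene_list.txt")
jsonlite::write_json(ov, "results/overlap/overlap_report.json",
                     auto_unbox = TRUE, digits = NA)
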