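pipeline_defaults <- function() {
  list(seed = 1L,
       outdir = NULL,
       simulate = NULL,
       inputs = NULL,
       normalization = list(target_mean = 1000),
       receptor = list(er_probe = ER_PROBE, er_cutoff = 500,
                       erbb2_probe = ERBB2_PROBE, erbb2_cutoff = 4800),
       cohort = list(subtype = "er_pos_erbb2_neg",
                     treatment_rule = "chemo_documented"),
       scan = list(ties = "efron", test = "score"),
       filters = list(fdr_max = 0.05, min_max_expression = 1000,
                      min_cutoff = 100))
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full biomarker-ranking pipeline
#'
#' Orchestrates the stages in fixed order: load (or simulate) inputs,
#' scaling normalization, QC classification with exclusion of biased
#' arrays, redundant-sample removal, receptor calling and cohort selection,
#' transcriptome-wide best-cutoff Cox scan with BH-FDR, filter cascade and
#' absolute-HR ranking. All stage outputs and a run manifest are written
#' under `outdir` when one is configured; any stage error aborts with the
#' stage name. Identical configuration and seed reproduce identical result
#' tables.
#'
#' @param config a configuration list or the path to a YAML file. Sections
#'   (all optional except one of `simulate`/`inputs`): `seed`, `outdir`,
#'   `simulate` (arguments to [sim_config()]), `inputs` (paths
#'   `expression`, `clinical`, `qc`, `probe_map`), `normalization`
#'   (`target_mean`), `receptor` (probes and cutoffs), `cohort` (`subtype`,
#'   `treatment_rule`), `scan` (`ties`, `test`), `filters` (`fdr_max`,
#'   `min_max_expression`, `min_cutoff`).
#' @return list with `manifest`, `ranked`, `report`, `results` (full scan
#'   table), `cohort_samples`, `qc_statuses`, `dropped_duplicates`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("stage 'load' failed: configure either `simulate` or `inputs`",
         call. = FALSE)

  loaded <- run_stage("load", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      cohort <- do.call(sim_config, sim_args)
      cohort <- simulate_cohort(cohort)
      list(matrix = cohort$matrix, clinical = cohort$clinical,
           qc = cohort$qc, probe_map = cohort$probe_map)
    } else {
      clinical <- read.table(cfg$inputs$clinical, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
      list(matrix = read_expr_matrix(cfg$inputs$expression,
             setNames(clinical$dataset_id, clinical$sample_id)),
           clinical = clinical,
           qc = read.table(cfg$inputs$qc, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE),
           probe_map = read.table(cfg$inputs$probe_map, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE))
    }
  })
  n_input <- ncol(loaded$matrix$values)

  em <- run_stage("normalize",
    scale_normalize(loaded$matrix,
                    target_mean = cfg$normalization$target_mean))

  statuses <- run_stage("qc", classify_qc(loaded$qc))
  em <- run_stage("qc", exclude_biased(em, statuses))
  n_biased <- sum(statuses$label == "biased")
  n_outlier <- sum(statuses$label == "outlier")

  dedup <- run_stage("deduplicate", remove_redundant(em))
  em <- dedup$matrix

  cohort_samples <- run_stage("cohort", {
    calls <- assign_receptor_status(
      em, er_probe = cfg$receptor$er_probe,
      erbb2_probe = cfg$receptor$erbb2_probe,
      er_cutoff = cfg$receptor$er_cutoff,
      erbb2_cutoff = cfg$receptor$erbb2_cutoff)
    ids <- select_cohort(loaded$clinical[
        loaded$clinical$sample_id %in% colnames(em$values), ], calls,
      subtype = cfg$cohort$subtype,
      treatment_rule = cfg$cohort$treatment_rule)
    if (length(ids) == 0)
      stop("selected cohort is empty (subtype = ", cfg$cohort$subtype,
           ", treatment rule = ", cfg$cohort$treatment_rule, ")")
    ids
  })

  results <- run_stage("scan", {
    emc <- em_subset(em, samples = cohort_samples)
    clin <- loaded$clinical[match(cohort_samples,
                                  loaded$clinical$sample_id), ]
    scan_transcriptome(emc, clin$rfs_months, clin$rfs_event,
                       loaded$probe_map, ties = cfg$scan$ties,
                       test = cfg$scan$test)
  })

  filtered <- run_stage("rank",
    apply_filters(results, loaded$probe_map,
                  fdr_max = cfg$filters$fdr_max,
                  min_max_expression = cfg$filters$min_max_expression,
                  min_cutoff = cfg$filters$min_cutoff))

  manifest <- list(
    package = "survscan",
    version = as.character(utils::packageVersion("survscan")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "outdir")],
    counts = list(n_samples_input = n_input,
                  n_probes = nrow(loaded$matrix$values),
                  n_outlier_flagged = n_outlier,
                  n_biased_excluded = n_biased,
                  n_duplicates_dropped = nrow(dedup$dropped),
                  n_samples_analysis = ncol(em$values),
                  n_cohort = length(cohort_samples),
                  n_scanned = nrow(results),
                  n_estimable = sum(results$estimable),
                  filter = filtered$report[
                    setdiff(names(filtered$report), "thresholds")],
                  n_ranked = nrow(filtered$ranked)))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    qc_out <- statuses
    qc_out$failed_parameters <- vapply(statuses$failed_parameters,
                                       paste, "", collapse = ",")
    write.table(qc_out, file.path(cfg$outdir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dedup$dropped,
                file.path(cfg$outdir, "dropped_duplicates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(cohort_samples,
               file.path(cfg$outdir, "cohort_samples.txt"))
    write.table(results, file.path(cfg$outdir, "scan_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(filtered$ranked,
                file.path(cfg$outdir, "ranked_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(unique(filtered$ranked$gene_symbol),
               file.path(cfg$outdir, "gene_list.txt"))
    jsonlite::write_json(filtered$report,
                         file.path(cfg$outdir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(manifest = manifest, ranked = filtered$ranked,
       report = filtered$report, results = results,
       cohort_samples = cohort_samples, qc_statuses = statuses,
       dropped_duplicates = dedup$dropped)
}

km_step_coords <- function(curve, xmax) {
  list(x = c(0, rep(curve$time, each = 2), xmax),
       y = c(1, 1, rep(curve$surv, each = 2)))
}

km_at_risk <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time >= tt)
    if (tt <= 0) curve$n
    else if (length(i)) unname(curve$n_risk[min(i)])
    else 0L
  }, numeric(1))
}

draw_km_panel <- function(curve_high, curve_low, annotations) {
  xmax <- max(curve_high$time, curve_low$time)
  graphics::par(mar = c(7, 4, 3, 1))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1.02),
                 xlab = paste0("Time (", curve_high$time_unit, ")"),
                 ylab = "Relapse-free survival probability",
                 main = if (!is.null(annotations$gene))
                   annotations$gene else "")
  ch <- km_step_coords(curve_high, xmax)
  cl <- km_step_coords(curve_low, xmax)
  graphics::lines(cl$x, cl$y, col = "black", lwd = 2)
  graphics::lines(ch$x, ch$y, col = "red3", lwd = 2)
  ann <- character(0)
  if (!is.null(annotations$cutoff))
    ann <- c(ann, sprintf("cutoff = %.6g", annotations$cutoff))
  if (!is.null(annotations$hr)) {
    s <- sprintf("HR = %.2f", annotations$hr)
    if (!is.null(annotations$ci))
      s <- paste0(s, sprintf(" (%.2f-%.2f)", annotations$ci[1],
                             annotations$ci[2]))
    ann <- c(ann, s)
  }
  if (!is.null(annotations$p))
    ann <- c(ann, sprintf("p = %.2g", annotations$p))
  graphics::legend("bottomleft", bty = "n",
                   legend = c(sprintf("high (n = %d)", curve_high$n),
                              sprintf("low (n = %d)", curve_low$n),
                              ann),
                   col = c("red3", "black", rep(NA, length(ann))),
                   lwd = c(2, 2, rep(NA, length(ann))))
  at <- pretty(c(0, xmax), n = 5)
  at <- at[at <= xmax]
  graphics::mtext("At risk:", side = 1, line = 4, adj = 0, cex = 0.8)
  graphics::mtext(km_at_risk(curve_high, at), side = 1, line = 5, at = at,
                  col = "red3", cex = 0.8)
  graphics::mtext(km_at_risk(curve_low, at), side = 1, line = 6, at = at,
                  cex = 0.8)
}

#' Render a two-arm Kaplan-Meier plot to SVG and PNG
#'
#' Draws the high- and low-expression arms as step curves with at-risk
#' counts and an annotation box (gene, cutoff, HR with confidence interval,
#' p-value), written as `<file_base>.svg` and `<file_base>.png`.
#'
#' @param curve_high,curve_low [km_curve()] objects for the two arms; their
#'   time units must match.
#' @param annotations optional list with any of `gene`, `cutoff`, `hr`,
#'   `ci` (length-2), `p`.
#' @param file_base output path without extension.
#' @return character vector of the two files written, invisibly.
#' @export
render_km <- function(curve_high, curve_low, annotations = list(),
                      file_base) {
  if (!inherits(curve_high, "km_curve") || !inherits(curve_low, "km_curve"))
    stop("both arms must be km_curve objects")
  if (!identical(curve_high$time_unit, curve_low$time_unit))
    stop("mismatched time units: ", curve_high$time_unit, " vs ",
         curve_low$time_unit)
  paths <- paste0(file_base, c(".svg", ".png"))
  grDevices::svg(paths[1], width = 7, height = 6)
  draw_km_panel(curve_high, curve_low, annotations)
  grDevices::dev.off()
  grDevices::png(paths[2], width = 700, height = 600)
  draw_km_panel(curve_high, curve_low, annotations)
  grDevices::dev.off()
  invisible(paths)
}
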