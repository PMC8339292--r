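#' Absolute (direction-symmetric) hazard ratio
#'
#' Treats protective and risk directions symmetrically by inverting hazard
#' ratios below one: `max(hr, 1/hr)`. A reported HR of 0.3 corresponds to
#' an absolute HR of 3.33.
#'
#' @param hr positive hazard ratio(s).
#' @return numeric vector of values >= 1.
#' @export
absolute_hr <- function(hr) {
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("hazard ratios must be positive")
  pmax(hr, 1 / hr)
}

#' Filter cascade and absolute-HR ranking of scan results
#'
#' Applies, in order: (1) keep probes mapped to a gene symbol; (2) FDR
#' q-value at most `fdr_max`; (3) maximal expression strictly over
#' `min_max_expression` (robustly expressed genes); (4) best cutoff
#' strictly over `min_cutoff` (cutoffs clear of background noise); (5) keep
#' only probes flagged as the best probe of their gene. Survivors are
#' ranked by absolute hazard ratio, descending. Non-estimable probes never
#' survive stage 2 (their q-value is undefined).
#'
#' @param results a `scan_result` data.frame from [scan_transcriptome()].
#' @param probe_map data.frame with `probe_id`, `gene_symbol`,
#'   `is_best_probe`.
#' @param fdr_max,min_max_expression,min_cutoff cascade thresholds.
#' @return list with `ranked` (surviving rows plus `abs_hr` and `rank`) and
#'   `report`, the per-stage counts (`n_gene_mapped`, `n_fdr_pass`,
#'   `n_maxexpr_pass`, `n_cutoff_pass`, `n_bestprobe_pass`) with the
#'   thresholds used.
#' @export
apply_filters <- function(results, probe_map, fdr_max = 0.05,
                          min_max_expression = 1000, min_cutoff = 100) {
  pm_gene <- setNames(probe_map$gene_symbol, probe_map$probe_id)
  pm_best <- setNames(probe_map$is_best_probe, probe_map$probe_id)
  r <- results
  gene <- pm_gene[r$probe_id]
  r <- r[!is.na(gene) & gene != "", , drop = FALSE]
  n_gene_mapped <- nrow(r)
  r <- r[!is.na(r$fdr_q) & r$fdr_q <= fdr_max, , drop = FALSE]
  n_fdr_pass <- nrow(r)
  r <- r[r$max_expression > min_max_expression, , drop = FALSE]
  n_maxexpr_pass <- nrow(r)
  r <- r[r$best_cutoff > min_cutoff, , drop = FALSE]
  n_cutoff_pass <- nrow(r)
  r <- r[pm_best[r$probe_id] %in% TRUE, , drop = FALSE]
  n_bestprobe_pass <- nrow(r)
  if (nrow(r)) {
    r$abs_hr <- absolute_hr(r$hr)
    r <- r[order(-r$abs_hr, r$p_value, r$probe_id), , drop = FALSE]
    r$rank <- seq_len(nrow(r))
  } else {
    r$abs_hr <- numeric(0)
    r$rank <- integer(0)
  }
  rownames(r) <- NULL
  list(ranked = r,
       report = list(n_gene_mapped = n_gene_mapped,
                     n_fdr_pass = n_fdr_pass,
                     n_maxexpr_pass = n_maxexpr_pass,
                     n_cutoff_pass = n_cutoff_pass,
                     n_bestprobe_pass = n_bestprobe_pass,
                     thresholds = list(fdr_max = fdr_max,
                                       min_max_expression = min_max_expression,
                                       min_cutoff = min_cutoff)))
}

#' Overlap statistics between two gene lists
#'
#' Reports the shared and unique fractions of two deduplicated gene-symbol
#' lists relative to their union, with percentages rounded half-up to one
#' decimal.
#'
#' @param list_a,list_b character vectors of gene symbols.
#' @return list with `n_a`, `n_b`, `n_shared`, `n_combined`,
#'   `pct_shared_of_combined`, `pct_unique_to_one`.
#' @export
list_overlap <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  n_shared <- length(intersect(a, b))
  n_combined <- length(union(a, b))
  pct_shared <- if (n_combined) round_half_up(100 * n_shared / n_combined)
                else 0
  list(n_a = length(a), n_b = length(b), n_shared = n_shared,
       n_combined = n_combined,
       pct_shared_of_combined = pct_shared,
       pct_unique_to_one = if (n_combined)
         round_half_up(100 * (n_combined - n_shared) / n_combined) else 0)
}
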