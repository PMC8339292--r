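# Continuous QC parameters checked against the cohort-wide central 95% range.
QC_CONTINUOUS <- c("background", "raw_q", "percent_present", "ratio_3to5")

#' Second-pass scaling normalization
#'
#' Rescales every array (column) so that its mean intensity over a fixed set
#' of reference probes equals `target_mean`. This is the batch-effect
#' reduction step applied after per-array summarization: with all arrays
#' anchored to the same mean over the same probe set, multiplicative scale
#' differences between datasets drop out.
#'
#' @param matrix an [expr_matrix()].
#' @param reference_probes probe ids defining the anchoring set; defaults to
#'   all probes in the matrix.
#' @param target_mean target per-array mean over the reference probes
#'   (intensity units).
#' @return an [expr_matrix()] with every column scaled.
#' @export
scale_normalize <- function(matrix, reference_probes = NULL,
                            target_mean = 1000) {
  stopifnot(inherits(matrix, "expr_matrix"), target_mean > 0)
  v <- matrix$values
  if (is.null(reference_probes)) reference_probes <- rownames(v)
  missing <- setdiff(reference_probes, rownames(v))
  if (length(missing))
    stop("reference probe(s) not in matrix: ",
         paste(missing, collapse = ", "))
  ref_means <- colMeans(v[reference_probes, , drop = FALSE])
  bad <- ref_means <= 0
  if (any(bad))
    stop("non-positive reference mean for sample(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  v <- sweep(v, 2, target_mean / ref_means, `*`)
  expr_matrix(v, matrix$dataset_id, matrix$dataset_order)
}

#' Classify arrays by five quality-control parameters
#'
#' An array passes a continuous parameter (background, raw Q, percent
#' present calls, GAPDH/ACTB 3'/5' ratio) when its value is strictly
#' positive and lies within the central 95% range of that parameter across
#' all arrays (2.5th to 97.5th percentile, inclusive, linear-interpolation
#' percentiles). The BioB/C/D spike flag fails when the spikes are absent.
#' Arrays failing exactly one parameter are `outlier`s (flagged but
#' retained downstream); arrays failing two or more are `biased` and are
#' excluded from statistical analyses.
#'
#' @param qc data.frame with columns `sample_id`, `background`, `raw_q`,
#'   `percent_present`, `biob_spikes_present` (logical), `ratio_3to5`.
#' @return data.frame with columns `sample_id`, `label` (pass / outlier /
#'   biased), `n_failed` and list-column `failed_parameters`.
#' @export
classify_qc <- function(qc) {
  needed <- c("sample_id", QC_CONTINUOUS, "biob_spikes_present")
  missing <- setdiff(needed, names(qc))
  if (length(missing))
    stop("QC table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(qc) < 1) stop("QC table must have at least one sample")
  na_rows <- qc$sample_id[!stats::complete.cases(qc[, needed])]
  if (length(na_rows))
    stop("missing QC values for sample(s): ",
         paste(na_rows, collapse = ", "))
  fails <- matrix(FALSE, nrow(qc), length(QC_CONTINUOUS) + 1,
                  dimnames = list(qc$sample_id,
                                  c(QC_CONTINUOUS, "biob_spikes_present")))
  for (p in QC_CONTINUOUS) {
    x <- qc[[p]]
    rng <- quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
    fails[, p] <- x <= 0 | x < rng[1] | x > rng[2]
  }
  fails[, "biob_spikes_present"] <- !qc$biob_spikes_present
  n_failed <- rowSums(fails)
  label <- ifelse(n_failed == 0, "pass",
                  ifelse(n_failed == 1, "outlier", "biased"))
  failed_parameters <- lapply(seq_len(nrow(qc)),
                              function(i) colnames(fails)[fails[i, ]])
  out <- data.frame(sample_id = qc$sample_id, label = label,
                    n_failed = as.integer(n_failed),
                    stringsAsFactors = FALSE)
  out$failed_parameters <- failed_parameters
  out
}

#' Remove redundant (re-published) arrays
#'
#' Arrays with identical expression vectors (compared after rounding to six
#' significant digits, which guards against serialization noise) are
#' collapsed to a single copy: the one from the dataset with the smallest
#' publication order, ties broken by lexicographically smallest sample id.
#'
#' @param matrix an [expr_matrix()].
#' @return list with `matrix` (deduplicated [expr_matrix()]) and `dropped`,
#'   a data.frame of (`kept_sample_id`, `dropped_sample_id`) pairs.
#' @export
remove_redundant <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  n <- ncol(v)
  empty <- data.frame(kept_sample_id = character(0),
                      dropped_sample_id = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(list(matrix = matrix, dropped = empty))
  keys <- vapply(seq_len(n), function(j)
    paste(signif(v[, j], 6), collapse = "\r"), character(1))
  ord <- matrix$dataset_order[matrix$dataset_id[colnames(v)]]
  groups <- split(seq_len(n), keys)
  kept <- logical(n)
  dropped_list <- list()
  for (g in groups) {
    if (length(g) == 1) { kept[g] <- TRUE; next }
    ids <- colnames(v)[g]
    first <- g[order(ord[g], ids)][1]
    kept[first] <- TRUE
    others <- setdiff(g, first)
    dropped_list[[length(dropped_list) + 1]] <- data.frame(
      kept_sample_id = colnames(v)[first],
      dropped_sample_id = colnames(v)[others],
      stringsAsFactors = FALSE)
  }
  dropped <- if (length(dropped_list)) do.call(rbind, dropped_list)
             else empty
  dropped <- dropped[order(dropped$dropped_sample_id), , drop = FALSE]
  rownames(dropped) <- NULL
  list(matrix = em_subset(matrix, samples = colnames(v)[kept]),
       dropped = dropped)
}

#' Exclude biased arrays from a matrix
#'
#' Removes every sample labeled `biased` by [classify_qc()]; arrays labeled
#' `outlier` (a single failing parameter) are retained.
#'
#' @param matrix an [expr_matrix()].
#' @param statuses data.frame from [classify_qc()], covering all samples in
#'   `matrix`.
#' @return an [expr_matrix()] without the biased samples.
#' @export
exclude_biased <- function(matrix, statuses) {
  stopifnot(inherits(matrix, "expr_matrix"))
  samples <- colnames(matrix$values)
  missing <- setdiff(samples, statuses$sample_id)
  if (length(missing))
    stop("QC status missing for sample(s): ",
         paste(missing, collapse = ", "))
  biased <- statuses$sample_id[statuses$label == "biased"]
  em_subset(matrix, samples = setdiff(samples, biased))
}
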