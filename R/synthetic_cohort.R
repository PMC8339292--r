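# Probe ids used for receptor-status calling (Affymetrix GPL96/570/571).
ER_PROBE <- "205225_at"
ERBB2_PROBE <- "216836_s_at"

#' Configuration for the synthetic multi-dataset cohort generator
#'
#' Defines the study conditions a simulated cohort is drawn under: number of
#' datasets (series) and samples per dataset, transcriptome size, planted
#' prognostic effects, the survival/censoring model, per-dataset batch
#' scales, receptor-status and treatment mix, and planted data-quality
#' defects (duplicated arrays, QC-failing arrays).
#'
#' Planted prognostic probes are co-expressed readouts of a single latent
#' binary risk factor (a prognostic "module"), each with a random direction;
#' the hazard acts through that latent factor with log hazard ratio
#' `true_log_hr`, so each planted probe's own dichotomization at
#' `planted_quantile` carries a marginal log hazard ratio of
#' `+/- true_log_hr` and parameter recovery is well defined.
#'
#' @param n_datasets,samples_per_dataset cohort structure; total base
#'   samples = `n_datasets * samples_per_dataset`.
#' @param n_probes number of generic probes; two receptor probes
#'   (`205225_at`, `216836_s_at`) are appended on top.
#' @param n_prognostic number of planted prognostic probes.
#' @param true_log_hr magnitude of the planted log hazard ratio; the sign is
#'   drawn at random per planted probe.
#' @param baseline_median_survival baseline median event time, months.
#' @param censoring_fraction_target target fraction of right-censored
#'   samples, in `[0, 1)`; censoring times are uniform on `(0, c)` with `c`
#'   calibrated by bisection.
#' @param batch_scale_range range of the per-dataset multiplicative scale
#'   applied to all probes of a dataset.
#' @param er_positive_fraction,erbb2_positive_fraction expected fractions of
#'   receptor-positive samples.
#' @param treated_fraction,untreated_fraction expected fractions of samples
#'   with documented systemic treatment / documented absence of systemic
#'   treatment; the remainder has unknown treatment. Must sum to at most 1.
#' @param n_duplicates number of exact array copies appended to the last
#'   dataset (re-published samples).
#' @param n_outlier_arrays,n_biased_arrays number of arrays planted with
#'   exactly one / at least two QC parameters far outside the cohort range.
#' @param weibull_shape baseline Weibull shape (1 = exponential).
#' @param planted_quantile quantile of each planted probe's expression at
#'   which its true dichotomization sits (default median).
#' @param seed master seed; each generator stage draws from its own stream
#'   derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 5, samples_per_dataset = 80,
                       n_probes = 1000, n_prognostic = 20,
                       true_log_hr = log(2.5),
                       baseline_median_survival = 60,
                       censoring_fraction_target = 0.3,
                       batch_scale_range = c(0.6, 1.8),
                       er_positive_fraction = 0.7,
                       erbb2_positive_fraction = 0.15,
                       treated_fraction = 0.5, untreated_fraction = 0.3,
                       n_duplicates = 0, n_outlier_arrays = 0,
                       n_biased_arrays = 0, weibull_shape = 1,
                       planted_quantile = 0.5, seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              samples_per_dataset = as.integer(samples_per_dataset),
              n_probes = as.integer(n_probes),
              n_prognostic = as.integer(n_prognostic),
              true_log_hr = true_log_hr,
              baseline_median_survival = baseline_median_survival,
              censoring_fraction_target = censoring_fraction_target,
              batch_scale_range = batch_scale_range,
              er_positive_fraction = er_positive_fraction,
              erbb2_positive_fraction = erbb2_positive_fraction,
              treated_fraction = treated_fraction,
              untreated_fraction = untreated_fraction,
              n_duplicates = as.integer(n_duplicates),
              n_outlier_arrays = as.integer(n_outlier_arrays),
              n_biased_arrays = as.integer(n_biased_arrays),
              weibull_shape = weibull_shape,
              planted_quantile = planted_quantile,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  cfg_stop <- function(msg) stop("invalid simulation config: ", msg,
                                 call. = FALSE)
  with(cfg, {
    if (n_datasets < 1 || samples_per_dataset < 1 || n_probes < 1)
      cfg_stop("counts must be positive")
    n_base <- n_datasets * samples_per_dataset
    if (n_prognostic < 0 || n_prognostic > n_probes)
      cfg_stop("n_prognostic must lie in [0, n_probes]")
    if (!is.finite(true_log_hr)) cfg_stop("true_log_hr must be finite")
    if (baseline_median_survival <= 0)
      cfg_stop("baseline_median_survival must be > 0")
    if (censoring_fraction_target < 0 || censoring_fraction_target >= 1)
      cfg_stop("censoring_fraction_target must be in [0, 1)")
    if (length(batch_scale_range) != 2 || any(batch_scale_range <= 0) ||
        batch_scale_range[1] > batch_scale_range[2])
      cfg_stop("batch_scale_range must be an increasing pair of positives")
    for (f in c(er_positive_fraction, erbb2_positive_fraction,
                treated_fraction, untreated_fraction))
      if (f < 0 || f > 1) cfg_stop("fractions must lie in [0, 1]")
    if (treated_fraction + untreated_fraction > 1)
      cfg_stop("treated_fraction + untreated_fraction must be <= 1")
    if (n_duplicates < 0 || n_duplicates > n_base)
      cfg_stop("n_duplicates exceeds the sample budget")
    if (n_outlier_arrays < 0 || n_biased_arrays < 0 ||
        n_outlier_arrays + n_biased_arrays > n_base)
      cfg_stop("planted QC failures exceed the sample budget")
    if (weibull_shape <= 0) cfg_stop("weibull_shape must be > 0")
    if (planted_quantile <= 0 || planted_quantile >= 1)
      cfg_stop("planted_quantile must be in (0, 1)")
  })
  invisible(cfg)
}

#' Draw proportional-hazards survival times with independent right censoring
#'
#' Event times come from a Weibull (exponential by default) baseline whose
#' median equals `baseline_median_survival`, scaled on the hazard scale by
#' `exp(linear_predictor)`. Censoring times are uniform on `(0, c)` with `c`
#' calibrated by bisection so that the expected censored fraction matches
#' `censoring_fraction_target` for the realized event times.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param linear_predictor numeric vector, one value per sample.
#' @param config a [sim_config()].
#' @return data.frame with columns `time` (months, strictly positive) and
#'   `event` (1 = event, 0 = censored).
#' @export
simulate_survival <- function(linear_predictor, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(linear_predictor) == 0)
    stop("linear_predictor must be non-empty")
  if (any(!is.finite(linear_predictor)))
    stop("non-finite linear predictor")
  shape <- config$weibull_shape
  lambda0 <- log(2) / config$baseline_median_survival^shape
  u <- runif(length(linear_predictor))
  t_event <- (-log(u) / (lambda0 * exp(linear_predictor)))^(1 / shape)
  t_event <- pmax(t_event, .Machine$double.eps)
  target <- config$censoring_fraction_target
  if (target <= 0)
    return(data.frame(time = t_event,
                      event = rep(1L, length(t_event))))
  # expected censored fraction under C ~ U(0, c): mean(min(T/c, 1))
  frac <- function(cc) mean(pmin(t_event / cc, 1))
  lo <- min(t_event) * 1e-3
  hi <- max(t_event) * 1e3
  while (frac(hi) > target) hi <- hi * 10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) > target) lo <- mid else hi <- mid
  }
  cc <- sqrt(lo * hi)
  t_cens <- runif(length(t_event), 0, cc)
  data.frame(time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a multi-dataset expression cohort with planted prognostic genes
#'
#' Generates MAS5-like non-negative intensities (log-normal marginals) for
#' probes across several datasets with per-dataset multiplicative batch
#' scales, proportional-hazards relapse-free survival driven by a planted
#' latent risk factor read out by `n_prognostic` co-expressed probes,
#' receptor-status and treatment annotations, a five-parameter QC table with
#' planted outlier/biased arrays, exact duplicated arrays assigned to the
#' last dataset, and a probe-to-gene map with best-probe flags.
#'
#' Each generator stage draws from its own RNG stream derived from
#' `config$seed`, so identical configs reproduce identical cohorts.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cohort` with elements `matrix`
#'   ([expr_matrix()]), `clinical`, `qc`, `probe_map` (data.frames), `truth`
#'   (ground truth: planted probes and effects, per-sample linear predictor,
#'   planted-high indicators, duplicate pairs, QC-failure labels, intended
#'   receptor status) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  k <- config$n_datasets
  spd <- config$samples_per_dataset
  n <- k * spd
  ds_ids <- sprintf("D%02d", seq_len(k))
  ds_of <- rep(ds_ids, each = spd)
  sample_ids <- paste0(ds_of, "_S", formatC(rep(seq_len(spd), k),
                                            width = 3, flag = "0"))

  # --- phenotype stream: receptor status, latent risk, treatment ---------
  set.seed(stream_seed(config$seed, "phenotype"))
  er_pos <- runif(n) < config$er_positive_fraction
  erbb2_pos <- runif(n) < config$erbb2_positive_fraction
  z_risk <- rbinom(n, 1L, 0.5)
  u_treat <- runif(n)
  treated <- u_treat < config$treated_fraction
  untreated <- !treated &
    u_treat < config$treated_fraction + config$untreated_fraction
  # treated samples get chemotherapy and/or endocrine therapy
  chemo <- treated & (runif(n) < 0.75)
  endocrine <- treated & (runif(n) < 0.5)
  endocrine[treated & !chemo & !endocrine] <- TRUE
  adjuvant <- chemo & (runif(n) < 0.7)
  chemotherapy <- ifelse(treated, ifelse(chemo, "yes", "no"),
                         ifelse(untreated, "no", "unknown"))
  endocrine_therapy <- ifelse(treated, ifelse(endocrine, "yes", "no"),
                              ifelse(untreated, "no", "unknown"))
  adjuvant_setting <- ifelse(chemo, ifelse(adjuvant, "yes", "no"),
                             ifelse(untreated, "no", "unknown"))
  systemically_untreated <- ifelse(untreated, "yes",
                                   ifelse(treated, "no", "unknown"))

  # --- expression stream -------------------------------------------------
  set.seed(stream_seed(config$seed, "expression"))
  ng <- config$n_probes
  probe_ids <- sprintf("P%05d", seq_len(ng))
  mu <- runif(ng, log(30), log(3000))
  sdlog <- runif(ng, 0.6, 1.1)
  logv <- mu + sdlog * matrix(rnorm(ng * n), nrow = ng)
  planted <- character(0)
  true_lhr <- numeric(0)
  if (config$n_prognostic > 0) {
    planted <- sort(sample(probe_ids, config$n_prognostic))
    orient <- ifelse(runif(config$n_prognostic) < 0.5, 1, -1)
    true_lhr <- setNames(orient * abs(config$true_log_hr), planted)
    # planted probes: well-expressed bimodal readouts of the latent factor
    for (i in seq_along(planted)) {
      zo <- if (orient[i] > 0) z_risk else 1L - z_risk
      logv[match(planted[i], probe_ids), ] <-
        rnorm(n, log(300) + 2.0 * zo, 0.5)
    }
  }
  values <- exp(logv)
  er_vals <- exp(ifelse(er_pos, rnorm(n, log(2500), 0.35),
                        rnorm(n, log(120), 0.4)))
  erbb2_vals <- exp(ifelse(erbb2_pos, rnorm(n, log(9000), 0.3),
                           rnorm(n, log(1200), 0.4)))
  values <- rbind(values, matrix(er_vals, nrow = 1),
                  matrix(erbb2_vals, nrow = 1))
  rownames(values) <- c(probe_ids, ER_PROBE, ERBB2_PROBE)
  colnames(values) <- sample_ids

  # true dichotomization of each planted probe, pre batch scale
  planted_high <- NULL
  if (length(planted)) {
    planted_high <- t(vapply(planted, function(p) {
      x <- values[p, ]
      x > quantile(x, config$planted_quantile, type = 7)
    }, logical(n)))
    rownames(planted_high) <- planted
  }

  # --- batch stream: per-dataset multiplicative scale --------------------
  set.seed(stream_seed(config$seed, "batch"))
  scales <- setNames(runif(k, config$batch_scale_range[1],
                           config$batch_scale_range[2]), ds_ids)
  values <- sweep(values, 2, scales[ds_of], `*`)

  # --- survival stream ---------------------------------------------------
  lp <- abs(config$true_log_hr) * z_risk
  if (config$n_prognostic == 0) lp <- rep(0, n)
  set.seed(stream_seed(config$seed, "survival"))
  surv <- simulate_survival(lp, config)

  # --- QC stream ---------------------------------------------------------
  set.seed(stream_seed(config$seed, "qc"))
  qc_specs <- list(background = c(55, 6), raw_q = c(2.4, 0.35),
                   percent_present = c(46, 4), ratio_3to5 = c(1.25, 0.2))
  # clean arrays: the four continuous parameters are comonotone by
  # cyclically shifted ranks, so no clean array sits in the outer tail of
  # two parameters at once and only planted arrays can be "biased"
  base_perm <- sample.int(n)
  shift <- max(1L, n %/% 4L)
  qc_vals <- matrix(0, n, 4, dimnames = list(sample_ids, names(qc_specs)))
  for (j in seq_along(qc_specs)) {
    sp <- qc_specs[[j]]
    vals <- sort(rnorm(n, sp[1], sp[2]))
    ranks <- ((base_perm - 1L + (j - 1L) * shift) %% n) + 1L
    qc_vals[, j] <- vals[ranks]
  }
  n_fail <- config$n_outlier_arrays + config$n_biased_arrays
  qc_fail_labels <- character(0)
  if (n_fail > 0) {
    fail_idx <- sample.int(n, n_fail)
    out_idx <- head(fail_idx, config$n_outlier_arrays)
    bias_idx <- fail_idx[seq_len(config$n_biased_arrays) +
                           config$n_outlier_arrays]
    centers <- vapply(qc_specs, `[`, 0, 1)
    far <- vapply(qc_specs, function(sp) sp[1] + 12 * sp[2], 0)
    for (ii in seq_along(out_idx)) {
      j <- ((ii - 1L) %% 4L) + 1L
      qc_vals[out_idx[ii], ] <- centers
      qc_vals[out_idx[ii], j] <- far[j]
    }
    for (ii in seq_along(bias_idx)) {
      qc_vals[bias_idx[ii], ] <- centers
      qc_vals[bias_idx[ii], c("background", "ratio_3to5")] <-
        far[c("background", "ratio_3to5")]
    }
    qc_fail_labels <- setNames(
      c(rep("outlier", length(out_idx)), rep("biased", length(bias_idx))),
      sample_ids[c(out_idx, bias_idx)])
  }
  qc <- data.frame(sample_id = sample_ids,
                   background = qc_vals[, "background"],
                   raw_q = qc_vals[, "raw_q"],
                   percent_present = qc_vals[, "percent_present"],
                   biob_spikes_present = TRUE,
                   ratio_3to5 = qc_vals[, "ratio_3to5"],
                   row.names = NULL, stringsAsFactors = FALSE)

  clinical <- data.frame(sample_id = sample_ids, dataset_id = ds_of,
                         rfs_months = surv$time, rfs_event = surv$event,
                         chemotherapy = chemotherapy,
                         endocrine_therapy = endocrine_therapy,
                         adjuvant_setting = adjuvant_setting,
                         systemically_untreated = systemically_untreated,
                         stringsAsFactors = FALSE)

  # --- duplicates stream: exact copies republished in the last dataset ---
  set.seed(stream_seed(config$seed, "duplicates"))
  duplicate_pairs <- data.frame(original = character(0), copy = character(0),
                                stringsAsFactors = FALSE)
  dataset_id <- setNames(ds_of, sample_ids)
  if (config$n_duplicates > 0) {
    pool <- if (k >= 2) sample_ids[ds_of != ds_ids[k]] else sample_ids
    originals <- sample(pool, min(config$n_duplicates, length(pool)))
    copies <- paste0(originals, "_dup")
    values <- cbind(values, values[, originals, drop = FALSE])
    colnames(values) <- c(sample_ids, copies)
    dataset_id <- c(dataset_id, setNames(rep(ds_ids[k], length(copies)),
                                         copies))
    dup_clin <- clinical[match(originals, clinical$sample_id), ]
    dup_clin$sample_id <- copies
    dup_clin$dataset_id <- ds_ids[k]
    clinical <- rbind(clinical, dup_clin)
    centers <- vapply(qc_specs, `[`, 0, 1)
    dup_qc <- data.frame(sample_id = copies, background = centers[1],
                         raw_q = centers[2], percent_present = centers[3],
                         biob_spikes_present = TRUE, ratio_3to5 = centers[4],
                         row.names = NULL, stringsAsFactors = FALSE)
    qc <- rbind(qc, dup_qc)
    duplicate_pairs <- data.frame(original = originals, copy = copies,
                                  stringsAsFactors = FALSE)
    rownames(clinical) <- NULL
  }

  # --- probe map stream --------------------------------------------------
  set.seed(stream_seed(config$seed, "probe_map"))
  non_planted <- setdiff(probe_ids, planted)
  n_unmapped <- min(round(0.1 * ng), length(non_planted))
  unmapped <- if (n_unmapped > 0) sample(non_planted, n_unmapped)
              else character(0)
  mapped <- setdiff(probe_ids, unmapped)
  sec_pool <- setdiff(mapped, planted)
  n_secondary <- min(round(0.15 * length(mapped)), length(sec_pool))
  secondary <- if (n_secondary > 0) sample(sec_pool, n_secondary)
               else character(0)
  primary <- setdiff(mapped, secondary)
  gene_of <- setNames(rep(NA_character_, ng), probe_ids)
  gene_of[primary] <- sprintf("GENE%05d", seq_along(primary))
  if (length(secondary))
    gene_of[secondary] <- sample(gene_of[primary], length(secondary),
                                 replace = TRUE)
  probe_map <- data.frame(
    probe_id = c(probe_ids, ER_PROBE, ERBB2_PROBE),
    gene_symbol = c(unname(gene_of), "ESR1", "ERBB2"),
    is_best_probe = c(probe_ids %in% primary, TRUE, TRUE),
    stringsAsFactors = FALSE)

  em <- expr_matrix(values, dataset_id,
                    setNames(seq_len(k), ds_ids))
  truth <- list(prognostic_probe_ids = planted,
                true_log_hr = true_lhr,
                linear_predictor = setNames(lp, sample_ids),
                latent_risk = setNames(z_risk, sample_ids),
                planted_high = planted_high,
                duplicate_pairs = duplicate_pairs,
                qc_fail_labels = qc_fail_labels,
                er_status = setNames(ifelse(er_pos, "positive", "negative"),
                                     sample_ids),
                erbb2_status = setNames(ifelse(erbb2_pos, "positive",
                                               "negative"), sample_ids),
                batch_scales = scales)
  structure(list(matrix = em, clinical = clinical, qc = qc,
                 probe_map = probe_map, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(paste0("<sim_cohort> %d probes x %d samples, %d dataset(s), ",
                     "%d planted prognostic probe(s)\n"),
              nrow(x$matrix$values), ncol(x$matrix$values),
              x$config$n_datasets, length(x$truth$prognostic_probe_ids)))
  invisible(x)
}

#' Write a simulated cohort to tab-separated files plus a ground-truth JSON
#'
#' Writes `expression.tsv` (probes x samples), `clinical.tsv`, `qc.tsv`,
#' `probe_map.tsv` and `ground_truth.json` under `dir`.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expr_matrix(cohort$matrix, file.path(dir, "expression.tsv"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$qc, file.path(dir, "qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$probe_map, file.path(dir, "probe_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  gt <- list(
    prognostic_probe_ids = truth$prognostic_probe_ids,
    true_log_hr = as.list(truth$true_log_hr),
    linear_predictor = as.list(truth$linear_predictor),
    duplicate_pairs = truth$duplicate_pairs,
    qc_fail_labels = as.list(truth$qc_fail_labels),
    planted_high_samples = if (is.null(truth$planted_high)) list() else
      lapply(rownames(truth$planted_high), function(p)
        names(which(truth$planted_high[p, ]))))
  if (length(gt$planted_high_samples))
    names(gt$planted_high_samples) <- rownames(truth$planted_high)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
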