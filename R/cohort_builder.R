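#' Call receptor status from probe intensities
#'
#' Estrogen-receptor and ERBB2 status are assigned per sample from the
#' normalized intensity of a dedicated probe against a fixed cutoff:
#' strictly above the cutoff is positive, at or below is negative. Defaults
#' use probe `205225_at` (ESR1) at 500 and probe `216836_s_at` (ERBB2) at
#' 4800, the established intensity thresholds for MAS5-scaled GPL96-family
#' arrays anchored to a mean of 1000.
#'
#' @param matrix an [expr_matrix()] of normalized intensities.
#' @param er_probe,erbb2_probe probe ids used for the two calls.
#' @param er_cutoff,erbb2_cutoff intensity cutoffs; positivity is strict
#'   (`value > cutoff`).
#' @return data.frame with columns `sample_id`, `er_status`,
#'   `erbb2_status` (`"positive"` / `"negative"`), `er_probe_value`,
#'   `erbb2_probe_value`.
#' @export
assign_receptor_status <- function(matrix, er_probe = ER_PROBE,
                                   erbb2_probe = ERBB2_PROBE,
                                   er_cutoff = 500, erbb2_cutoff = 4800) {
  stopifnot(inherits(matrix, "expr_matrix"))
  for (p in c(er_probe, erbb2_probe))
    if (!p %in% rownames(matrix$values))
      stop("probe not in matrix: ", p)
  er_v <- matrix$values[er_probe, ]
  erbb2_v <- matrix$values[erbb2_probe, ]
  data.frame(sample_id = colnames(matrix$values),
             er_status = ifelse(er_v > er_cutoff, "positive", "negative"),
             erbb2_status = ifelse(erbb2_v > erbb2_cutoff, "positive",
                                   "negative"),
             er_probe_value = unname(er_v),
             erbb2_probe_value = unname(erbb2_v),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select an analysis cohort by molecular subtype and documented treatment
#'
#' Applies the subtype filter (`er_pos_erbb2_neg`: ER positive and ERBB2
#' negative; `basal`: negative for both receptors), then the treatment
#' filter. Treatment filters keep only samples whose relevant annotation is
#' documented: `chemo_documented` keeps chemotherapy = yes;
#' `any_systemic_treatment_documented` keeps chemotherapy = yes or
#' endocrine therapy = yes (dropping unknown and untreated);
#' `adjuvant_chemo_documented` keeps chemotherapy = yes in the adjuvant
#' setting; `untreated_documented` keeps documented systemically untreated
#' samples. Samples lacking relapse-free survival time or event flag are
#' always dropped.
#'
#' @param clinical clinical data.frame (columns `sample_id`, `rfs_months`,
#'   `rfs_event`, `chemotherapy`, `endocrine_therapy`, `adjuvant_setting`,
#'   `systemically_untreated`, with the yes/no/unknown vocabulary).
#' @param calls receptor calls from [assign_receptor_status()], covering
#'   all clinical samples.
#' @param subtype one of `"er_pos_erbb2_neg"`, `"basal"`.
#' @param treatment_rule one of `"chemo_documented"`,
#'   `"any_systemic_treatment_documented"`, `"adjuvant_chemo_documented"`,
#'   `"untreated_documented"`.
#' @return character vector of selected sample ids (possibly empty).
#' @export
select_cohort <- function(clinical, calls,
                          subtype = c("er_pos_erbb2_neg", "basal"),
                          treatment_rule = c(
                            "chemo_documented",
                            "any_systemic_treatment_documented",
                            "adjuvant_chemo_documented",
                            "untreated_documented")) {
  subtype <- match.arg(subtype)
  treatment_rule <- match.arg(treatment_rule)
  missing <- setdiff(clinical$sample_id, calls$sample_id)
  if (length(missing))
    stop("receptor call missing for sample(s): ",
         paste(missing, collapse = ", "))
  cc <- calls[match(clinical$sample_id, calls$sample_id), ]
  sub_ok <- switch(subtype,
    er_pos_erbb2_neg = cc$er_status == "positive" &
                       cc$erbb2_status == "negative",
    basal = cc$er_status == "negative" & cc$erbb2_status == "negative")
  treat_ok <- switch(treatment_rule,
    chemo_documented = clinical$chemotherapy == "yes",
    any_systemic_treatment_documented =
      clinical$chemotherapy == "yes" | clinical$endocrine_therapy == "yes",
    adjuvant_chemo_documented = clinical$chemotherapy == "yes" &
      clinical$adjuvant_setting == "yes",
    untreated_documented = clinical$systemically_untreated == "yes")
  surv_ok <- !is.na(clinical$rfs_months) & !is.na(clinical$rfs_event)
  clinical$sample_id[sub_ok & treat_ok & surv_ok]
}
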