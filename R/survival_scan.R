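check_survival <- function(time, event) {
  if (length(time) == 0) stop("empty survival data")
  if (length(event) != length(time))
    stop("time and event must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier (product-limit) survival curve
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' estimate S(t) = prod over event times t_i <= t of (1 - d_i / n_i).
#'
#' @param time positive event/censoring times (months).
#' @param event 1 = event, 0 = censored.
#' @param time_unit unit label carried for plotting consistency checks.
#' @return object of class `km_curve`: `time` (ordered observed times),
#'   `surv`, `n_risk`, `n_event`, `n`.
#' @export
km_curve <- function(time, event, time_unit = "months") {
  check_survival(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "none")
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, n = length(time),
                 time_unit = time_unit),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step evaluation: S(t) = 1 for t before the first
#' observed time.
#'
#' @param curve a [km_curve()].
#' @param t times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
km_eval <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  f <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  f(t)
}

#' Cox proportional-hazards fit for a single binary covariate
#'
#' Maximizes the Cox partial likelihood for group membership (1 = high)
#' with the Efron tie correction (Breslow available) by Newton-Raphson with
#' step-halving; the standard error comes from the observed information.
#' The default p-value is the score test at beta = 0, which for a binary
#' covariate is the log-rank test; a Wald p-value is available. Monotone
#' likelihood (all events in one group) and non-convergence are reported as
#' non-estimable rather than as errors.
#'
#' @param time,event survival data (positive times; 1 = event).
#' @param group binary high/low indicator per sample (logical or 0/1).
#' @param ties tie correction, `"efron"` (default) or `"breslow"`.
#' @param test p-value type, `"score"` (log-rank-equivalent, default) or
#'   `"wald"`.
#' @param max_iter,tol Newton-Raphson controls (tolerance on beta).
#' @return object of class `cox_fit`: `log_hr`, `hr`, `se_beta`, `p_value`,
#'   `n_high`, `n_low`, `n_events`, `estimable`, `converged`.
#' @export
cox_binary <- function(time, event, group, ties = c("efron", "breslow"),
                       test = c("score", "wald"), max_iter = 50,
                       tol = 1e-8) {
  ties <- match.arg(ties)
  test <- match.arg(test)
  check_survival(time, event)
  group <- as.integer(as.logical(group))
  if (length(group) != length(time))
    stop("group must have one flag per sample")
  n_high <- sum(group)
  if (n_high == 0 || n_high == length(group))
    stop("both groups must be non-empty")
  if (sum(event) < 1) stop("at least one event is required")
  r <- cox_fit_cpp(as.numeric(time), as.integer(event), group,
                   ties == "efron", test == "score",
                   as.integer(max_iter), tol)
  structure(list(log_hr = unname(r["beta"]), hr = exp(unname(r["beta"])),
                 se_beta = unname(r["se"]), p_value = unname(r["p"]),
                 n_high = n_high, n_low = length(group) - n_high,
                 n_events = sum(event),
                 estimable = r["estimable"] == 1,
                 converged = r["converged"] == 1),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("<cox_fit> non-estimable (monotone likelihood or no convergence)\n")
  } else {
    cat(sprintf("<cox_fit> HR %.3f (log HR %.3f, se %.3f), p = %.3g, ",
                x$hr, x$log_hr, x$se_beta, x$p_value))
    cat(sprintf("n = %d/%d (high/low), %d events\n",
                x$n_high, x$n_low, x$n_events))
  }
  invisible(x)
}

# Candidate cutoffs: distinct observed values in [Q1, Q3); "high" is
# strictly greater than the cutoff, so these are exactly the points where
# group membership changes.
scan_candidates <- function(expression) {
  q <- quantile(expression, c(0.25, 0.75), type = 7, names = FALSE)
  v <- sort(unique(expression))
  v[v >= q[1] & v < q[2]]
}

#' Best-cutoff survival scan for one gene
#'
#' Evaluates every candidate dichotomization of the gene's expression
#' between its lower and upper quartiles (each distinct observed value c
#' with Q1 <= c < Q3; high = expression strictly greater than c), fits the
#' binary Cox model at each, and selects the cutoff with the smallest
#' p-value. Exact p-value ties are broken by the largest absolute hazard
#' ratio `max(HR, 1/HR)`, remaining ties by the smallest cutoff.
#'
#' @param expression intensity per sample (same order as `time`).
#' @param time,event survival data.
#' @param ties,test,max_iter,tol passed to [cox_binary()].
#' @return object of class `gene_scan`: `best_cutoff`, `log_hr`, `hr`,
#'   `se_beta`, `p_value`, `n_high`, `n_low`, `n_events`,
#'   `max_expression`, `n_cutoffs` (candidates evaluated), `estimable`,
#'   `unscannable` (no valid cutoff or no estimable fit).
#' @export
scan_gene <- function(expression, time, event, ties = c("efron", "breslow"),
                      test = c("score", "wald"), max_iter = 50, tol = 1e-8) {
  ties <- match.arg(ties)
  test <- match.arg(test)
  check_survival(time, event)
  if (length(expression) != length(time))
    stop("expression must have one value per sample")
  if (length(time) < 8) stop("at least 8 samples are required to scan")
  empty <- structure(list(best_cutoff = NA_real_, log_hr = NA_real_,
                          hr = NA_real_, se_beta = NA_real_,
                          p_value = NA_real_, n_high = NA_integer_,
                          n_low = NA_integer_, n_events = sum(event),
                          max_expression = max(expression),
                          n_cutoffs = 0L, estimable = FALSE,
                          unscannable = TRUE), class = "gene_scan")
  cands <- scan_candidates(expression)
  if (length(cands) == 0) return(empty)
  m <- cox_scan_cpp(as.numeric(expression), as.numeric(time),
                    as.integer(event), cands, ties == "efron",
                    test == "score", as.integer(max_iter), tol)
  ok <- m[, "estimable"] == 1
  if (!any(ok)) { empty$n_cutoffs <- length(cands); return(empty) }
  mo <- m[ok, , drop = FALSE]
  sel <- mo[order(mo[, "p"], -abs(mo[, "beta"]), mo[, "cutoff"])[1], ]
  structure(list(best_cutoff = unname(sel["cutoff"]),
                 log_hr = unname(sel["beta"]),
                 hr = exp(unname(sel["beta"])),
                 se_beta = unname(sel["se"]),
                 p_value = unname(sel["p"]),
                 n_high = as.integer(sel["n_high"]),
                 n_low = as.integer(sel["n_low"]),
                 n_events = sum(event),
                 max_expression = max(expression),
                 n_cutoffs = length(cands), estimable = TRUE,
                 unscannable = FALSE), class = "gene_scan")
}

#' Benjamini-Hochberg false discovery rate q-values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation:
#' every p-value must lie in (0, 1].
#'
#' @param p_values numeric vector of p-values.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Transcriptome-wide best-cutoff survival scan
#'
#' Runs [scan_gene()] on every probe mapped to a gene symbol (unmapped
#' probes are excluded before multiple-testing correction), then attaches
#' Benjamini-Hochberg q-values computed across the best p-values of all
#' estimable probes. With `scan = FALSE` every gene is instead split at its
#' median (a fixed-cutoff analysis, useful for calibration studies of the
#' base test without minimum-p selection).
#'
#' @param matrix an [expr_matrix()] restricted to the analysis cohort.
#' @param time,event survival data aligned with the matrix columns.
#' @param probe_map data.frame with `probe_id`, `gene_symbol`,
#'   `is_best_probe`.
#' @param ties,test passed to the Cox fits.
#' @param scan if `FALSE`, use a fixed median cutoff per gene instead of
#'   the quartile-restricted scan.
#' @return data.frame of class `scan_result` with one row per scanned
#'   probe: `probe_id`, `gene_symbol`, `best_cutoff`, `log_hr`, `hr`,
#'   `se_beta`, `p_value`, `fdr_q`, `n_high`, `n_low`, `n_events`,
#'   `max_expression`, `estimable`. Non-estimable/unscannable probes have
#'   `NA` statistics and are excluded from the FDR vector.
#' @export
scan_transcriptome <- function(matrix, time, event, probe_map,
                               ties = c("efron", "breslow"),
                               test = c("score", "wald"), scan = TRUE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  ties <- match.arg(ties)
  test <- match.arg(test)
  check_survival(time, event)
  if (length(time) != ncol(matrix$values))
    stop("survival data and expression matrix samples are misaligned")
  pm <- probe_map[!is.na(probe_map$gene_symbol) &
                    probe_map$gene_symbol != "", ]
  probes <- intersect(rownames(matrix$values), pm$probe_id)
  gene_of <- setNames(pm$gene_symbol, pm$probe_id)
  rows <- lapply(probes, function(p) {
    x <- matrix$values[p, ]
    if (scan) {
      g <- scan_gene(x, time, event, ties = ties, test = test)
    } else {
      cut <- median(x)
      if (min(x) == max(x) || sum(x > cut) == 0 || sum(x > cut) == length(x)) {
        g <- list(best_cutoff = NA_real_, log_hr = NA_real_, hr = NA_real_,
                  se_beta = NA_real_, p_value = NA_real_,
                  n_high = NA_integer_, n_low = NA_integer_,
                  n_events = sum(event), max_expression = max(x),
                  estimable = FALSE)
      } else {
        f <- cox_binary(time, event, x > cut, ties = ties, test = test)
        g <- list(best_cutoff = cut, log_hr = f$log_hr, hr = f$hr,
                  se_beta = f$se_beta, p_value = f$p_value,
                  n_high = f$n_high, n_low = f$n_low,
                  n_events = f$n_events, max_expression = max(x),
                  estimable = f$estimable)
      }
    }
    data.frame(probe_id = p, gene_symbol = unname(gene_of[p]),
               best_cutoff = g$best_cutoff, log_hr = g$log_hr, hr = g$hr,
               se_beta = g$se_beta, p_value = g$p_value,
               n_high = g$n_high, n_low = g$n_low, n_events = g$n_events,
               max_expression = g$max_expression,
               estimable = isTRUE(g$estimable),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(probe_id = character(0), gene_symbol = character(0),
                      best_cutoff = numeric(0), log_hr = numeric(0),
                      hr = numeric(0), se_beta = numeric(0),
                      p_value = numeric(0), n_high = integer(0),
                      n_low = integer(0), n_events = integer(0),
                      max_expression = numeric(0), estimable = logical(0),
                      stringsAsFactors = FALSE)
  res$fdr_q <- NA_real_
  est <- res$estimable & !is.na(res$p_value)
  if (any(est)) res$fdr_q[est] <- bh_fdr(res$p_value[est])
  res <- res[, c("probe_id", "gene_symbol", "best_cutoff", "log_hr", "hr",
                 "se_beta", "p_value", "fdr_q", "n_high", "n_low",
                 "n_events", "max_expression", "estimable")]
  class(res) <- c("scan_result", "data.frame")
  res
}
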