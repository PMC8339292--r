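# Independent oracles used across the suite.

# Written-out Efron partial log-likelihood for a single binary covariate,
# straight from the definition (loops over event times, explicit risk sets).
efron_loglik <- function(beta, time, event, group) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    s1 <- sum(group[D])
    sumR <- sum(exp(beta * group[R]))
    sumD <- sum(exp(beta * group[D]))
    ll <- ll + beta * s1
    for (j in seq_len(d) - 1) ll <- ll - log(sumR - (j / d) * sumD)
  }
  ll
}

# Brute-force maximizer of the written-out partial likelihood: coarse grid
# over (-5, 5), then local refinement (the likelihood is concave in beta).
grid_cox_beta <- function(time, event, group, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, efron_loglik, numeric(1),
               time = time, event = event, group = group)
  b0 <- grid[which.max(ll)]
  stats::optimize(efron_loglik, c(b0 - 0.02, b0 + 0.02), time = time,
                  event = event, group = group, maximum = TRUE,
                  tol = 1e-9)$maximum
}

# Exhaustive re-scan over all interquartile cutoffs with an independent
# implementation of the selection rule (smallest p, then largest absolute
# HR, then smallest cutoff).
rescan_oracle <- function(x, time, event) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  cands <- sort(unique(x))
  cands <- cands[cands >= q[1] & cands < q[2]]
  rows <- do.call(rbind, lapply(cands, function(cc) {
    f <- cox_binary(time, event, x > cc)
    if (!f$estimable) return(NULL)
    data.frame(cutoff = cc, p = f$p_value, beta = f$log_hr, hr = f$hr)
  }))
  if (is.null(rows)) return(NULL)
  best <- rows[rows$p == min(rows$p), , drop = FALSE]
  ahr <- pmax(best$hr, 1 / best$hr)
  best <- best[ahr == max(ahr), , drop = FALSE]
  best[which.min(best$cutoff), ]
}

# Random small survival datasets with an estimable binary-covariate fit.
rand_estimable_dataset <- function(n_range = 8:20) {
  repeat {
    n <- sample(n_range, 1)
    time <- round(rexp(n, 0.05) + 0.1, 3)
    event <- rbinom(n, 1, 0.75)
    group <- rbinom(n, 1, 0.5)
    if (sum(group) == 0 || sum(group) == n || sum(event) == 0) next
    if (sum(event[group == 1]) == 0 || sum(event[group == 0]) == 0) next
    f <- cox_binary(time, event, group)
    if (f$estimable) return(list(time = time, event = event,
                                 group = group, fit = f))
  }
}
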