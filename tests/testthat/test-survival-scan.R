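test_that("the product-limit estimator matches closed-form evaluation", {
  # all censored: S stays at 1
  k0 <- km_curve(c(1, 2, 5), c(0, 0, 0))
  expect_true(all(k0$surv == 1))
  # worked example: censored at 1, events at 2 and 3
  k <- km_curve(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km_eval(k, c(0.5, 1.5, 2, 2.9, 3, 10)),
               c(1, 1, 0.5, 0.5, 0, 0))
  # survival is non-increasing and starts at 1
  set.seed(61)
  k2 <- km_curve(rexp(50, 0.05) + 0.1, rbinom(50, 1, 0.6))
  expect_true(all(diff(k2$surv) <= 0))
  expect_lte(max(k2$surv), 1)
  # duplicating every subject leaves the estimate unchanged
  tm <- c(1, 2, 2, 4, 7)
  ev <- c(1, 0, 1, 1, 0)
  k3 <- km_curve(tm, ev)
  k4 <- km_curve(rep(tm, 2), rep(ev, 2))
  expect_equal(km_eval(k4, c(1, 2, 4, 7)), km_eval(k3, c(1, 2, 4, 7)))
  expect_error(km_curve(numeric(0), integer(0)), "empty")
})

test_that("the binary Cox fit maximizes the written-out partial likelihood", {
  # 8-subject toy data without ties
  tm <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ev <- c(1, 1, 0, 1, 1, 0, 1, 1)
  gr <- c(1, 0, 1, 1, 0, 0, 1, 0)
  f <- cox_binary(tm, ev, gr)
  expect_lt(abs(f$log_hr - grid_cox_beta(tm, ev, gr)), 1e-4)
  # with ties, against the independent likelihood oracle
  set.seed(62)
  for (i in 1:5) {
    d <- rand_estimable_dataset(12:20)
    expect_lt(abs(d$fit$log_hr - grid_cox_beta(d$time, d$event, d$group)),
              1e-3)
  }
})

test_that("the binary Cox fit agrees with an established implementation", {
  set.seed(63)
  for (i in 1:5) {
    n <- 80
    tm <- round(rexp(n, 0.03) + 0.1, 2)  # rounding forces ties
    ev <- rbinom(n, 1, 0.7)
    gr <- rbinom(n, 1, 0.5)
    for (ties in c("efron", "breslow")) {
      f <- cox_binary(tm, ev, gr, ties = ties)
      cp <- survival::coxph(survival::Surv(tm, ev) ~ gr, ties = ties)
      expect_equal(f$log_hr, unname(coef(cp)), tolerance = 1e-7)
      expect_equal(f$se_beta, sqrt(vcov(cp)[1, 1]), tolerance = 1e-7)
      expect_equal(f$p_value, summary(cp)$sctest[["pvalue"]],
                   tolerance = 1e-7)
      fw <- cox_binary(tm, ev, gr, ties = ties, test = "wald")
      expect_equal(fw$p_value, summary(cp)$coefficients[1, "Pr(>|z|)"],
                   tolerance = 1e-7)
    }
  }
})

test_that("identical survival in both groups gives HR 1 and p 1", {
  tm <- rep(c(2, 4, 6, 9), 2)
  ev <- rep(c(1, 1, 0, 1), 2)
  gr <- rep(c(0, 1), each = 4)
  f <- cox_binary(tm, ev, gr)
  expect_identical(f$log_hr, 0)
  expect_identical(f$hr, 1)
  expect_identical(f$p_value, 1)
})

test_that("swapping group labels negates the log hazard ratio", {
  set.seed(64)
  for (i in 1:20) {
    d <- rand_estimable_dataset(10:25)
    f1 <- cox_binary(d$time, d$event, d$group)
    f2 <- cox_binary(d$time, d$event, 1 - d$group)
    expect_equal(f2$log_hr, -f1$log_hr, tolerance = 1e-9)
    expect_equal(f2$p_value, f1$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate Cox inputs error or flag non-estimability", {
  tm <- c(1, 2, 3, 4)
  expect_error(cox_binary(tm, c(1, 1, 1, 1), c(1, 1, 1, 1)), "non-empty")
  expect_error(cox_binary(tm, c(0, 0, 0, 0), c(1, 0, 1, 0)), "event")
  # all events in one group: monotone likelihood
  f <- cox_binary(c(1, 2, 10, 11), c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_false(f$estimable)
  expect_true(is.na(f$log_hr))
})

test_that("a large simulated effect is recovered near its true hazard ratio", {
  set.seed(65)
  n <- 3000
  gr <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.01 * 2^gr)
  f <- cox_binary(tm, rep(1, n), gr)
  expect_gt(f$hr, 1.8)
  expect_lt(f$hr, 2.2)
})

test_that("the cutoff scan equals exhaustive re-evaluation", {
  set.seed(66)
  for (i in 1:10) {
    n <- 50 + 10 * i
    x <- rlnorm(n, 6, 0.8)
    tm <- rexp(n, 0.02) + 1e-3
    ev <- rbinom(n, 1, 0.7)
    g <- scan_gene(x, tm, ev)
    o <- rescan_oracle(x, tm, ev)
    expect_identical(g$best_cutoff, o$cutoff)
    expect_identical(g$p_value, o$p)
    expect_identical(g$log_hr, o$beta)
  }
})

test_that("the scan respects the quartile restriction and group floor", {
  set.seed(67)
  x <- rlnorm(200, 6, 1)
  tm <- rexp(200, 0.02) + 1e-3
  ev <- rbinom(200, 1, 0.7)
  g <- scan_gene(x, tm, ev)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  expect_gte(g$best_cutoff, q[1])
  expect_lt(g$best_cutoff, q[2])
  expect_gte(min(g$n_high, g$n_low), ceiling(0.25 * 200) - 1)
  expect_identical(g$max_expression, max(x))
})

test_that("inverting the expression direction flips the hazard ratio", {
  set.seed(68)
  for (i in 1:5) {
    x <- rlnorm(120, 6, 0.9)
    tm <- rexp(120, 0.02) + 1e-3
    ev <- rbinom(120, 1, 0.7)
    a <- scan_gene(x, tm, ev)
    b <- scan_gene(max(x) - x, tm, ev)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-9)
    expect_equal(b$hr, 1 / a$hr, tolerance = 1e-7)
  }
})

test_that("degenerate expression is reported as unscannable", {
  tm <- rexp(20, 0.05) + 0.1
  ev <- rbinom(20, 1, 0.8)
  g <- scan_gene(rep(100, 20), tm, ev)
  expect_true(g$unscannable)
  expect_false(g$estimable)
  expect_error(scan_gene(rlnorm(5), rexp(5) + 0.1, rep(1, 5)), "8 samples")
})

test_that("a planted step effect is located near the true split", {
  set.seed(69)
  hits <- replicate(40, {
    n <- 400
    z <- rbinom(n, 1, 0.5)
    x <- exp(rnorm(n, 5 + 2 * z, 0.5))
    tm <- rexp(n, 0.01 * exp(log(3) * z))
    g <- scan_gene(x, tm, rep(1, n))
    g$best_cutoff >= quantile(x, 0.4, type = 7) &&
      g$best_cutoff <= quantile(x, 0.6, type = 7)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_identical(bh_fdr(0.031), 0.031)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  # q-values are monotone in the sorted p order and the alpha-level set
  # matches the classical step-up rule
  set.seed(70)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  alpha <- 0.1
  m <- length(p)
  ps <- sort(p)
  k <- max(c(0, which(ps <= alpha * seq_len(m) / m)))
  classical <- if (k > 0) p <= ps[k] else rep(FALSE, m)
  expect_identical(q <= alpha, classical)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the transcriptome scan attaches FDR over gene-mapped probes only", {
  set.seed(71)
  n <- 60
  v <- matrix(rlnorm(5 * n, 6, 0.8), nrow = 5,
              dimnames = list(sprintf("P%d", 1:5), sprintf("S%03d", 1:n)))
  em <- expr_matrix(v, rep("D1", n))
  tm <- rexp(n, 0.02) + 1e-3
  ev <- rbinom(n, 1, 0.7)
  pm <- data.frame(probe_id = sprintf("P%d", 1:5),
                   gene_symbol = c("G1", "G2", NA, "G4", "G5"),
                   is_best_probe = TRUE, stringsAsFactors = FALSE)
  res <- scan_transcriptome(em, tm, ev, pm)
  expect_false("P3" %in% res$probe_id)  # unmapped excluded before FDR
  expect_identical(nrow(res), 4L)
  expect_equal(res$fdr_q[res$estimable],
               bh_fdr(res$p_value[res$estimable]))
  # single-probe matrix: q equals p
  res1 <- scan_transcriptome(em_subset(em, probes = "P1"), tm, ev, pm)
  expect_identical(res1$fdr_q, res1$p_value)
  # per-probe results equal the single-gene scan
  g <- scan_gene(v["P2", ], tm, ev)
  expect_identical(res$best_cutoff[res$probe_id == "P2"], g$best_cutoff)
  expect_identical(res$p_value[res$probe_id == "P2"], g$p_value)
  expect_error(scan_transcriptome(em, tm[-1], ev[-1], pm), "misaligned")
})
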