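make_em <- function(v, ds = NULL, order = NULL) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("P%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("S%03d", seq_len(ncol(v)))
  if (is.null(ds)) ds <- rep("D1", ncol(v))
  expr_matrix(v, ds, order)
}

qc_row <- function(sample_id, background = 55, raw_q = 2.4,
                   percent_present = 46, biob = TRUE, ratio = 1.25) {
  data.frame(sample_id = sample_id, background = background, raw_q = raw_q,
             percent_present = percent_present, biob_spikes_present = biob,
             ratio_3to5 = ratio, stringsAsFactors = FALSE)
}

test_that("scaling normalization anchors every array to the target mean", {
  # a column whose reference mean is already on target is untouched
  v <- matrix(c(1000, 1000, 500, 1500), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  em <- make_em(v)
  nm <- scale_normalize(em, reference_probes = c("A", "B"))
  expect_equal(nm$values[, "s1"], v[, "s1"])
  # linear scaling is forced: reference mean 500 with values (200, 800)
  v2 <- matrix(c(200, 800), nrow = 2,
               dimnames = list(c("A", "B"), "s1"))
  nm2 <- scale_normalize(make_em(v2), reference_probes = c("A", "B"))
  expect_equal(unname(nm2$values[, "s1"]), c(400, 1600))
  # random matrix: recomputed reference means all equal the target
  set.seed(7)
  v3 <- matrix(rlnorm(50 * 20, 6, 1), nrow = 50)
  nm3 <- scale_normalize(make_em(v3))
  expect_lt(max(abs(colMeans(nm3$values) - 1000)) / 1000, 1e-9)
  # idempotence
  nm4 <- scale_normalize(nm3)
  expect_equal(nm4$values, nm3$values, tolerance = 1e-12)
  # a zero column is reported by sample name
  v5 <- v3
  v5[, 3] <- 0
  expect_error(scale_normalize(make_em(v5)), "S003")
})

test_that("QC classification flags values outside the central 95% range", {
  # degenerate distribution: every value is its own 2.5-97.5 percentile
  qc <- do.call(rbind, lapply(sprintf("S%02d", 1:10), qc_row))
  st <- classify_qc(qc)
  expect_true(all(st$label == "pass"))
  # one extreme background among 100 central samples -> outlier, and the
  # percentile oracle over the 100 values agrees
  set.seed(11)
  qc2 <- qc_row(sprintf("S%03d", 1:100),
                background = rnorm(100, 55, 3),
                raw_q = 2.4, percent_present = 46, ratio = 1.25)
  qc2$background[17] <- 500
  st2 <- classify_qc(qc2)
  rng <- quantile(qc2$background, c(0.025, 0.975), type = 7)
  expect_identical(st2$label[17], "outlier")
  expect_identical(st2$failed_parameters[[17]], "background")
  outside <- qc2$background < rng[1] | qc2$background > rng[2]
  expect_identical(st2$label == "outlier", unname(outside))
  # two or more failing parameters mark a biased array
  qc3 <- qc_row(sprintf("S%03d", 1:50), background = rnorm(50, 55, 3),
                ratio = rnorm(50, 1.25, 0.1))
  qc3$background[5] <- 900
  qc3$ratio_3to5[5] <- 40
  st3 <- classify_qc(qc3)
  expect_identical(st3$label[5], "biased")
  expect_setequal(st3$failed_parameters[[5]], c("background", "ratio_3to5"))
  # absent spikes fail regardless of the continuous values
  qc4 <- qc_row(sprintf("S%02d", 1:10))
  qc4$biob_spikes_present[2] <- FALSE
  expect_identical(classify_qc(qc4)$label[2], "outlier")
  # non-positive continuous values fail even inside the percentile range
  qc5 <- qc_row(sprintf("S%02d", 1:40), background = seq(-1, 60,
                                                         length.out = 40))
  st5 <- classify_qc(qc5)
  expect_true("background" %in% st5$failed_parameters[[1]])
  # missing values are reported by sample
  qc6 <- qc_row(c("A1", "A2"))
  qc6$raw_q[2] <- NA
  expect_error(classify_qc(qc6), "A2")
  # labels partition the samples
  st <- classify_qc(qc2)
  expect_identical(sum(st$label %in% c("pass", "outlier", "biased")),
                   nrow(qc2))
})

test_that("redundancy removal keeps the earliest published copy", {
  set.seed(3)
  v <- matrix(rlnorm(30 * 6, 6, 1), nrow = 30,
              dimnames = list(sprintf("P%03d", 1:30),
                              sprintf("S%03d", 1:6)))
  em <- make_em(v, ds = c("D1", "D1", "D2", "D2", "D3", "D3"))
  rr <- remove_redundant(em)
  expect_identical(nrow(rr$dropped), 0L)
  expect_identical(rr$matrix$values, em$values)
  # an identical column in a later dataset is dropped
  v2 <- cbind(v, v[, 1])
  colnames(v2) <- c(colnames(v), "S_copy")
  em2 <- make_em(v2, ds = c("D1", "D1", "D2", "D2", "D3", "D3", "D3"))
  rr2 <- remove_redundant(em2)
  expect_identical(rr2$dropped$kept_sample_id, "S001")
  expect_identical(rr2$dropped$dropped_sample_id, "S_copy")
  expect_false("S_copy" %in% colnames(rr2$matrix$values))
})

test_that("redundancy removal is stable under column permutation", {
  set.seed(4)
  v <- matrix(rlnorm(20 * 5, 6, 1), nrow = 20)
  v <- cbind(v, v[, 2], v[, 4])
  colnames(v) <- sprintf("S%02d", 1:7)
  rownames(v) <- sprintf("P%03d", 1:20)
  ds <- c("D1", "D1", "D2", "D2", "D2", "D3", "D3")
  names(ds) <- colnames(v)
  ord <- setNames(1:3, c("D1", "D2", "D3"))
  kept_ref <- sort(colnames(
    remove_redundant(expr_matrix(v, ds, ord))$matrix$values))
  for (i in 1:5) {
    perm <- sample(ncol(v))
    em <- expr_matrix(v[, perm], ds[perm], ord)
    expect_identical(sort(colnames(remove_redundant(em)$matrix$values)),
                     kept_ref)
  }
})

test_that("planted duplicates and biased arrays are recovered exactly", {
  co <- simulate_cohort(sim_config(n_datasets = 3, samples_per_dataset = 60,
                                   n_probes = 120, n_prognostic = 0,
                                   n_duplicates = 5, n_outlier_arrays = 4,
                                   n_biased_arrays = 3, seed = 13))
  nm <- scale_normalize(co$matrix)
  rr <- remove_redundant(nm)
  expect_identical(sort(rr$dropped$dropped_sample_id),
                   sort(co$truth$duplicate_pairs$copy))
  expect_identical(
    rr$dropped$kept_sample_id[order(rr$dropped$dropped_sample_id)],
    co$truth$duplicate_pairs$original[
      order(co$truth$duplicate_pairs$copy)])
  st <- classify_qc(co$qc)
  planted_biased <- names(co$truth$qc_fail_labels)[
    co$truth$qc_fail_labels == "biased"]
  expect_setequal(st$sample_id[st$label == "biased"], planted_biased)
  planted_outlier <- names(co$truth$qc_fail_labels)[
    co$truth$qc_fail_labels == "outlier"]
  expect_true(all(planted_outlier %in%
                    st$sample_id[st$label == "outlier"]))
  ex <- exclude_biased(nm, st)
  expect_setequal(setdiff(colnames(nm$values), colnames(ex$values)),
                  planted_biased)
})

test_that("only biased arrays are excluded", {
  set.seed(5)
  v <- matrix(rlnorm(10 * 10, 6, 1), nrow = 10,
              dimnames = list(sprintf("P%03d", 1:10),
                              sprintf("S%03d", 1:10)))
  em <- make_em(v)
  st <- data.frame(sample_id = colnames(v),
                   label = c("biased", rep("pass", 5), rep("outlier", 4)),
                   stringsAsFactors = FALSE)
  ex <- exclude_biased(em, st)
  expect_identical(ncol(ex$values), 9L)
  expect_false("S001" %in% colnames(ex$values))
  st$label <- "pass"
  expect_identical(exclude_biased(em, st)$values, em$values)
  expect_error(exclude_biased(em, st[-1, ]), "S001")
})
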