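test_that("sample filtering retains the 49 located study samples", {
  sim <- generate_dataset(sim_config(), seed = 1)
  expect_identical(n_samples(sim$dataset), 65L)
  d <- filter_samples(sim$dataset)
  expect_identical(n_samples(d), 49L)
  expect_true(all(d$samples$role == "study" & d$samples$tissue != "none"))

  expect_identical(n_samples(filter_samples(d)), 49L)  # idempotent

  all_blank <- sim$dataset
  all_blank$samples$role <- "blank"
  all_blank$samples$tissue <- "none"
  expect_error(filter_samples(all_blank), "no study samples")
})

test_that("blank-peak removal follows the median-ratio rule", {
  # 4 study + 2 blank samples, 3 metabolites:
  # m1 well above blanks, m2 equal to blanks, m3 absent from blanks
  vals <- rbind(matrix(c(100, 100, 100, 100,   10, 10, 10, 10,  5, 6, 7, 8),
                       nrow = 4),
                matrix(c(10, 10,   10, 10,   0, 0), nrow = 2))
  d <- layout_dataset(c(rep("SI", 4), "none", "none"), vals, scale = "raw")
  out <- remove_blank_peaks(d, ratio_threshold = 3)
  expect_identical(out$removed, "m002")
  expect_identical(colnames(out$dataset$abundance), c("m001", "m003"))

  no_blank <- subset_samples(d, 1:4)
  expect_warning(out2 <- remove_blank_peaks(no_blank), "no blank samples")
  expect_identical(n_metabolites(out2$dataset), 3L)

  # exactly at the threshold is still below: median 30 vs 3 x 10 kept?
  vals3 <- rbind(matrix(rep(c(31, 29), each = 4), nrow = 4),
                 matrix(rep(10, 4), nrow = 2))
  d3 <- layout_dataset(c(rep("SI", 4), "none", "none"), vals3, scale = "raw")
  out3 <- remove_blank_peaks(d3, 3)
  expect_identical(out3$removed, "m002")  # 29 < 30, removed; 31 kept
})

test_that("QC drift correction flattens a log-linear drift", {
  set.seed(1)
  n <- 20
  ord <- seq_len(n)
  role <- rep("study", n); role[c(3, 8, 13, 18)] <- "QC"
  tissue <- ifelse(role == "QC", "none", "SI")
  base <- c(12, 14)  # two metabolites, log2 base level
  drift <- 0.02
  vals <- 2^(outer(drift * ord, rep(1, 2)) +
               matrix(rep(base, each = n), nrow = n))
  d <- layout_dataset(tissue, vals, role = role, scale = "raw")
  out <- qc_drift_correct(d)
  qc <- which(role == "QC")
  for (j in 1:2) {
    b <- coef(lm(log2(out$abundance[qc, j]) ~ ord[qc]))[2]
    expect_lt(abs(b), 1e-6)
    # mean QC level preserved
    expect_equal(mean(log2(out$abundance[qc, j])),
                 mean(log2(d$abundance[qc, j])), tolerance = 1e-9)
  }
  # study samples flattened too (all samples shared the drift)
  stud <- which(role == "study")
  b <- coef(lm(log2(out$abundance[stud, 1]) ~ ord[stud]))[2]
  expect_lt(abs(b), 1e-6)

  # zero drift: matrix unchanged
  vals0 <- 2^(matrix(rep(base, each = n), nrow = n))
  d0 <- layout_dataset(tissue, vals0, role = role, scale = "raw")
  expect_equal(qc_drift_correct(d0)$abundance, d0$abundance,
               tolerance = 1e-9)

  # fewer than 3 QCs: skip with warning
  d2 <- subset_samples(d, which(role == "study" | ord <= 3))
  expect_warning(out2 <- qc_drift_correct(d2), "fewer than 3 QC")
  expect_equal(out2$abundance, d2$abundance)
})

test_that("isomer deduplication keeps the largest log-scale IQR", {
  # group of two isomers with log2 IQRs 1.2 vs 0.5; singleton; unnamed
  q <- c(-0.6, -0.2, 0.2, 0.6)  # IQR 0.8 shape, scaled below
  vals <- 2^cbind(10 + 1.5 * q, 10 + 0.625 * q, 8 + q, 9 + q)
  d <- layout_dataset(rep("SI", 4), vals, scale = "raw",
                      names_ = c("Iso A", "Iso A", "Single", ""))
  d$metabolites$isomer_group <- c("g1", "g1", "", "")
  out <- dedup_isomers(d)
  expect_identical(out$metabolites$metabolite_id, c("m001", "m003"))
  expect_identical(attr(out, "n_unnamed_dropped"), 1L)
  expect_identical(attr(out, "n_isomer_collapsed"), 1L)
  # retained values are untouched
  expect_identical(out$abundance[, "m001"], d$abundance[, "m001"])

  # exact IQR tie (identical value columns) keeps the first in input order
  vals2 <- 2^cbind(10 + q, 10 + q, 10 + q)
  d2 <- layout_dataset(rep("SI", 4), vals2, scale = "raw",
                       names_ = c("T one", "T two", "T three"))
  d2$metabolites$isomer_group <- c("g", "g", "g")
  out2 <- dedup_isomers(d2)
  expect_identical(out2$metabolites$metabolite_id, "m001")
  expect_identical(attr(out2, "n_isomer_collapsed"), 2L)
})

test_that("log2 quantile normalization matches the hand-computed example", {
  # samples [1,3] and [2,4]: log2 rows [0,1.585] and [1,2] -> both map to
  # the mean sorted distribution [0.5, 1.7925]
  vals <- rbind(c(1, 3), c(2, 4))
  d <- layout_dataset(c("SI", "decidua"), vals, scale = "raw")
  out <- log2_quantile_normalize(d)
  ref <- c((0 + 1) / 2, (log2(3) + 2) / 2)
  expect_equal(unname(out$abundance[1, ]), ref, tolerance = 1e-12)
  expect_equal(unname(out$abundance[2, ]), ref, tolerance = 1e-12)
  expect_identical(out$scale, "log2_normalized")
})

test_that("quantile normalization has its defining property and is idempotent", {
  set.seed(9)
  vals <- matrix(2^rnorm(8 * 30, 12, 2), nrow = 8)
  d <- layout_dataset(rep(c("SI", "decidua"), 4), vals, scale = "raw")
  out <- log2_quantile_normalize(d)
  sorted <- apply(out$abundance, 1, sort)
  for (i in 2:8) expect_equal(sorted[, i], sorted[, 1], tolerance = 1e-9)
  # ranks within each sample preserved
  for (i in 1:8) {
    expect_identical(order(out$abundance[i, ]), order(vals[i, ]))
  }
  # idempotence: re-normalizing the (already normalized) matrix in raw space
  d2 <- met_dataset(2^out$abundance, out$samples, out$metabolites,
                    scale = "raw")
  out2 <- log2_quantile_normalize(d2)
  expect_equal(out2$abundance, out$abundance, tolerance = 1e-9)
  # identical multisets stay unchanged (up to log2)
  v3 <- rbind(c(1, 8, 2), c(8, 1, 2))
  d3 <- layout_dataset(c("SI", "decidua"), v3, scale = "raw")
  out3 <- log2_quantile_normalize(d3)
  expect_equal(out3$abundance, log2(v3), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("normalization handles missing values and rejects starved samples", {
  vals <- rbind(c(2, 4, 8, NA), c(2, 4, 8, 16), c(4, 8, 16, 32))
  d <- layout_dataset(c("SI", "decidua", "SI"), vals, scale = "raw")
  out <- log2_quantile_normalize(d)
  expect_identical(is.na(out$abundance), is.na(vals), ignore_attr = TRUE)

  vals2 <- rbind(c(2, NA, NA, NA), c(2, 4, 8, 16), c(4, 8, 16, 32))
  d2 <- layout_dataset(c("SI", "decidua", "SI"), vals2, scale = "raw")
  expect_error(log2_quantile_normalize(d2), "smp01")
})

test_that("half-minimum imputation respects its bounds and determinism", {
  vals <- rbind(c(8, 10), c(NA, 12), c(16, NA))
  d <- layout_dataset(rep("SI", 3), vals, scale = "raw")
  out0 <- impute_half_min(d, noise_scale = 0, seed = 1)
  expect_equal(out0$abundance[2, 1], 4)          # half of min 8, no noise
  expect_equal(out0$abundance[3, 2], 5)
  expect_identical(attr(out0, "n_imputed"), 2L)

  # noise bound over many draws: (half-min, 0.55 * min]
  vals2 <- cbind(c(8, rep(NA, 1000)), 1)
  d2 <- layout_dataset(rep("SI", 1001), cbind(vals2[, 1], 1:1001),
                       scale = "raw")
  out2 <- impute_half_min(d2, noise_scale = 0.1, seed = 4)
  imp <- out2$abundance[-1, 1]
  expect_true(all(imp > 4 - 1e-12 & imp <= 4.4 + 1e-12))
  expect_true(all(imp < 8))
  # deterministic
  out2b <- impute_half_min(d2, noise_scale = 0.1, seed = 4)
  expect_identical(out2$abundance, out2b$abundance)

  # no missing: identity
  d3 <- layout_dataset(rep("SI", 3),
                       rbind(c(8, 10), c(9, 12), c(16, 11)), scale = "raw")
  expect_equal(impute_half_min(d3, seed = 1)$abundance, d3$abundance)

  # fully missing metabolite: error naming it
  vals4 <- rbind(c(NA, 10), c(NA, 12))
  d4 <- layout_dataset(rep("SI", 2), vals4, scale = "raw")
  expect_error(impute_half_min(d4, seed = 1), "m001")

  # on the log2 scale the rule acts on intensities: min - 1 + log2(1 + u)
  vals5 <- rbind(c(3, 1), c(NA, 2))
  d5 <- layout_dataset(rep("SI", 2), vals5, scale = "log2_normalized")
  out5 <- impute_half_min(d5, noise_scale = 0, seed = 1)
  expect_equal(out5$abundance[2, 1], 2)  # 3 - 1
})

test_that("full preprocessing reconciles its report counts", {
  sim <- generate_dataset(sim_config(), seed = 21)
  pp <- preprocess(sim$dataset, seed = 5)
  r <- pp$report
  expect_identical(r$n_samples_out, 49L)
  expect_identical(r$n_metabolites_in - r$n_blank_removed -
                     r$n_unnamed_dropped - r$n_isomer_collapsed,
                   r$n_metabolites_out)
  expect_identical(pp$dataset$scale, "log2_normalized")
  expect_false(anyNA(pp$dataset$abundance))
  # contaminant peaks (blank-dominant by construction) were all removed
  gt <- sim$ground_truth$metabolites
  contam <- gt$metabolite_id[gt$is_contaminant]
  expect_length(intersect(contam, pp$dataset$metabolites$metabolite_id), 0)
})
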