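test_that("pair enumeration reproduces the printed pair counts", {
  d <- filter_samples(generate_dataset(sim_config(), seed = 2)$dataset)
  dec_gi <- enumerate_cross_tissue_pairs(d, "decidua", "GI", "all_pairs")
  expect_identical(nrow(dec_gi), 88L)    # 8 decidua x 11 GI
  gi_mec <- enumerate_cross_tissue_pairs(d, "GI", "meconium", "all_pairs")
  expect_identical(nrow(gi_mec), 209L)   # 11 GI x 19 meconium
  # age-matched at 23 weeks
  expect_identical(nrow(enumerate_cross_tissue_pairs(d, "decidua", "GI",
                                                     "age_matched")), 12L)
  expect_identical(nrow(enumerate_cross_tissue_pairs(d, "GI", "meconium",
                                                     "age_matched")), 21L)
  # all-pairs count is always |A| x |B|
  pv <- enumerate_cross_tissue_pairs(d, "decidua", "PV", "all_pairs")
  expect_identical(nrow(pv), 88L)        # 8 x 11

  sub <- enumerate_cross_tissue_pairs(d, "decidua", "GI", "subject_matched")
  expect_true(all(sub$same_subject))
  expect_gte(nrow(sub), 2L)
})

test_that("subject-matched mode keeps one pair for a matched couple", {
  vals <- matrix(rnorm(8), nrow = 2)
  d <- layout_dataset(c("decidua", "SI"), vals, subject = c("s1", "s1"))
  p <- enumerate_cross_tissue_pairs(d, "decidua", "GI", "subject_matched")
  expect_identical(nrow(p), 1L)
  expect_identical(p$sample_a, "smp01")
  expect_identical(p$sample_b, "smp02")
})

test_that("panel correlation matches a covariance/sd oracle", {
  set.seed(31)
  vals <- matrix(rnorm(2 * 41), nrow = 2)
  d <- layout_dataset(c("decidua", "SI"), vals)
  rho <- panel_profile_correlation(d, "smp01", "smp02",
                                   d$metabolites$metabolite_id)
  a <- vals[1, ]; b <- vals[2, ]
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(rho, oracle, tolerance = 1e-12)

  # identity and negation
  d2 <- layout_dataset(c("decidua", "SI"), rbind(vals[1, ], vals[1, ]))
  expect_equal(panel_profile_correlation(d2, "smp01", "smp02",
                                         d2$metabolites$metabolite_id), 1.0)
  d3 <- layout_dataset(c("decidua", "SI"), rbind(vals[1, ], -vals[1, ]))
  expect_equal(panel_profile_correlation(d3, "smp01", "smp02",
                                         d3$metabolites$metabolite_id), -1.0)

  # Pearson is invariant to affine rescaling of one sample's vector
  d4 <- layout_dataset(c("decidua", "SI"), rbind(3 * vals[1, ] + 7, vals[2, ]))
  expect_equal(panel_profile_correlation(d4, "smp01", "smp02",
                                         d4$metabolites$metabolite_id),
               rho, tolerance = 1e-12)

  # degenerate inputs
  d5 <- layout_dataset(c("decidua", "SI"), rbind(rep(1, 41), vals[2, ]))
  expect_error(panel_profile_correlation(d5, "smp01", "smp02",
                                         d5$metabolites$metabolite_id),
               "zero variance")
  expect_error(panel_profile_correlation(d, "smp01", "smp02",
                                         d$metabolites$metabolite_id[1:2]),
               "fewer than 3")
})

test_that("subject correlation matrix is symmetric with unit diagonal", {
  sim <- generate_dataset(sim_config(), seed = 13)
  pp <- preprocess(sim$dataset, seed = 1)
  d <- pp$dataset
  ids <- panel_ids(d, "microbial")
  m <- subject_correlation_matrix(d, "S16", ids)
  expect_identical(dim(m), c(6L, 6L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 6))
  expect_true(all(m >= -1 & m <= 1))

  # a subject with identical abundance in every tissue gives all ones
  vals <- matrix(rep(rnorm(10), each = 3), nrow = 3)
  d2 <- layout_dataset(c("decidua", "SI", "SI_mec"), vals,
                       subject = rep("s1", 3))
  m2 <- subject_correlation_matrix(d2, "s1", d2$metabolites$metabolite_id)
  expect_equal(m2, matrix(1, 3, 3), ignore_attr = TRUE)

  expect_error(subject_correlation_matrix(d, "S21", ids), "fewer than 2")
})

test_that("matched-subject decidua-GI coupling exceeds meconium-GI", {
  # Monte Carlo against the analytic ordering of expected correlations
  cfg <- fast_config(missing_rate = 0, age_slopes = NULL,
                     n_isomer_duplicates = 0)
  wins <- replicate(100, {
    sim <- generate_dataset(cfg, seed = sample.int(1e6, 1))
    d <- filter_samples(sim$dataset)
    lx <- met_dataset(log2(d$abundance), d$samples, d$metabolites,
                      scale = "log2")
    m <- subject_correlation_matrix(lx, "S16", panel_ids(lx, "microbial"))
    mean(m["decidua", c("SI", "LI")]) >
      mean(m[c("SI_mec", "LI_mec"), c("SI", "LI")])
  })
  expect_gte(mean(wins), 0.95)
})

test_that("correlation-class contrast applies the Welch test and labels", {
  # Welch oracle on constructed vectors
  set.seed(12)
  a <- rnorm(12, 0.88, 0.03)
  b <- rnorm(21, 0.62, 0.05)
  res <- contrast_correlation_classes(a, b, panel = "microbial")
  na <- length(a); nb <- length(b)
  t_oracle <- (mean(a) - mean(b)) / sqrt(var(a) / na + var(b) / nb)
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-12)
  expect_identical(res$label, "maternal")
  expect_lt(res$p_value, 0.001)

  res2 <- contrast_correlation_classes(b, a)
  expect_identical(res2$label, "local")

  same <- c(0.5, 0.6, 0.7)
  res3 <- contrast_correlation_classes(same, same)
  expect_equal(res3$t_statistic, 0)
  expect_identical(res3$label, "indeterminate")

  expect_error(contrast_correlation_classes(1, c(0.2, 0.3)), "at least 2")
})

test_that("panel attribution recovers the planted origin labels", {
  sim <- generate_dataset(sim_config(), seed = 41)
  pp <- preprocess(sim$dataset, seed = 2)
  att <- attribute_all_panels(pp$dataset)
  expect_identical(att$label[att$panel == "microbial"], "maternal")
  expect_identical(att$label[att$panel == "xenobiotic"], "maternal")
  expect_identical(att$label[att$panel == "fetal_derived"], "local")
  expect_identical(att$n_dec_gi[1], 88L)
  expect_identical(att$n_mec_gi[1], 209L)
  long <- attr(att, "pair_correlations")
  expect_identical(nrow(long), 3L * (88L + 209L))
  expect_true(all(long$rho >= -1 & long$rho <= 1, na.rm = TRUE))
})

test_that("degenerate panels give an indeterminate verdict with warning", {
  # every sample's microbial panel vector is constant -> rho undefined
  vals <- cbind(rep(1, 6), rep(1, 6), rep(1, 6), rnorm(6))
  d <- layout_dataset(c("decidua", "decidua", "SI", "SI", "SI_mec", "LI_mec"),
                      vals, panel = c(rep("microbial", 3), "other"))
  w <- capture_warnings(att <- attribute_all_panels(d, panels = "microbial"))
  expect_true(any(grepl("undefined", w)))
  expect_true(any(grepl("indeterminate", w)))
  expect_identical(att$label, "indeterminate")
})

test_that("subject-matched attribution uses only matched pairs", {
  sim <- generate_dataset(sim_config(), seed = 15)
  pp <- preprocess(sim$dataset, seed = 3)
  att <- attribute_all_panels(pp$dataset, mode = "subject_matched")
  dmatched <- enumerate_cross_tissue_pairs(pp$dataset, "decidua", "GI",
                                           "subject_matched")
  expect_identical(att$n_dec_gi[1], nrow(dmatched))
  expect_identical(att$label[att$panel == "microbial"], "maternal")
})
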