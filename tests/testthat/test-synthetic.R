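# Calibration of group SDs from published p-values, feature generation,
# and the synthetic-DICOM end-to-end round trip.

test_that("calibrate_sds inverts the Welch test and is monotone in p", {
  s <- calibrate_sds(6.21, 3.70, 18, 43, 0.036)
  # forward check: expected Welch statistic at that SD reproduces the p
  q <- 1 / 18 + 1 / 43
  df <- q^2 / ((1 / 18)^2 / 17 + (1 / 43)^2 / 42)
  t <- (6.21 - 3.70) / (s * sqrt(q))
  expect_equal(2 * pt(-t, df), 0.036, tolerance = 1e-6)
  # larger target p (weaker separation) needs a larger SD
  expect_gt(calibrate_sds(6.21, 3.70, 18, 43, 0.5), s)
  expect_gt(calibrate_sds(6.21, 3.70, 18, 43, 0.801),
            calibrate_sds(6.21, 3.70, 18, 43, 0.5))
  expect_error(calibrate_sds(5, 5, 18, 43, 0.5), "equal means")
  expect_error(calibrate_sds(6, 3, 18, 43, 1.5), "target_p")
})

test_that("Monte-Carlo round trip: cohorts at the calibrated SD reproduce the p", {
  # 500 normal cohorts drawn at the calibrated SD: the median Welch p must
  # bracket the calibration target within a factor of two
  for (target in c(0.036, 0.3)) {
    s <- calibrate_sds(6.21, 3.70, 18, 43, target)
    p <- artpredict:::with_seed(1234, replicate(500, {
      welch_t_test(rnorm(18, 6.21, s), rnorm(43, 3.70, s))$p
    }))
    expect_gt(median(p), target / 2)
    expect_lt(median(p), target * 2)
  }
})

test_that("generate_cohort_features is deterministic and recovers group means", {
  spec <- cohort_spec(seed = 6)
  co1 <- generate_cohort_features(spec)
  co2 <- generate_cohort_features(spec)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 671)
  expect_true(all(co1$bin_dose >= 0))
  expect_true(all(co1$ctv_high_per_bmi > 0))
  # large-sample recovery of the ART-group calibration targets within 1%
  big <- generate_cohort_features(cohort_spec(n_non_art = 0, n_art = 10000,
                                              seed = 7))
  per <- big[big$eqif_size == 3, ]     # one row per patient
  expect_equal(mean(per$ctv_high_per_bmi), 6.21, tolerance = 0.01)
  expect_equal(mean(per$oral_mean_dose) * 100, 3298, tolerance = 0.01)
  expect_equal(mean(per$total_mu), 644, tolerance = 0.01)
})

test_that("calibrated cohorts reproduce the published significance pattern", {
  # Calibrating a group SD to a published p-value p0 fixes the expected
  # Welch statistic at the p0 critical value, so the rejection rate of an
  # alpha = 0.05 test is the noncentral-t power at that effect, not a free
  # parameter: ~0.55 for the oral dose (p0 = 0.040), ~0.94 non-rejection
  # for MU (p0 = 0.801). CTV-high/BMI rejects more often (~0.7) because
  # zero-truncation shrinks its realized SDs below the calibrated scale.
  q <- 1 / 18 + 1 / 43
  df <- q^2 / ((1 / 18)^2 / 17 + (1 / 43)^2 / 42)
  crit <- qt(0.975, df)
  power_at <- function(p0) {
    ncp <- qt(1 - p0 / 2, df)
    1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
  }
  n_rep <- 200
  sig <- matrix(NA, n_rep, 3)
  for (i in seq_len(n_rep)) {
    co <- generate_cohort_features(cohort_spec(seed = 5000 + i))
    gs <- cohort_group_summary(co)
    sig[i, ] <- gs$p_t < 0.05
  }
  expect_gte(mean(sig[, 1]), 0.6)                        # ctv significant
  expect_lt(abs(mean(sig[, 3]) - power_at(0.040)), 0.1)  # oral at its power
  expect_gte(mean(!sig[, 2]), 0.6)                       # MU non-significant
})

test_that("DICOM generation round-trips to the drawn feature table", {
  spec <- cohort_spec(n_non_art = 2, n_art = 2, seed = 11)
  dir <- tempfile()
  manifest <- generate_dicom_cohort(spec, dir)
  expect_equal(nrow(manifest), 4)
  expect_true(all(file.exists(file.path(dir, paste0(
    manifest$patient_id, "_rtplan.dcm")))))
  ext <- extract_features(dir)
  ref <- generate_cohort_features(spec)
  expect_equal(nrow(ext), nrow(ref))
  expect_equal(ext$patient_id, ref$patient_id)
  # tolerances: bin doses within 10%, oral dose 2%, MU exact
  expect_true(all(abs(ext$bin_dose - ref$bin_dose) <=
                    pmax(0.1 * ref$bin_dose, 1e-6)))
  expect_equal(ext$oral_mean_dose, ref$oral_mean_dose, tolerance = 0.02)
  expect_equal(ext$total_mu, ref$total_mu, tolerance = 1e-8)
  expect_equal(ext$ctv_high_per_bmi, ref$ctv_high_per_bmi, tolerance = 1e-6)
  expect_equal(ext$label, ref$label)
  # arc count drives segment count: 90 per arc
  plan <- read_rtplan(file.path(dir, paste0(manifest$patient_id[1],
                                            "_rtplan.dcm")))
  segs <- sum(vapply(plan$beams, function(b) nrow(resample_arc(b)),
                     numeric(1)))
  expect_equal(segs, 90 * manifest$arcs[1])
})

test_that("an all-zero dose profile is an unsatisfiable generation request", {
  expect_error(artpredict:::write_synth_rtplan(tempfile(), "p",
                                               rep(0, 11), 600),
               "unsatisfiable")
})
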