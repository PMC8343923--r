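test_that("generated cohorts respect every printed range and are seeded", {
  prof <- demographic_profile()
  co <- generate_cohort(prof, n = 2000, seed = 12)
  expect_true(all(co$AGE >= 1 & co$AGE <= 72))
  expect_true(all(co$WT >= 3.98 & co$WT <= 17.7))
  expect_true(all(co$SCR >= 0.27 & co$SCR <= 0.51))
  expect_true(all(co$DOSE_PER_KG >= 1.78 & co$DOSE_PER_KG <= 2.73))
  expect_true(all(co$INTERVAL %in% c(8, 12)))
  expect_true(all(co$SEX %in% 0:1))
  co2 <- generate_cohort(prof, n = 2000, seed = 12)
  expect_identical(co, co2)
})

test_that("cohort summaries converge to the calibrated cohort means", {
  co <- generate_cohort(demographic_profile(), n = 20000, seed = 77)
  expect_lt(abs(mean(co$WT) - 10.13), 0.35)
  expect_lt(abs(mean(co$AGE) - 34.88), 1.5)
  expect_lt(abs(mean(co$DOSE_PER_KG) - 2.26), 0.02)
  expect_lt(abs(mean(co$SEX) - 0.591), 0.02)
  # interval: median 8 h with upper quartile 12 h
  expect_equal(median(co$INTERVAL), 8)
  expect_equal(unname(quantile(co$INTERVAL, 0.75)), 12)
  # weight increases with age in expectation (monotone growth curve)
  young <- co$AGE < 12
  expect_gt(mean(co$WT[!young]), mean(co$WT[young]))
})

test_that("a zero-variance profile collapses every subject onto the means", {
  prof <- demographic_profile(age_sd = 0, growth_cv = 0, dose_sd = 0,
                              scr_range = c(0.39, 0.39),
                              male_fraction = 1, p_interval_long = 0)
  co <- generate_cohort(prof, n = 10, seed = 1)
  expect_equal(length(unique(co$AGE)), 1)
  expect_equal(co$AGE[1], prof$age_mean)
  expect_equal(length(unique(co$WT)), 1)
  expect_equal(co$DOSE_PER_KG, rep(prof$dose_mean, 10))
  expect_equal(co$SCR, rep(0.39, 10))
  expect_equal(co$INTERVAL, rep(8, 10))
})

test_that("infeasible profiles are rejected up front", {
  expect_error(demographic_profile(weight_mean = 30), "infeasible")
  expect_error(demographic_profile(dose_mean = 5), "infeasible")
  # zero-noise curve that cannot reach the weight window
  prof <- demographic_profile(age_sd = 0, age_mean = 1, growth_cv = 0,
                              weight_mean = 10, weight_range = c(6, 17.7))
  expect_error(generate_cohort(prof, n = 5, seed = 1), "infeasible")
})

test_that("TDM datasets implement the peak/trough design contract", {
  m <- final_model_prop()
  co <- generate_cohort(demographic_profile(), seed = 31)
  dd <- generate_tdm_dataset(co, sampling_design(), m, seed = 32)
  for (id in unique(dd$ID)) {
    sub <- dd[dd$ID == id, ]
    expect_equal(sum(sub$EVID == 0), 2)      # exactly one peak + one trough
    expect_gte(sum(sub$EVID == 1), 4)        # at least four dose records
    tau <- co$INTERVAL[co$ID == id]
    peak <- sub[sub$EVID == 0 & sub$OBSCLASS == "peak", ]
    trough <- sub[sub$EVID == 0 & sub$OBSCLASS == "trough", ]
    # peak: 0.5 h after the end of the third dose's 30-min infusion
    expect_equal(peak$TIME, 2 * tau + 0.5 + 0.5)
    # trough: immediately before the fourth dose
    expect_equal(trough$TIME, 3 * tau)
    expect_lt(peak$TIME, trough$TIME)
  }
  dd2 <- generate_tdm_dataset(co, sampling_design(), m, seed = 32)
  expect_identical(dd, dd2)
})

test_that("a degenerate generating model reproduces the typical predictions exactly", {
  m0 <- gentamicin_final_model(residual = residual_model("additive", sigma_add = 0))
  m0$omega2[] <- 0
  co <- generate_cohort(demographic_profile(n = 5), seed = 41)
  dd <- generate_tdm_dataset(co, sampling_design(), m0, seed = 42)
  for (id in unique(dd$ID)) {
    sub <- dd[dd$ID == id, ]
    i <- which(co$ID == id)
    typ <- typical_params(m0, list(WT = co$WT[i]))
    doses <- sub[sub$EVID == 1, ]
    ev <- dose_events(doses$TIME, doses$AMT, doses$DUR)
    obs <- sub[sub$EVID == 0, ]
    expect_equal(obs$DV, predict_concentrations(typ, ev, obs$TIME),
                 tolerance = 1e-12)
  }
})

test_that("peak samples exceed trough samples under the reference model", {
  m <- final_model_prop()
  co <- generate_cohort(demographic_profile(), seed = 51)
  dd <- generate_tdm_dataset(co, sampling_design(), m, seed = 52)
  obs <- dd[dd$EVID == 0, ]
  peaks <- obs$DV[obs$OBSCLASS == "peak"]
  troughs <- obs$DV[obs$OBSCLASS == "trough"]
  expect_true(all(peaks > troughs))
})
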