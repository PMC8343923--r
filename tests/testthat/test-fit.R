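test_that("the optimizer never returns a worse objective than its start", {
  m <- final_model_prop()
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 12), seed = 51),
                             sampling_design(), m, seed = 52)
  ft <- suppressWarnings(fit_model(m, dd, control = fit_control(se = FALSE)))
  expect_lte(ft$neg2ll, ft$neg2ll_start + 1e-6)
  expect_equal(ft$aic, ft$neg2ll + 2 * ft$n_par)
})

test_that("structural parameters are recovered from near-noiseless rich data", {
  # 12 subjects x 10 samples, no BSV, tiny residual noise
  m <- final_model_prop(sigma_prop = 0.01)
  m$omega2[] <- 1e-10
  dd <- rich_dataset(m, n = 12, seed = 61,
                     tsamp = c(0.75, 1, 1.5, 2, 3, 4, 6, 9, 14, 23.5))
  tmpl <- gentamicin_final_model(residual = residual_model("proportional",
                                                           sigma_prop = 0.01))
  tmpl$theta <- c(CL = 3, Vc = 10, Vp = 3, Q = 0.5)
  tmpl$omega2 <- c(CL = 0, Vc = 0)
  ft <- suppressWarnings(
    fit_model(tmpl, dd, fixed = c("beta.WT~CL", "beta.WT~Vc", "omega2.CL",
                                  "omega2.Vc"),
              control = fit_control(se = FALSE, objective = "warm")))
  expect_lt(abs(ft$model$theta[["CL"]] / 4.64 - 1), 0.02)
  expect_lt(abs(ft$model$theta[["Vc"]] / 15.87 - 1), 0.02)
})

test_that("model comparison obeys its identities and refuses foreign fits", {
  m <- final_model_prop()
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 8), seed = 71),
                             sampling_design(), m, seed = 72)
  ft <- suppressWarnings(fit_model(m, dd, fixed = c("beta.WT~CL", "beta.WT~Vc"),
                                   control = fit_control(se = FALSE)))
  self <- compare_models(ft, ft)
  expect_equal(self$delta_neg2ll, 0)
  expect_equal(self$delta_aic, 0)
  expect_equal(self$preferred, "a")  # tie resolves to equal-or-fewer parameters
  # delta AIC == delta -2LL + 2 * delta p by construction
  expect_equal(self$delta_aic, self$delta_neg2ll + 2 * self$delta_par)
  dd2 <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 8), seed = 73),
                              sampling_design(), m, seed = 74)
  ft2 <- suppressWarnings(fit_model(m, dd2, fixed = c("beta.WT~CL", "beta.WT~Vc"),
                                    control = fit_control(se = FALSE)))
  expect_error(compare_models(ft, ft2), "identical dataset")
})

test_that("eta shrinkage follows its defining formula", {
  # fixed fixture: five EBEs against omega = 0.3
  ebes <- matrix(c(-0.1, 0.05, 0.12, -0.07, 0.02), ncol = 1,
                 dimnames = list(NULL, "CL"))
  out <- gentapk:::eta_shrinkage_values(ebes, c(CL = 0.09))
  expect_equal(out$raw, 1 - sd(ebes[, 1]) / 0.3, tolerance = 1e-12)
  # all-zero EBEs: complete shrinkage
  zero <- matrix(0, 5, 1, dimnames = list(NULL, "CL"))
  expect_equal(gentapk:::eta_shrinkage_values(zero, c(CL = 0.09))$shrinkage, 1)
  # negative raw values are clipped at zero for reporting
  wide <- matrix(c(-1, 1, -1, 1, 0), ncol = 1, dimnames = list(NULL, "CL"))
  outw <- gentapk:::eta_shrinkage_values(wide, c(CL = 0.01))
  expect_lt(outw$raw, 0)
  expect_equal(outw$shrinkage, 0)
})

test_that("fit reports carry the documented columns", {
  m <- final_model_prop()
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 8), seed = 81),
                             sampling_design(), m, seed = 82)
  ft <- suppressWarnings(fit_model(m, dd, fixed = c("beta.WT~CL", "beta.WT~Vc"),
                                   control = fit_control(se = FALSE)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(ft, path)
  rep <- read.csv(path)
  expect_identical(names(rep), c("parameter", "estimate", "se", "cv_percent"))
  expect_true(all(c("neg2ll", "aic", "theta.CL", "omega2.CL") %in% rep$parameter))
  expect_true(any(grepl("^shrinkage\\.", rep$parameter)))
})

test_that("standard errors are reported on the natural scale when requested", {
  m <- final_model_prop(sigma_prop = 0.05)
  dd <- rich_dataset(m, n = 60, seed = 91)
  ft <- suppressWarnings(
    fit_model(m, dd, fixed = c("beta.WT~CL", "beta.WT~Vc"),
              control = fit_control(se = TRUE, objective = "warm")))
  est <- ft$estimates
  expect_true(all(is.finite(est$se[est$parameter == "theta.CL"])))
  expect_gt(est$se[est$parameter == "theta.CL"], 0)
})
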