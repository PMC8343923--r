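test_that("bootstrap of cloned subjects gives zero-width confidence intervals", {
  m <- final_model_prop()
  one <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 1), seed = 3),
                              sampling_design(), m, seed = 4)
  clones <- do.call(rbind, lapply(1:6, function(k) {
    d <- one
    d$ID <- sprintf("C%02d", k)
    d
  }))
  class(clones) <- c("event_record", "data.frame")
  ft <- suppressWarnings(fit_model(m, clones,
                                   fixed = c("beta.WT~CL", "beta.WT~Vc"),
                                   control = fit_control(se = FALSE, restarts = 2)))
  boot <- suppressWarnings(pk_bootstrap(ft, n_replicates = 4, seed = 9,
                                        control = fit_control(se = FALSE, restarts = 1)))
  # every resample is the same dataset, so the replicate estimates coincide
  expect_lt(max(boot$table$ci_high - boot$table$ci_low), 1e-6)
})

test_that("bootstrap medians sit near the point estimates on a synthetic cohort", {
  m <- final_model_prop()
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(), seed = 41),
                             sampling_design(), m, seed = 42)
  ft <- suppressWarnings(fit_model(m, dd, fixed = c("beta.WT~CL", "beta.WT~Vc"),
                                   control = fit_control(se = FALSE)))
  boot <- suppressWarnings(pk_bootstrap(ft, n_replicates = 20, seed = 7,
                                        control = fit_control(se = FALSE, restarts = 1)))
  tab <- boot$table
  expect_true(all(tab$ci_low <= tab$median + 1e-9))
  expect_true(all(tab$median <= tab$ci_high + 1e-9))
  expect_equal(nrow(boot$estimates) + boot$n_failed, boot$n_requested)
  # the point estimate of CL lies inside its own bootstrap interval
  cl_row <- tab[tab$parameter == "theta.CL", ]
  cl_hat <- ft$estimates$estimate[ft$estimates$parameter == "theta.CL"]
  expect_gte(cl_hat, cl_row$ci_low)
  expect_lte(cl_hat, cl_row$ci_high)
  # seeded determinism
  boot2 <- suppressWarnings(pk_bootstrap(ft, n_replicates = 20, seed = 7,
                                         control = fit_control(se = FALSE, restarts = 1)))
  expect_identical(boot$table, boot2$table)
})

test_that("VPC quantiles are ordered, seeded and collapse without variability", {
  m <- final_model_prop()
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(), seed = 51),
                             sampling_design(), m, seed = 52)
  v <- vpc(m, dd, n_replicates = 80, seed = 3)
  tab <- v$table
  for (cls in unique(tab$class)) {
    for (src in c("observed", "simulated")) {
      vals <- tab$value[tab$class == cls & tab$source == src]
      expect_true(all(diff(vals) >= -1e-12))  # p5 <= p50 <= p95
    }
  }
  # per-replicate ordering of the simulated quantiles
  expect_true(all(v$replicate_quantiles[, , 1] <= v$replicate_quantiles[, , 2] + 1e-12))
  expect_true(all(v$replicate_quantiles[, , 2] <= v$replicate_quantiles[, , 3] + 1e-12))
  v2 <- vpc(m, dd, n_replicates = 80, seed = 3)
  expect_identical(v$table, v2$table)
  # degenerate generating model: all simulated quantiles equal the typical
  # prediction within each class structure
  m0 <- m
  m0$omega2[] <- 0
  m0$residual <- residual_model("additive", sigma_add = 0)
  v0 <- vpc(m0, dd, n_replicates = 5, seed = 1)
  sim <- v0$table[v0$table$source == "simulated", ]
  expect_equal(sim$ci_low, sim$value, tolerance = 1e-12)
  expect_equal(sim$ci_high, sim$value, tolerance = 1e-12)
})

test_that("VPC of self-simulated data covers ~90% of observations", {
  m <- final_model_prop()
  # data simulated from the model itself: the 5-95% simulated band should
  # contain close to 90% of the observations (binomial tolerance)
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 40), seed = 61),
                             sampling_design(), m, seed = 62)
  v <- vpc(m, dd, n_replicates = 150, seed = 8)
  tab <- v$table
  obs <- dd[dd$EVID == 0, ]
  inside <- 0
  for (cls in c("peak", "trough")) {
    lo <- tab$value[tab$class == cls & tab$source == "simulated" & tab$quantile == 0.05]
    hi <- tab$value[tab$class == cls & tab$source == "simulated" & tab$quantile == 0.95]
    dv <- obs$DV[obs$OBSCLASS == cls]
    inside <- inside + sum(dv >= lo & dv <= hi)
  }
  frac <- inside / nrow(obs)
  expect_gt(frac, 0.78)   # binomial noise around 0.90 with n = 80
  expect_lte(frac, 1.0)
})

test_that("evaluation tables are written with their documented columns", {
  m <- final_model_prop()
  dd <- generate_tdm_dataset(generate_cohort(demographic_profile(n = 6), seed = 71),
                             sampling_design(), m, seed = 72)
  v <- vpc(m, dd, n_replicates = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vpc_table(v, path)
  tab <- read.csv(path)
  expect_identical(names(tab),
                   c("class", "source", "quantile", "value", "ci_low", "ci_high"))
  ft <- suppressWarnings(fit_model(m, dd, fixed = c("beta.WT~CL", "beta.WT~Vc"),
                                   control = fit_control(se = FALSE, restarts = 1)))
  boot <- suppressWarnings(pk_bootstrap(ft, n_replicates = 4, seed = 2,
                                        control = fit_control(se = FALSE, restarts = 1)))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_bootstrap_table(boot, path2)
  tab2 <- read.csv(path2)
  expect_identical(names(tab2), c("parameter", "median", "ci_low", "ci_high"))
})
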