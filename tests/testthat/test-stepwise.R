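# The selection logic is exercised against a scripted likelihood: a fitter
# that returns a fixed -2LL for each model class (keyed by its effect set).
# This isolates the threshold/ordering rules from estimation numerics.

scripted_fitter <- function(table, default_step = 0.5) {
  function(model, data, init, control) {
    labs <- sort(vapply(model$effects, gentapk:::effect_label, character(1)))
    key <- if (!length(labs)) "(base)" else paste(labs, collapse = "|")
    n2ll <- if (!is.null(table[[key]])) {
      table[[key]]
    } else {
      100 - default_step * length(labs)  # unknown classes: tiny improvements
    }
    structure(list(model = model, neg2ll = n2ll, aic = n2ll,
                   estimates = data.frame(parameter = character(0),
                                          estimate = numeric(0)),
                   etas = NULL, ids = unique(data$ID), n_par = 0L,
                   convergence = TRUE, fingerprint = c(1, 1, 1, 1)),
              class = "pk_fit")
  }
}

scripted_base <- function(fitter, data) {
  fitter(population_model("two_compartment",
                          theta = c(CL = 1, Vc = 2, Vp = 4, Q = 0.6),
                          omega2 = c(CL = 0.1, Vc = 0.1),
                          residual = residual_model("proportional",
                                                    sigma_prop = 0.05)),
         data, NULL, NULL)
}

toy_data <- function() {
  m <- final_model_prop()
  generate_tdm_dataset(generate_cohort(demographic_profile(n = 6), seed = 5),
                       sampling_design(), m, seed = 6)
}

test_that("no candidate above the forward cutoff leaves the base model unchanged", {
  dd <- toy_data()
  fitter <- scripted_fitter(list("(base)" = 100))  # all candidates gain 0.5
  base <- scripted_base(fitter, dd)
  out <- stepwise_covariate_search(base, dd, fitter = fitter)
  expect_length(out$model$effects, 0)
  expect_true(all(out$trail$phase == "forward"))
  expect_true(all(out$trail$action == "tested"))
  expect_equal(nrow(out$trail), 8)  # 4 covariates x 2 targets, all logged
})

test_that("an effect between the cutoffs is added forward then removed backward", {
  dd <- toy_data()
  # WT~CL improves by 8: above 6.64 (enters), below 10.83 (cannot be kept)
  fitter <- scripted_fitter(list("(base)" = 100, "WT~CL" = 92))
  base <- scripted_base(fitter, dd)
  out <- stepwise_covariate_search(base, dd, fitter = fitter)
  expect_length(out$model$effects, 0)
  expect_true(any(out$trail$action == "added" & out$trail$effect == "WT~CL"))
  expect_true(any(out$trail$action == "removed" & out$trail$effect == "WT~CL"))
  removed <- out$trail[out$trail$action == "removed", ]
  expect_equal(removed$delta_neg2ll, 8, tolerance = 1e-9)
})

test_that("an effect above the retention cutoff is kept", {
  dd <- toy_data()
  fitter <- scripted_fitter(list("(base)" = 100, "WT~CL" = 88))
  base <- scripted_base(fitter, dd)
  out <- stepwise_covariate_search(base, dd, fitter = fitter)
  labs <- vapply(out$model$effects, gentapk:::effect_label, character(1))
  expect_identical(labs, "WT~CL")
  expect_equal(out$fit$neg2ll, 88)
})

test_that("the largest improvement wins and ties break lexicographically", {
  dd <- toy_data()
  fitter <- scripted_fitter(list("(base)" = 100, "WT~CL" = 80, "AGE~CL" = 85,
                                 "WT~CL|WT~Vc" = 60, "AGE~Vc|WT~CL" = 60))
  base <- scripted_base(fitter, dd)
  out <- stepwise_covariate_search(base, dd, fitter = fitter)
  added <- out$trail[out$trail$action == "added", ]
  expect_equal(added$effect[1], "WT~CL")  # 20 beats 15
  # second step: AGE~Vc and WT~Vc tie at 20; AGE~Vc is lexicographically first
  expect_equal(added$effect[2], "AGE~Vc")
})

test_that("failed candidate fits are skipped and logged, never fatal", {
  dd <- toy_data()
  failing <- function(model, data, init, control) {
    labs <- vapply(model$effects, gentapk:::effect_label, character(1))
    if ("SCR~CL" %in% labs) stop("synthetic failure")
    scripted_fitter(list("(base)" = 100, "WT~CL" = 88))(model, data, init, control)
  }
  base <- scripted_base(failing, dd)
  out <- stepwise_covariate_search(base, dd, fitter = failing)
  expect_true(any(grepl("skipped", out$trail$action)))
  labs <- vapply(out$model$effects, gentapk:::effect_label, character(1))
  expect_identical(labs, "WT~CL")
})

test_that("selected weight effects are re-referenced to 70 kg without changing the model", {
  dd <- toy_data()
  fitter <- scripted_fitter(list("(base)" = 100, "WT~CL" = 80))
  base <- scripted_base(fitter, dd)
  out <- stepwise_covariate_search(base, dd, fitter = fitter)
  eff <- out$model$effects[[1]]
  expect_equal(eff$ref, 70)
  # equivalence: theta70 * (wt/70)^e == theta_med * (wt/med)^e
  fit_eff <- out$fit$model$effects[[1]]
  wt <- 9.3
  expect_equal(out$model$theta[["CL"]] * (wt / 70)^eff$exponent,
               out$fit$model$theta[["CL"]] * (wt / fit_eff$ref)^fit_eff$exponent,
               tolerance = 1e-12)
})

test_that("the cutoff configuration is validated", {
  expect_error(stepwise_config(forward_cutoff = 11, backward_cutoff = 6), ">=")
  cfg <- stepwise_config()
  expect_equal(cfg$forward_cutoff, 6.64)
  expect_equal(cfg$backward_cutoff, 10.83)
})
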