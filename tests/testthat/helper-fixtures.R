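# Shared fixtures: models, dataset builders, independent oracles.
# All fixtures are generated in code under fixed seeds; nothing is stored.

published_theta <- c(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
published_cv <- c(CL = 27.89, Vc = 37.80)
published_exponents <- c(CL = 0.71, Vc = 0.93)

# final published model with assay-consistent proportional noise (the
# generator default used throughout the simulation-based tests)
final_model_prop <- function(sigma_prop = 0.05) {
  gentamicin_final_model(residual = residual_model("proportional",
                                                   sigma_prop = sigma_prop))
}

# covariate-free two-compartment template used as the stepwise base
base_model_2cpt <- function() {
  population_model(
    structure = "two_compartment",
    theta = c(CL = 1.2, Vc = 2.6, Vp = 4, Q = 0.6),
    omega2 = c(CL = cv_to_omega2(30), Vc = cv_to_omega2(30)),
    residual = residual_model("proportional", sigma_prop = 0.05))
}

# rich single-dose design: n subjects across the cohort weight range,
# 8 samples over 0-24 h, simulated from `model` with BSV + residual noise
rich_dataset <- function(model, n = 200, seed = 1,
                         tsamp = c(0.75, 1, 1.5, 2, 4, 6, 12, 23.5)) {
  gentapk:::with_seed(seed, {
    wt <- runif(n, 3.98, 17.7)
    etas <- gentapk:::sample_etas(model, n)
    rows <- lapply(seq_len(n), function(i) {
      amt <- 2.26 * wt[i]
      cf <- gentapk:::covariate_factors(model, list(WT = wt[i]))[1, ]
      mult <- function(p) {
        v <- model$theta[[p]] * cf[[p]]
        if (p %in% colnames(etas)) v * exp(etas[i, p]) else v
      }
      sp <- structural_params(mult("CL"), mult("Vc"), mult("Vp"), mult("Q"))
      f <- predict_concentrations(sp, dose_events(0, amt, 0.5), tsamp)
      sd_obs <- sqrt(model$residual$sigma_add^2 +
                       (model$residual$sigma_prop * f)^2)
      dv <- pmax(f + sd_obs * rnorm(length(f)), 1e-3)
      nt <- length(tsamp)
      cls <- ifelse(seq_len(nt) <= ceiling(nt / 2), "peak", "trough")
      data.frame(ID = sprintf("R%03d", i),
                 TIME = c(0, tsamp), EVID = c(1L, rep(0L, nt)),
                 AMT = c(amt, rep(NA, nt)),
                 DUR = c(0.5, rep(NA, nt)),
                 DV = c(NA, dv),
                 OBSCLASS = c(NA, cls),
                 WT = wt[i], AGE = 36, SEX = 0L, SCR = 0.39,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("event_record", "data.frame")
    out
  })
}

# small single-dose toy with well-spread samples (well-identified,
# unimodal subject posteriors) for the quadrature-oracle comparisons
toy_single_dose <- function(model, n = 3, seed = 1, tsamp = c(1, 3, 8)) {
  rich_dataset(model, n = n, seed = seed, tsamp = tsamp)
}

## ---------------------------------------------------------------------------
## independent oracles

# numerical integration of the two-compartment infusion ODE system,
# integrated piecewise between rate discontinuities (infusion on/off) so the
# solver never steps across a switch
ode_oracle <- function(params, doses, times) {
  CL <- params$CL; Vc <- params$Vc
  Vp <- if (is.null(params$Vp)) Inf else params$Vp
  Q <- if (is.null(params$Q)) 0 else params$Q
  rate_in <- function(t) {
    sum(doses$amount / doses$infusion_duration *
          (t >= doses$start_time - 1e-12 &
             t < doses$start_time + doses$infusion_duration - 1e-12))
  }
  breaks <- sort(unique(c(0, doses$start_time,
                          doses$start_time + doses$infusion_duration,
                          max(times))))
  breaks <- breaks[breaks <= max(times)]
  sol_t <- numeric(0)
  sol_c <- numeric(0)
  y <- c(0, 0)
  for (k in seq_len(length(breaks) - 1)) {
    lo <- breaks[k]; hi <- breaks[k + 1]
    r <- rate_in((lo + hi) / 2)  # constant within the piece
    derivs <- function(t, y, p) {
      d1 <- r - (CL / Vc) * y[1] - (Q / Vc) * y[1] + (Q / Vp) * y[2]
      d2 <- (Q / Vc) * y[1] - (Q / Vp) * y[2]
      list(c(d1, d2))
    }
    grid <- sort(unique(c(lo, times[times > lo & times < hi], hi)))
    out <- deSolve::lsoda(y, grid, derivs, NULL, rtol = 1e-11, atol = 1e-13)
    sol_t <- c(sol_t, out[, 1])
    sol_c <- c(sol_c, out[, 2] / Vc)
    y <- unname(out[nrow(out), 2:3])
  }
  keep <- !duplicated(sol_t)
  approx(sol_t[keep], sol_c[keep], xout = times, rule = 2)$y
}

# adaptive 64-node Gauss-Hermite marginal -2LL: an independent path (its own
# g definition, base-R optimizer, pracma quadrature nodes)
agh_neg2ll <- function(data, model, nq = 64) {
  panel <- gentapk:::prepare_panel(data)
  om <- model$omega2[model$omega2 > 0]
  sa <- model$residual$sigma_add
  sp <- model$residual$sigma_prop
  q <- pracma::gaussHermite(nq)
  total <- 0
  for (i in seq_len(panel$ns)) {
    rows <- which(panel$obs_subj == i)
    wt <- panel$cov$WT[i]
    di <- which(data$EVID == 1 & data$ID == panel$ids[i])
    ev <- dose_events(data$TIME[di], data$AMT[di], data$DUR[di])
    cf <- gentapk:::covariate_factors(model, list(WT = wt))[1, ]
    g <- function(eta) {
      if (any(!is.finite(eta)) || any(abs(eta) > 25)) return(1e8)
      cl <- model$theta[["CL"]] * cf[["CL"]] * exp(eta[1])
      vc <- model$theta[["Vc"]] * cf[["Vc"]] * exp(eta[2])
      if (!is.finite(cl) || !is.finite(vc) || cl <= 0 || vc <= 0 ||
          cl > 1e6 || vc > 1e6) return(1e8)
      p <- structural_params(cl, vc, model$theta[["Vp"]], model$theta[["Q"]])
      f <- predict_concentrations(p, ev, panel$obs_time[rows])
      v <- sa^2 + (sp * f)^2
      if (any(v <= 0)) return(1e8)
      sum((panel$dv[rows] - f)^2 / (2 * v) + 0.5 * log(2 * pi * v)) +
        sum(eta^2 / (2 * om) + 0.5 * log(2 * pi * om))
    }
    starts <- expand.grid(e1 = c(-1, 0, 1), e2 = c(-1, 0, 1))
    os <- lapply(seq_len(nrow(starts)), function(k) {
      optim(as.numeric(starts[k, ]), g, method = "BFGS",
            control = list(reltol = 1e-14))
    })
    o <- os[[which.min(vapply(os, `[[`, numeric(1), "value"))]]
    H <- optimHess(o$par, g)
    Cm <- chol(solve(H))
    tot <- 0
    for (j in seq_len(nq)) {
      for (k in seq_len(nq)) {
        u <- c(q$x[j], q$x[k])
        x <- o$par + sqrt(2) * as.vector(t(Cm) %*% u)
        tot <- tot + q$w[j] * q$w[k] * exp(sum(u^2)) * exp(-(g(x) - o$value))
      }
    }
    total <- total - 2 * (log(tot) - o$value + log(2) +
                            0.5 * log(det(solve(H))))
  }
  total
}
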