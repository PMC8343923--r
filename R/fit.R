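## Maximum marginal-likelihood estimation. All positive parameters (typical
## values, BSV variances, residual sigmas) are estimated on the log scale;
## covariate-effect coefficients on their natural scale (power exponents) or
## log scale (categorical fractions). The outer objective (Laplace -2LL) is
## minimized with stats::nlminb, warm-starting the per-subject empirical
## Bayes modes across outer iterations.

#' Fit control settings
#'
#' @param rel_tol Relative -2LL convergence tolerance of the outer optimizer.
#' @param max_iter Outer iteration cap.
#' @param se Compute standard errors from a finite-difference Hessian.
#' @param trace Record the outer objective trajectory.
#' @param sigma_add_floor,sigma_prop_floor Lower bounds for the residual
#'   sigmas during estimation. Designs with as many observations per subject
#'   as random effects are degenerate as sigma tends to 0 (the marginal
#'   likelihood can grow without the residual model meaning anything), so
#'   sigmas are kept above a small fraction of the assay scale.
#' @param restarts Cap on the restart-verification loop around PORT's
#'   "false convergence" exit (see Details); warm-started screening fits use
#'   a smaller cap than reported reference fits.
#' @param objective `"cold"` evaluates the Laplace objective from scratch at
#'   every outer iteration (deterministic, robust to inner-mode branch
#'   switching; the default for sparse designs with <= 3 observations per
#'   subject), `"warm"` tracks the inner modes across iterations (faster;
#'   the default for rich designs), `"auto"` picks by design density.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(rel_tol = 1e-8, max_iter = 500L, se = TRUE,
                        trace = FALSE, sigma_add_floor = 0.005,
                        sigma_prop_floor = 0.01,
                        objective = c("auto", "cold", "warm"),
                        restarts = 8L) {
  structure(list(rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 se = se, trace = trace, sigma_add_floor = sigma_add_floor,
                 sigma_prop_floor = sigma_prop_floor,
                 objective = match.arg(objective),
                 restarts = as.integer(restarts)),
            class = "fit_control")
}

## parameter packing ---------------------------------------------------------

## Build the estimated-parameter specification for a model template.
## `fixed` names parameters excluded from estimation ("theta.Vp",
## "beta.WT~CL", "omega2.CL", "sigma.add", ...).
build_parspec <- function(model, fixed = character(0)) {
  entries <- list()
  add <- function(name, type, trans, value, target = NULL) {
    if (name %in% fixed) return()
    entries[[length(entries) + 1L]] <<- list(name = name, type = type,
                                             trans = trans, value = value,
                                             target = target)
  }
  for (p in names(model$theta)) {
    add(paste0("theta.", p), "theta", "log", model$theta[[p]], p)
  }
  for (k in seq_along(model$effects)) {
    e <- model$effects[[k]]
    if (e$fixed) next
    nm <- paste0("beta.", effect_label(e))
    if (e$type == "power") add(nm, "effect", "identity", e$exponent, k)
    else add(nm, "effect", "log", e$fraction, k)
  }
  for (p in names(model$omega2)) {
    v <- model$omega2[[p]]
    add(paste0("omega2.", p), "omega", "log", if (v > 0) v else cv_to_omega2(30),
        p)
  }
  fam <- model$residual$family
  if (fam %in% c("additive", "combined")) {
    add("sigma.add", "sigma", "log",
        if (model$residual$sigma_add > 0) model$residual$sigma_add else 0.1, "add")
  }
  if (fam %in% c("proportional", "combined")) {
    add("sigma.prop", "sigma", "log",
        if (model$residual$sigma_prop > 0) model$residual$sigma_prop else 0.05, "prop")
  }
  entries
}

to_trans <- function(spec, natural) {
  vapply(seq_along(spec), function(i) {
    if (spec[[i]]$trans == "log") log(natural[i]) else natural[i]
  }, numeric(1))
}

to_natural <- function(spec, trans) {
  vapply(seq_along(spec), function(i) {
    if (spec[[i]]$trans == "log") exp(trans[i]) else trans[i]
  }, numeric(1))
}

## instantiate a model from the template + natural-scale estimate vector
apply_estimates <- function(model, spec, natural) {
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    v <- natural[i]
    if (s$type == "theta") {
      model$theta[[s$target]] <- v
    } else if (s$type == "effect") {
      e <- model$effects[[s$target]]
      if (e$type == "power") e$exponent <- v else e$fraction <- v
      model$effects[[s$target]] <- e
    } else if (s$type == "omega") {
      model$omega2[[s$target]] <- v
    } else if (s$target == "add") {
      model$residual$sigma_add <- v
    } else {
      model$residual$sigma_prop <- v
    }
  }
  model
}

## crude pooled (eta = 0) nonlinear least squares to seed the typical values
pooled_init <- function(model, panel, spec) {
  th_idx <- which(vapply(spec, function(s) s$type %in% c("theta", "effect"),
                         logical(1)))
  if (!length(th_idx)) return(model)
  start <- to_trans(spec, vapply(spec, `[[`, numeric(1), "value"))[th_idx]
  sse <- function(p) {
    nat <- vapply(spec, `[[`, numeric(1), "value")
    nat[th_idx] <- to_natural(spec[th_idx], p)
    m <- apply_estimates(model, spec, nat)
    typ <- panel_typicals(m, panel)
    pred <- panel_predict(panel, typ$CL, typ$Vc, typ$Vp, typ$Q)
    sum((panel$dv - pred)^2)
  }
  opt <- tryCatch(
    stats::nlminb(start, sse, control = list(iter.max = 100, rel.tol = 1e-6)),
    error = function(e) NULL)
  if (is.null(opt)) return(model)
  nat <- vapply(spec, `[[`, numeric(1), "value")
  nat[th_idx] <- to_natural(spec[th_idx], opt$par)
  apply_estimates(model, spec, nat)
}

#' Fit a population model by Laplace maximum likelihood
#'
#' Estimates the free parameters of a [population_model] template from an
#' event-record dataset by minimizing the Laplace-approximated marginal -2LL
#' (see [marginal_neg2ll]). Typical values start from a naive pooled
#' least-squares fit unless `init` overrides them; BSV starts at 30 %CV and
#' residual sigmas at assay-scale defaults when the template carries zeros.
#'
#' @param model A [population_model] template. Template values define the
#'   structure (which parameters exist, which effects, which BSV terms) and
#'   serve as fallback initial values.
#' @param data Event-record dataset.
#' @param fixed Character vector of parameter names not to estimate (e.g.
#'   `"theta.Vp"`, `"beta.WT~CL"`, `"sigma.add"`).
#' @param init Optional named numeric vector of natural-scale starting
#'   values, named as in `fixed` (overrides the pooled-NLS seed).
#' @param control A [fit_control] list.
#' @details Standard errors come from a finite-difference Hessian of the
#'   Laplace objective. On rich designs they are well behaved; on sparse
#'   peak/trough designs the objective carries small kinks where a
#'   subject's inner mode switches branch, which can corrupt the local
#'   curvature — parameter uncertainty for sparse data should be taken from
#'   [pk_bootstrap] instead.
#' @return A `pk_fit` object: `model` (template updated with estimates),
#'   `estimates` table (name, estimate, se), `neg2ll`, `aic`, `n_par`,
#'   `etas` (empirical Bayes modes), `shrinkage`, `convergence`, `message`,
#'   `iterations`, `n_evals`, and the `data` the fit used.
#' @export
fit_model <- function(model, data, fixed = character(0), init = NULL,
                      control = fit_control()) {
  stopifnot(inherits(model, "population_model"))
  panel <- if (is.list(data) && !is.null(data$pair_obs)) data else prepare_panel(data)
  spec <- build_parspec(model, fixed)
  p <- length(spec)
  if (p == 0L) stop_validation("no free parameters to estimate")
  if (p >= panel$n_obs) {
    stop_validation("model not identifiable: ", p, " parameters for ",
                    panel$n_obs, " observations")
  }
  ## starting values: a warm-started fit trusts its init; a de novo fit
  ## tries several starts (pooled least squares, the template itself, and a
  ## data heuristic) and keeps the best optimum
  nat_from_model <- function(m) {
    vapply(seq_along(spec), function(i) {
      s <- spec[[i]]
      switch(s$type,
             theta = m$theta[[s$target]],
             effect = {
               e <- m$effects[[s$target]]
               if (e$type == "power") e$exponent else e$fraction
             },
             omega = {
               w <- m$omega2[[s$target]]
               if (w > 0) w else cv_to_omega2(30)
             },
             sigma = s$value)
    }, numeric(1))
  }
  if (!is.null(init)) {
    start_nat <- nat_from_model(model)
    nm <- vapply(spec, `[[`, character(1), "name")
    hit <- match(names(init), nm)
    start_nat[hit[!is.na(hit)]] <- init[!is.na(hit)]
    start_nats <- list(start_nat)
  } else {
    heur <- model
    peak_dv <- stats::quantile(panel$dv, 0.9, names = FALSE)
    amt_med <- stats::median(panel$pair_R0 * panel$pair_dur)
    if (is.finite(peak_dv) && peak_dv > 0 && is.finite(amt_med)) {
      vc0 <- amt_med / peak_dv
      heur$theta[["Vc"]] <- max(vc0, 1e-3)
      heur$theta[["CL"]] <- max(0.3 * vc0, 1e-3)
      if (model$structure == "two_compartment") {
        heur$theta[["Vp"]] <- max(vc0, 1e-3)
        heur$theta[["Q"]] <- max(0.1 * vc0, 1e-3)
      }
    }
    start_nats <- list(nat_from_model(pooled_init(model, panel, spec)),
                       nat_from_model(model),
                       nat_from_model(heur))
  }
  start_nats <- lapply(start_nats, function(v) {
    for (i in seq_along(spec)) {
      if (spec[[i]]$trans == "log" && v[i] <= 0) v[i] <- 1e-3
    }
    v
  })
  starts <- lapply(start_nats, function(v) to_trans(spec, v))
  ## box constraints (transformed scale); the sigma floors remove the
  ## degenerate sigma -> 0 spike of #obs-per-subject == #etas designs
  bounds <- vapply(spec, function(s) {
    switch(s$type,
           theta = c(log(1e-5), log(1e6)),
           effect = if (s$trans == "log") c(log(1e-3), log(1e3)) else c(-10, 10),
           omega = c(log(1e-8), log(25)),
           sigma = if (s$target == "add") c(log(control$sigma_add_floor), log(100))
                   else c(log(control$sigma_prop_floor), log(10)))
  }, numeric(2))
  lower <- bounds[1, ]
  upper <- bounds[2, ]
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  env <- new.env(parent = emptyenv())
  env$etas <- NULL
  env$neval <- 0L
  env$trace <- if (control$trace) numeric(0) else NULL
  cold <- switch(control$objective,
                 cold = TRUE, warm = FALSE,
                 auto = panel$n_obs / panel$ns <= 3)
  objective <- function(ptrans) {
    nat <- to_natural(spec, ptrans)
    if (any(!is.finite(nat))) return(1e10)
    m <- apply_estimates(model, spec, nat)
    typ <- panel_typicals(m, panel)
    om <- m$omega2[m$omega2 > 0]
    res <- tryCatch(
      laplace_neg2ll(panel, typ, om, m$residual$sigma_add,
                     m$residual$sigma_prop, if (cold) NULL else env$etas),
      error = function(e) NULL)
    env$neval <- env$neval + 1L
    if (is.null(res) || !is.finite(res$neg2ll)) return(1e10)
    if (!cold) env$etas <- res$etas
    if (!is.null(env$trace)) env$trace <- c(env$trace, res$neg2ll)
    res$neg2ll
  }
  n2ll_start <- objective(starts[[1]])
  ## The Laplace surface can carry small kinks where a subject's inner mode
  ## switches branch; PORT then reports "false convergence". Re-verify such
  ## solutions by restarting at the solution: a stationary point is accepted
  ## when a restart no longer improves the objective materially.
  run_from <- function(start) {
    opt <- stats::nlminb(start, objective, lower = lower, upper = upper,
                         control = list(rel.tol = control$rel_tol,
                                        iter.max = control$max_iter,
                                        eval.max = 8L * control$max_iter))
    iterations <- opt$iterations
    converged <- opt$convergence == 0 && opt$objective < 1e10
    restarts <- 0L
    while (!converged && opt$objective < 1e10 && restarts < control$restarts) {
      restarts <- restarts + 1L
      opt2 <- stats::nlminb(opt$par, objective, lower = lower, upper = upper,
                            control = list(rel.tol = control$rel_tol,
                                           iter.max = control$max_iter,
                                           eval.max = 8L * control$max_iter))
      iterations <- iterations + opt2$iterations
      improved <- opt$objective - opt2$objective
      if (opt2$objective <= opt$objective) opt <- opt2
      if (opt$convergence == 0 || improved < 0.01) {
        converged <- opt$objective < 1e10
        break
      }
    }
    list(opt = opt, iterations = iterations, converged = converged)
  }
  best <- run_from(starts[[1]])
  if (length(starts) > 1L) {
    for (k in 2:length(starts)) {
      ## a later start is only pursued when it begins at a materially
      ## different objective region or the current optimum looks poor
      alt <- run_from(starts[[k]])
      if (alt$opt$objective < best$opt$objective - 1e-6) best <- alt
    }
  }
  opt <- best$opt
  iterations <- best$iterations
  converged <- best$converged
  nat <- to_natural(spec, opt$par)
  fitted_model <- apply_estimates(model, spec, nat)
  ## final consistent evaluation (refreshes EBEs at the solution)
  env$etas <- NULL
  final <- marginal_neg2ll(fitted_model, panel)
  se_nat <- rep(NA_real_, p)
  if (control$se) {
    ## the covariance Hessian is evaluated on the warm-tracking objective
    ## seeded at the solution's modes: locally smooth, unlike the cold
    ## objective whose multistart can switch basins between FD points
    env$etas <- final$etas
    objective_se <- function(ptrans) {
      nat <- to_natural(spec, ptrans)
      if (any(!is.finite(nat))) return(1e10)
      m <- apply_estimates(model, spec, nat)
      typ <- panel_typicals(m, panel)
      om <- m$omega2[m$omega2 > 0]
      res <- tryCatch(
        laplace_neg2ll(panel, typ, om, m$residual$sigma_add,
                       m$residual$sigma_prop, env$etas),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$neg2ll)) return(1e10)
      res$neg2ll
    }
    hess <- tryCatch(stats::optimHess(opt$par, objective_se),
                     error = function(e) NULL)
    if (!is.null(hess)) {
      vc <- tryCatch(2 * solve(hess), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0)) {
        se_t <- sqrt(diag(vc))
        se_nat <- vapply(seq_along(spec), function(i) {
          if (spec[[i]]$trans == "log") abs(nat[i]) * se_t[i] else se_t[i]
        }, numeric(1))
      } else {
        warning("singular Hessian: standard errors not available")
      }
    } else {
      warning("Hessian evaluation failed: standard errors not available")
    }
  }
  est <- data.frame(parameter = vapply(spec, `[[`, character(1), "name"),
                    estimate = nat, se = se_nat, stringsAsFactors = FALSE)
  om_pos <- fitted_model$omega2[fitted_model$omega2 > 0]
  shr <- eta_shrinkage_values(final$etas, om_pos)
  fit <- structure(list(
    model = fitted_model, template = model, spec = spec,
    estimates = est, neg2ll = final$neg2ll, aic = final$neg2ll + 2 * p,
    n_par = p, etas = final$etas, shrinkage = shr,
    convergence = converged,
    message = if (converged) "converged" else paste0("not converged: ", opt$message),
    neg2ll_start = n2ll_start, iterations = iterations,
    n_evals = env$neval, trace = env$trace,
    fingerprint = panel$fingerprint, ids = panel$ids,
    data = if (inherits(data, "event_record")) data else NULL,
    fixed = fixed), class = "pk_fit")
  if (!converged) warning("fit did not converge: ", opt$message)
  fit
}

eta_shrinkage_values <- function(etas, omega2) {
  if (is.null(etas) || !length(omega2)) return(NULL)
  raw <- 1 - apply(etas, 2, stats::sd) / sqrt(omega2[colnames(etas)])
  data.frame(parameter = colnames(etas), shrinkage = pmax(raw, 0), raw = raw)
}

#' Eta shrinkage of a fit
#'
#' Shrinkage per BSV parameter, `1 - SD(EBE etas)/omega`. Values are clipped
#' at 0 for reporting; the raw (possibly negative) value is carried in the
#' `raw` column. Parameters with `omega = 0` are not reported.
#'
#' @param fit A `pk_fit` object.
#' @return Data frame with columns `parameter`, `shrinkage`, `raw`.
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (is.null(fit$shrinkage)) {
    stop_validation("fit carries no empirical Bayes estimates (no BSV)")
  }
  fit$shrinkage
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (Laplace)\n")
  cat(sprintf("  -2LL = %.3f, AIC = %.3f, %d parameters, %s\n",
              x$neg2ll, x$aic, x$n_par, x$message))
  est <- x$estimates
  est$estimate <- signif(est$estimate, 5)
  est$se <- signif(est$se, 3)
  print(est, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$neg2ll / 2, df = object$n_par, class = "logLik")
}

#' Compare two fits of the same dataset
#'
#' @param fit_a,fit_b `pk_fit` objects fitted to the identical dataset.
#' @return List with `delta_neg2ll` (`-2LL(a) - -2LL(b)`), `delta_aic`,
#'   `delta_par` and `preferred` (`"a"` or `"b"`, by AIC; ties resolved to
#'   the fit with fewer parameters, then to `"a"`).
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "pk_fit"), inherits(fit_b, "pk_fit"))
  if (!isTRUE(all.equal(fit_a$fingerprint, fit_b$fingerprint))) {
    stop_validation("fits are not on the identical dataset; comparison refused")
  }
  d2 <- fit_a$neg2ll - fit_b$neg2ll
  da <- fit_a$aic - fit_b$aic
  preferred <- if (da < 0) "a" else if (da > 0) "b" else {
    if (fit_a$n_par <= fit_b$n_par) "a" else "b"
  }
  list(delta_neg2ll = d2, delta_aic = da,
       delta_par = fit_a$n_par - fit_b$n_par, preferred = preferred)
}

#' Write a machine-readable fit report
#'
#' Writes the estimates table as CSV with fixed columns `parameter`,
#' `estimate`, `se`, `cv_percent` (filled for BSV variances) plus summary
#' rows `neg2ll`, `aic`, and per-parameter `shrinkage.<p>` rows.
#'
#' @param fit A `pk_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "pk_fit"))
  est <- fit$estimates
  est$cv_percent <- NA_real_
  is_om <- grepl("^omega2\\.", est$parameter)
  est$cv_percent[is_om] <- omega2_to_cv(est$estimate[is_om])
  extra <- data.frame(parameter = c("neg2ll", "aic"),
                      estimate = c(fit$neg2ll, fit$aic),
                      se = NA_real_, cv_percent = NA_real_)
  if (!is.null(fit$shrinkage)) {
    extra <- rbind(extra, data.frame(
      parameter = paste0("shrinkage.", fit$shrinkage$parameter),
      estimate = fit$shrinkage$shrinkage, se = NA_real_, cv_percent = NA_real_))
  }
  out <- rbind(est, extra)
  out$estimate <- fmt_num(out$estimate)
  out$se <- fmt_num(out$se)
  out$cv_percent <- fmt_num(out$cv_percent)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
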