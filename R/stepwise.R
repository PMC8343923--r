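## Stepwise covariate model building on the -2LL scale: forward addition
## (chi-square 1 df at alpha = 0.01 -> Delta -2LL > 6.64) followed by
## backward deletion (alpha = 0.001 -> an effect is retained only if its
## removal worsens -2LL by at least 10.83).

#' Stepwise search configuration
#'
#' @param forward_cutoff -2LL improvement required to add a covariate
#'   (default 6.64, chi-square 1 df at p = 0.01).
#' @param backward_cutoff -2LL worsening below which a covariate is deleted
#'   in the backward phase (default 10.83, chi-square 1 df at p = 0.001).
#' @param covariates Candidate covariate column names.
#' @param targets Candidate structural parameters.
#' @return List of class `stepwise_config`.
#' @export
stepwise_config <- function(forward_cutoff = 6.64, backward_cutoff = 10.83,
                            covariates = c("WT", "AGE", "SEX", "SCR"),
                            targets = c("CL", "Vc")) {
  if (backward_cutoff < forward_cutoff) {
    stop_validation("backward cutoff must be >= forward cutoff")
  }
  structure(list(forward_cutoff = forward_cutoff,
                 backward_cutoff = backward_cutoff,
                 covariates = covariates, targets = targets),
            class = "stepwise_config")
}

## candidate effect for a covariate/target pair; continuous covariates are
## power-on-normalized, SEX a fractional multiplier on the non-reference
## category. Candidates are centered at the cohort median during the search
## (decorrelating the exponent from the typical value, whose reference would
## otherwise sit far outside the pediatric weight range); selected weight
## effects are re-referenced to the conventional 70 kg afterwards.
candidate_effect <- function(covariate, target, data) {
  if (covariate == "SEX") {
    return(covariate_effect(target, "SEX", "fraction", fraction = 1))
  }
  first <- !duplicated(data$ID)
  ref <- stats::median(data[[covariate]][first])
  covariate_effect(target, covariate, "power", ref = ref, exponent = 0)
}

## change the reference value of a power effect without changing the model:
## theta (cov/ref_old)^e  ==  theta (ref_new/ref_old)^e (cov/ref_new)^e
rereference_effects <- function(model, covariate = "WT", ref_new = 70) {
  for (k in seq_along(model$effects)) {
    e <- model$effects[[k]]
    if (e$type == "power" && e$covariate == covariate && e$ref != ref_new) {
      model$theta[[e$param]] <- model$theta[[e$param]] *
        (ref_new / e$ref)^e$exponent
      e$ref <- ref_new
      model$effects[[k]] <- e
    }
  }
  model
}

## warm-start vector from a fit, restricted to names present in the new spec
warm_init <- function(fit) {
  stats::setNames(fit$estimates$estimate, fit$estimates$parameter)
}

## regression-informed starting values for a candidate effect: regress the
## parent fit's EBE etas for the target parameter on the (transformed)
## covariate; the slope seeds the coefficient, the residual variance seeds
## the shrunken BSV, the intercept adjusts the typical value
ebe_regression_init <- function(fit, eff, data) {
  etas <- fit$etas
  if (is.null(etas) || !eff$param %in% colnames(etas)) return(NULL)
  first <- !duplicated(data$ID)
  covv <- data[[eff$covariate]][first][match(fit$ids, data$ID[first])]
  x <- if (eff$type == "power") log(covv / eff$ref) else covv
  y <- etas[, eff$param]
  if (stats::var(x) < 1e-12) return(NULL)
  b <- stats::coef(stats::lm(y ~ x))
  resid_var <- stats::var(y - b[1] - b[2] * x)
  init <- warm_init(fit)
  init[paste0("beta.", effect_label(eff))] <-
    if (eff$type == "power") b[2] else exp(b[2])
  init[paste0("theta.", eff$param)] <-
    init[paste0("theta.", eff$param)] * exp(b[1])
  init[paste0("omega2.", eff$param)] <- max(resid_var, 1e-4)
  init
}

#' Stepwise forward/backward covariate search
#'
#' Starting from a converged base fit, repeatedly adds the single
#' covariate-parameter effect with the largest -2LL improvement while that
#' improvement exceeds the forward cutoff, then deletes any retained effect
#' whose removal worsens -2LL by less than the backward cutoff. Candidate
#' fits that fail are skipped and logged, never fatal. Ties in the forward
#' phase break to the larger improvement, then lexicographic effect name.
#'
#' @param base_fit A converged `pk_fit` for the covariate-free base model.
#' @param data The event-record dataset the base fit used.
#' @param config A [stepwise_config].
#' @param control [fit_control] used for candidate fits (standard errors off
#'   and a short restart-verification cap, for speed; the selected model can
#'   be refit at reference settings afterwards).
#' @param fitter Fitting backend, `function(model, data, init, control)`;
#'   defaults to [fit_model]. Exposed so the selection logic can be exercised
#'   against scripted likelihood values.
#' @return List with `fit` (final `pk_fit`), `model`, and `trail`, a data
#'   frame recording every tested effect (`phase`, `step`, `effect`,
#'   `delta_neg2ll`, `action`).
#' @export
stepwise_covariate_search <- function(base_fit, data, config = stepwise_config(),
                                      control = fit_control(se = FALSE, restarts = 2L),
                                      fitter = NULL) {
  stopifnot(inherits(base_fit, "pk_fit"))
  if (!base_fit$convergence) stop_validation("base fit is not converged")
  if (is.null(fitter)) {
    fitter <- function(model, data, init, control) {
      fit_model(model, data, init = init, control = control)
    }
  }
  current <- base_fit
  added <- character(0)
  trail <- data.frame(phase = character(0), step = integer(0),
                      effect = character(0), delta_neg2ll = numeric(0),
                      action = character(0), stringsAsFactors = FALSE)
  log_row <- function(phase, step, eff, delta, action) {
    trail[nrow(trail) + 1L, ] <<- list(phase, step, eff, delta, action)
  }
  in_model <- function(model) vapply(model$effects, effect_label, character(1))
  ## cache of the best fit seen for each nested model class (keyed by its
  ## effect set): every -2LL difference is taken between the best-known fits
  ## of the two classes, so an optimization lucky-strike in one class cannot
  ## masquerade as a covariate effect
  cache <- new.env(parent = emptyenv())
  class_key <- function(model) {
    labs <- sort(in_model(model))
    if (!length(labs)) "(base)" else paste(labs, collapse = "|")
  }
  cache_put <- function(fit) {
    key <- class_key(fit$model)
    old <- cache[[key]]
    if (is.null(old) || fit$neg2ll < old$neg2ll) cache[[key]] <- fit
    cache[[key]]
  }
  cache_put(base_fit)
  fit_multi <- function(m, inits) {
    ft <- NULL
    for (init in inits) {
      ft_s <- tryCatch(fitter(m, data, init = init, control = control),
                       error = function(e) NULL)
      if (!is.null(ft_s) && is.finite(ft_s$neg2ll)) {
        ft_s <- cache_put(ft_s)
        if (is.null(ft) || ft_s$neg2ll < ft$neg2ll) ft <- ft_s
      }
    }
    ft
  }
  ## starting values for fitting a candidate model (parent + one new effect):
  ## the null start (coefficient at "no effect") plus a regression-informed
  ## start from regressing the parent's empirical Bayes etas on the
  ## covariate — the standard EBE screening device, which lands the
  ## optimizer inside the basin where the covariate absorbs part of the BSV
  candidate_inits <- function(parent, eff) {
    par_name <- paste0("beta.", effect_label(eff))
    inits <- list(c(warm_init(parent),
                    stats::setNames(if (eff$type == "power") 0 else 1,
                                    par_name)))
    reg <- ebe_regression_init(parent, eff, data)
    if (!is.null(reg)) inits <- c(inits, list(reg))
    inits
  }
  ## model and starting values with effect `lab` removed from a fit, its
  ## contribution folded back into the target's BSV and typical value
  removal_setup <- function(fit, lab) {
    m <- fit$model
    keep <- vapply(m$effects, function(e) effect_label(e) != lab, logical(1))
    dropped <- m$effects[[which(!keep)[1]]]
    m$effects <- m$effects[keep]
    init <- warm_init(fit)
    init <- init[!names(init) %in% paste0("beta.", lab)]
    first <- !duplicated(data$ID)
    covv <- data[[dropped$covariate]][first]
    x <- if (dropped$type == "power") log(covv / dropped$ref) else covv
    coefv <- if (dropped$type == "power") dropped$exponent else log(dropped$fraction)
    om_name <- paste0("omega2.", dropped$param)
    if (om_name %in% names(init)) {
      init[om_name] <- init[om_name] + coefv^2 * stats::var(x)
    }
    th_name <- paste0("theta.", dropped$param)
    if (th_name %in% names(init)) {
      init[th_name] <- init[th_name] * exp(coefv * mean(x))
    }
    list(model = m, init = init, effect = dropped)
  }
  step <- 0L
  ## forward additions. A candidate fit can escape a local optimum of the
  ## parameters it shares with the parent, which would wrongly credit the
  ## escape to the new covariate; before accepting, the parent is therefore
  ## re-polished from the winning candidate's solution (nested consistency)
  ## and the improvement recomputed against the better parent.
  repeat {
    step <- step + 1L
    if (step > 50L) break
    present <- in_model(current$model)
    cands <- expand.grid(covariate = config$covariates, target = config$targets,
                         stringsAsFactors = FALSE)
    cands$label <- paste0(cands$covariate, "~", cands$target)
    cands <- cands[!cands$label %in% present, , drop = FALSE]
    cands <- cands[order(cands$label), , drop = FALSE]
    if (!nrow(cands)) break
    best <- NULL
    for (i in seq_len(nrow(cands))) {
      m <- current$model
      eff <- candidate_effect(cands$covariate[i], cands$target[i], data)
      m$effects <- c(m$effects, list(eff))
      ft <- fit_multi(m, candidate_inits(current, eff))
      if (is.null(ft)) {
        log_row("forward", step, cands$label[i], NA_real_, "fit failed, skipped")
        next
      }
      delta <- current$neg2ll - ft$neg2ll
      log_row("forward", step, cands$label[i], delta, "tested")
      if (is.null(best) || delta > best$delta + 1e-9) {
        best <- list(fit = ft, label = cands$label[i], delta = delta)
      }
    }
    if (is.null(best) || best$delta <= config$forward_cutoff) break
    ## nested-consistency polish: refit the parent class from the winning
    ## candidate's solution before trusting the improvement
    rs <- removal_setup(best$fit, best$label)
    parent2 <- tryCatch(fitter(rs$model, data, init = rs$init,
                               control = control),
                        error = function(e) NULL)
    if (!is.null(parent2) && is.finite(parent2$neg2ll)) cache_put(parent2)
    cur2 <- cache[[class_key(current$model)]]
    if (cur2$neg2ll < current$neg2ll - 1e-6) {
      current <- cur2
      best$delta <- current$neg2ll - best$fit$neg2ll
      log_row("forward", step, best$label, best$delta,
              "parent re-polished, improvement recomputed")
      if (best$delta <= config$forward_cutoff) next
    }
    current <- best$fit
    added <- c(added, best$label)
    log_row("forward", step, best$label, best$delta, "added")
  }
  ## backward deletions (weakest removable effect first). Symmetrically, the
  ## "without" fit can discover a better shared-parameter basin; the standing
  ## "with" fit is then re-polished from it before the worsening is judged.
  repeat {
    step <- step + 1L
    if (step > 100L) break
    removable <- intersect(added, in_model(current$model))
    if (!length(removable)) break
    weakest <- NULL
    restart_sweep <- FALSE
    for (lab in sort(removable)) {
      rs <- removal_setup(current, lab)
      ft <- tryCatch(fitter(rs$model, data, init = rs$init, control = control),
                     error = function(e) NULL)
      if (!is.null(ft) && is.finite(ft$neg2ll)) ft <- cache_put(ft)
      ft <- cache[[class_key(rs$model)]] %||% ft
      if (is.null(ft) || !is.finite(ft$neg2ll)) {
        log_row("backward", step, lab, NA_real_, "fit failed, skipped")
        next
      }
      ## symmetric polish: the "without" solution may reveal a better basin
      ## for the standing "with" fit
      fit_multi(current$model, candidate_inits(ft, rs$effect))
      with_best <- cache[[class_key(current$model)]]
      if (with_best$neg2ll < current$neg2ll - 1e-6) {
        ## deltas already collected this sweep are stale: restart the sweep
        current <- with_best
        restart_sweep <- TRUE
        log_row("backward", step, lab, NA_real_,
                "standing fit re-polished, sweep restarted")
        break
      }
      delta <- ft$neg2ll - current$neg2ll  # worsening caused by removal
      log_row("backward", step, lab, delta, "tested")
      if (delta < config$backward_cutoff &&
          (is.null(weakest) || delta < weakest$delta)) {
        weakest <- list(fit = ft, label = lab, delta = delta)
      }
    }
    if (restart_sweep) next
    if (is.null(weakest)) break
    current <- weakest$fit
    added <- setdiff(added, weakest$label)
    log_row("backward", step, weakest$label, weakest$delta, "removed")
  }
  final_model <- rereference_effects(current$model, "WT", 70)
  list(fit = current, model = final_model, trail = trail)
}
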