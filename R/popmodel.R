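## Population layer: covariate effects, between-subject variability (BSV) and
## residual-error families on top of the structural model.
##
## Individual parameters follow the standard NLME construction
##   P_i = theta_P * prod(covariate factors) * exp(eta_P,i),
## with eta ~ N(0, omega^2) independent across parameters (log-normal BSV).
## Continuous covariates enter as powers of the normalized covariate
## (e.g. allometric (WT/70)^k), categorical covariates as a multiplicative
## fraction relative to the reference category.

#' Covariate effect on a structural parameter
#'
#' @param param Target structural parameter name (`"CL"`, `"Vc"`, `"Vp"`, `"Q"`).
#' @param covariate Covariate name (e.g. `"WT"`, `"AGE"`, `"SCR"`, `"SEX"`).
#' @param type `"power"` for continuous covariates, factor
#'   `(cov/ref)^exponent`; `"fraction"` for 0/1 categorical covariates, factor
#'   `fraction^cov` (reference category 0 has factor 1).
#' @param ref Reference value for continuous covariates (> 0); e.g. 70 kg for
#'   allometric weight scaling.
#' @param exponent Power exponent (continuous).
#' @param fraction Multiplier for the non-reference category (> 0, categorical).
#' @param fixed Logical; if `TRUE` the effect coefficient is not estimated.
#' @return Object of class `covariate_effect`.
#' @examples
#' covariate_effect("CL", "WT", "power", ref = 70, exponent = 0.71)
#' @export
covariate_effect <- function(param, covariate, type = c("power", "fraction"),
                             ref = NULL, exponent = NULL, fraction = NULL,
                             fixed = FALSE) {
  type <- match.arg(type)
  if (type == "power") {
    if (is.null(ref) || !is.finite(ref) || ref <= 0) {
      stop_validation("power covariate effect requires a positive reference value")
    }
    exponent <- exponent %||% 0
    if (!is.finite(exponent)) stop_validation("exponent must be finite")
  } else {
    fraction <- fraction %||% 1
    if (!is.finite(fraction) || fraction <= 0) {
      stop_validation("categorical fraction must be finite and > 0")
    }
  }
  structure(list(param = param, covariate = covariate, type = type, ref = ref,
                 exponent = exponent, fraction = fraction, fixed = isTRUE(fixed)),
            class = "covariate_effect")
}

effect_label <- function(e) paste0(e$covariate, "~", e$param)

#' Residual (unexplained) error model
#'
#' @param family One of `"additive"` (constant SD, mg/L), `"proportional"`
#'   (SD proportional to the prediction) or `"combined"`.
#' @param sigma_add Additive SD, mg/L (>= 0).
#' @param sigma_prop Proportional SD, fraction (>= 0).
#' @return Object of class `residual_model`.
#' @export
residual_model <- function(family = c("additive", "proportional", "combined"),
                           sigma_add = 0, sigma_prop = 0) {
  family <- match.arg(family)
  if (sigma_add < 0 || sigma_prop < 0) stop_validation("sigmas must be >= 0")
  if (family == "additive") sigma_prop <- 0
  if (family == "proportional") sigma_add <- 0
  structure(list(family = family, sigma_add = sigma_add, sigma_prop = sigma_prop),
            class = "residual_model")
}

#' Residual variance at a prediction
#'
#' Returns the residual variance `sigma_add^2 + (sigma_prop * f)^2` implied by
#' the error model at prediction `f` (families drop the absent term).
#'
#' @param model A [residual_model].
#' @param prediction Predicted concentration(s), mg/L (>= 0).
#' @return Variance(s), (mg/L)^2.
#' @export
residual_variance <- function(model, prediction) {
  stopifnot(inherits(model, "residual_model"))
  if (any(prediction < 0)) stop_validation("predictions must be >= 0")
  model$sigma_add^2 + (model$sigma_prop * prediction)^2
}

#' Convert between %CV and log-scale variance
#'
#' Between-subject variability is log-normal; the exact mapping between the
#' reported coefficient of variation (percent) and the log-scale variance
#' omega^2 is `omega2 = log(1 + (cv/100)^2)` with inverse
#' `cv = 100 sqrt(exp(omega2) - 1)`.
#'
#' @param cv_percent CV, percent (>= 0).
#' @return `cv_to_omega2`: log-scale variance; `omega2_to_cv`: CV in percent.
#' @examples
#' cv_to_omega2(27.89)
#' omega2_to_cv(cv_to_omega2(27.89))
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0)) {
    stop_domain("cv_percent must be finite and >= 0")
  }
  log(1 + (cv_percent / 100)^2)
}

#' @rdname cv_to_omega2
#' @param omega2 Log-scale variance (>= 0).
#' @export
omega2_to_cv <- function(omega2) {
  if (any(!is.finite(omega2)) || any(omega2 < 0)) {
    stop_domain("omega2 must be finite and >= 0")
  }
  100 * sqrt(exp(omega2) - 1)
}

#' Population pharmacokinetic model
#'
#' Combines a structural family, typical parameter values, covariate effects,
#' log-normal between-subject variability and a residual-error model.
#'
#' @param structure `"two_compartment"` or `"one_compartment"`.
#' @param theta Named numeric vector of typical values: `CL`, `Vc` (and `Vp`,
#'   `Q` for two compartments), all > 0.
#' @param effects List of [covariate_effect] objects; each must target a
#'   parameter present in `theta`.
#' @param omega2 Named numeric vector of log-scale BSV variances (>= 0);
#'   names must be a subset of `names(theta)` (the reported model carries BSV
#'   on `CL` and `Vc`).
#' @param residual A [residual_model].
#' @return Object of class `population_model`.
#' @export
population_model <- function(structure = c("two_compartment", "one_compartment"),
                             theta, effects = list(),
                             omega2 = c(CL = 0, Vc = 0),
                             residual = residual_model("additive", sigma_add = 0.1)) {
  structure_fam <- match.arg(structure)
  need <- if (structure_fam == "two_compartment") c("CL", "Vc", "Vp", "Q") else c("CL", "Vc")
  if (!all(need %in% names(theta))) {
    stop_validation("theta must contain ", paste(need, collapse = ", "))
  }
  theta <- theta[need]
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop_validation("typical values must be finite and > 0")
  }
  for (e in effects) {
    if (!inherits(e, "covariate_effect")) stop_validation("effects must be covariate_effect objects")
    if (!e$param %in% names(theta)) {
      stop_validation("covariate effect targets unknown parameter '", e$param, "'")
    }
  }
  if (is.null(names(omega2)) || !all(names(omega2) %in% names(theta))) {
    stop_validation("omega2 must be named after structural parameters")
  }
  if (any(omega2 < 0)) stop_validation("omega2 entries must be >= 0")
  stopifnot(inherits(residual, "residual_model"))
  base::structure(list(structure = structure_fam, theta = theta,
                       effects = effects, omega2 = omega2, residual = residual),
                  class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population PK model (%s)\n", gsub("_", "-", x$structure)))
  cat("  theta:", paste(names(x$theta), signif(x$theta, 4), sep = "=", collapse = ", "), "\n")
  if (length(x$effects)) {
    for (e in x$effects) {
      val <- if (e$type == "power") sprintf("(%s/%g)^%.3g", e$covariate, e$ref, e$exponent)
             else sprintf("%.3g^%s", e$fraction, e$covariate)
      cat(sprintf("  %s on %s: x %s\n", e$covariate, e$param, val))
    }
  }
  cv <- omega2_to_cv(x$omega2)
  cat("  BSV (%CV):", paste(names(cv), sprintf("%.1f", cv), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  residual: %s (sigma_add=%.4g, sigma_prop=%.4g)\n",
              x$residual$family, x$residual$sigma_add, x$residual$sigma_prop))
  invisible(x)
}

## multiplicative covariate factor for one subject-row of covariates,
## vectorized over subjects: covariates is a data.frame/list of vectors
covariate_factors <- function(model, covariates) {
  n <- if (length(covariates)) length(covariates[[1]]) else 1L
  pars <- names(model$theta)
  fac <- matrix(1, nrow = n, ncol = length(pars), dimnames = list(NULL, pars))
  for (e in model$effects) {
    if (is.null(covariates[[e$covariate]])) {
      stop_validation("missing covariate '", e$covariate, "' required by the model")
    }
    v <- covariates[[e$covariate]]
    f <- if (e$type == "power") (v / e$ref)^e$exponent else e$fraction^v
    fac[, e$param] <- fac[, e$param] * f
  }
  fac
}

#' Typical structural parameters for given covariates
#'
#' Applies the model's covariate effects to the typical values: each power
#' effect multiplies its target by `(cov/ref)^exponent`, each categorical
#' effect by `fraction^cov`. Parameters without effects are returned
#' unchanged.
#'
#' @param model A [population_model].
#' @param covariates Named list/vector of covariate values (must include every
#'   covariate the model uses).
#' @return A [structural_params] object.
#' @examples
#' m <- gentamicin_final_model()
#' typical_params(m, list(WT = 70))$CL   # 4.64 L/h at the 70-kg reference
#' @export
typical_params <- function(model, covariates) {
  stopifnot(inherits(model, "population_model"))
  fac <- covariate_factors(model, lapply(covariates, function(v) v[1]))
  th <- model$theta * fac[1, names(model$theta)]
  structural_params(CL = th[["CL"]], Vc = th[["Vc"]],
                    Vp = if ("Vp" %in% names(th)) th[["Vp"]] else NULL,
                    Q = if ("Q" %in% names(th)) th[["Q"]] else NULL)
}

#' Sample individual parameters
#'
#' Draws log-normal between-subject random effects (`eta ~ N(0, omega^2)`,
#' independent across parameters) and returns the realized individual
#' parameters `theta * covariate factor * exp(eta)`.
#'
#' @param model A [population_model].
#' @param covariates Named list of covariate values for one subject.
#' @param seed Integer seed (draw is deterministic given the seed), or `NULL`
#'   to use the current RNG stream.
#' @return List with `eta` (named vector) and `params` ([structural_params]).
#' @export
sample_individual <- function(model, covariates, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  eta <- with_seed(seed, {
    stats::rnorm(length(model$omega2), 0, sqrt(model$omega2))
  })
  names(eta) <- names(model$omega2)
  fac <- covariate_factors(model, lapply(covariates, function(v) v[1]))[1, ]
  th <- model$theta * fac[names(model$theta)]
  mult <- rep(1, length(th)); names(mult) <- names(th)
  mult[names(eta)] <- exp(eta)
  th <- th * mult
  list(eta = eta,
       params = structural_params(CL = th[["CL"]], Vc = th[["Vc"]],
                                  Vp = if ("Vp" %in% names(th)) th[["Vp"]] else NULL,
                                  Q = if ("Q" %in% names(th)) th[["Q"]] else NULL))
}

## eta draws for n subjects as an n x d matrix (d = number of BSV parameters)
sample_etas <- function(model, n) {
  om <- model$omega2[model$omega2 > 0]
  d <- length(om)
  m <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
  m <- sweep(m, 2, sqrt(om), `*`)
  colnames(m) <- names(om)
  m
}

#' Published pediatric gentamicin model
#'
#' Convenience constructor for the final two-compartment pediatric gentamicin
#' model: `CL = 4.64 (WT/70)^0.71` L/h, `Vc = 15.87 (WT/70)^0.93` L,
#' `Vp = 4.11` L, `Q = 0.62` L/h, BSV 27.89 %CV on CL and 37.80 %CV on Vc,
#' additive residual error 0.011 mg/L. `Vp` and `Q` carry no covariates; an
#' optional allometric mode scales them too (`Vp` linearly, `Q` with exponent
#' 0.75) for sensitivity analysis.
#'
#' @param residual A [residual_model]; defaults to the reported additive
#'   error. Simulation-oriented callers often pass an assay-consistent
#'   proportional error instead.
#' @param scale_vp_q Logical; if `TRUE`, adds fixed allometric weight effects
#'   on `Vp` (exponent 1) and `Q` (exponent 0.75). Default `FALSE` (the
#'   reported model retains weight on `CL` and `Vc` only).
#' @return A [population_model].
#' @export
gentamicin_final_model <- function(residual = residual_model("additive", sigma_add = 0.011),
                                   scale_vp_q = FALSE) {
  eff <- list(
    covariate_effect("CL", "WT", "power", ref = 70, exponent = 0.71),
    covariate_effect("Vc", "WT", "power", ref = 70, exponent = 0.93)
  )
  if (scale_vp_q) {
    eff <- c(eff, list(
      covariate_effect("Vp", "WT", "power", ref = 70, exponent = 1, fixed = TRUE),
      covariate_effect("Q", "WT", "power", ref = 70, exponent = 0.75, fixed = TRUE)
    ))
  }
  population_model(
    structure = "two_compartment",
    theta = c(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62),
    effects = eff,
    omega2 = c(CL = cv_to_omega2(27.89), Vc = cv_to_omega2(37.80)),
    residual = residual
  )
}

## ---------------------------------------------------------------------------
## YAML serialization (bit-exact round trip: numbers stored as %.17g strings)

num_out <- function(x) sprintf("%.17g", x)
num_in <- function(x) as.numeric(x)

#' Serialize a population model to YAML
#'
#' Writes/reads the model (typical values, covariate effects, BSV as %CV and
#' as omega^2, residual sigmas) to a YAML config. Numbers are stored in full
#' precision so that a write/read round trip reproduces the model exactly.
#'
#' @param model A [population_model].
#' @param path File path.
#' @return `write_model_yaml` returns `path` invisibly; `read_model_yaml`
#'   returns a [population_model].
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  obj <- list(
    structure = model$structure,
    theta = lapply(as.list(model$theta), num_out),
    effects = lapply(model$effects, function(e) {
      list(param = e$param, covariate = e$covariate, type = e$type,
           ref = if (is.null(e$ref)) NULL else num_out(e$ref),
           exponent = if (is.null(e$exponent)) NULL else num_out(e$exponent),
           fraction = if (is.null(e$fraction)) NULL else num_out(e$fraction),
           fixed = e$fixed)
    }),
    bsv = list(omega2 = lapply(as.list(model$omega2), num_out),
               cv_percent = lapply(as.list(omega2_to_cv(model$omega2)), num_out)),
    residual = list(family = model$residual$family,
                    sigma_add = num_out(model$residual$sigma_add),
                    sigma_prop = num_out(model$residual$sigma_prop))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  theta <- vapply(obj$theta, num_in, numeric(1))
  effects <- lapply(obj$effects, function(e) {
    covariate_effect(e$param, e$covariate, e$type,
                     ref = if (is.null(e$ref)) NULL else num_in(e$ref),
                     exponent = if (is.null(e$exponent)) NULL else num_in(e$exponent),
                     fraction = if (is.null(e$fraction)) NULL else num_in(e$fraction),
                     fixed = isTRUE(e$fixed))
  })
  omega2 <- vapply(obj$bsv$omega2, num_in, numeric(1))
  population_model(structure = obj$structure, theta = theta, effects = effects,
                   omega2 = omega2,
                   residual = residual_model(obj$residual$family,
                                             sigma_add = num_in(obj$residual$sigma_add),
                                             sigma_prop = num_in(obj$residual$sigma_prop)))
}
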