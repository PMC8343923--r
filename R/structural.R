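## Closed-form one- and two-compartment IV infusion kinetics.
##
## All times are hours since the first dose start, amounts are mg,
## concentrations are mg/L. The two-compartment disposition is expressed in
## the usual hybrid (macro) constants alpha/beta obtained from the micro rate
## constants k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp; a single infusion of rate
## R0 over duration T contributes, per exponential term i with unit-impulse
## coefficient C_i and rate lambda_i,
##   during infusion:  R0 * C_i/lambda_i * (1 - exp(-lambda_i t))
##   after infusion :  R0 * C_i/lambda_i * (1 - exp(-lambda_i T)) *
##                     exp(-lambda_i (t - T))
## and multi-dose profiles are sums of shifted single-dose solutions
## (superposition; the kinetics are linear).

#' Structural disposition parameters
#'
#' Container for the structural parameters of a one- or two-compartment
#' intravenous model: clearance `CL` (L/h), central volume `Vc` (L) and, for
#' the two-compartment case, peripheral volume `Vp` (L) and intercompartmental
#' clearance `Q` (L/h). Omit `Vp`/`Q` for a one-compartment model.
#'
#' @param CL Clearance, L/h (> 0).
#' @param Vc Central volume of distribution, L (> 0).
#' @param Vp Peripheral volume, L (> 0), or `NULL` for one-compartment.
#' @param Q Intercompartmental clearance, L/h (> 0), or `NULL`.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
#' @export
structural_params <- function(CL, Vc, Vp = NULL, Q = NULL) {
  if (xor(is.null(Vp), is.null(Q))) {
    stop_validation("Vp and Q must be supplied together (two-compartment) or both omitted")
  }
  vals <- c(CL = CL, Vc = Vc)
  if (!is.null(Vp)) vals <- c(vals, Vp = Vp, Q = Q)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("all structural parameters must be finite and strictly positive; got ",
                paste(names(vals), "=", signif(vals, 6), collapse = ", "))
  }
  structure(list(CL = CL, Vc = Vc, Vp = Vp, Q = Q,
                 n_compartments = if (is.null(Vp)) 1L else 2L),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("%d-compartment structural parameters:\n", x$n_compartments))
  cat(sprintf("  CL = %.4g L/h, Vc = %.4g L", x$CL, x$Vc))
  if (x$n_compartments == 2L) cat(sprintf(", Vp = %.4g L, Q = %.4g L/h", x$Vp, x$Q))
  cat("\n")
  invisible(x)
}

#' Dose events
#'
#' A validated table of infusion dose events. Events must be sorted by start
#' time, amounts non-negative and durations strictly positive (boluses are
#' represented as short infusions if needed).
#'
#' @param start_time Numeric vector, h since first dose start.
#' @param amount Numeric vector, mg (>= 0).
#' @param infusion_duration Numeric vector, h (> 0); recycled if length 1.
#' @return A `data.frame` of class `dose_events` with columns `start_time`,
#'   `amount`, `infusion_duration`.
#' @export
dose_events <- function(start_time, amount, infusion_duration) {
  n <- length(start_time)
  if (length(amount) == 1L) amount <- rep(amount, n)
  if (length(infusion_duration) == 1L) infusion_duration <- rep(infusion_duration, n)
  if (length(amount) != n || length(infusion_duration) != n) {
    stop_validation("start_time, amount and infusion_duration must have equal length")
  }
  if (n == 0L) stop_validation("at least one dose event is required")
  if (any(!is.finite(start_time)) || any(!is.finite(amount)) ||
      any(!is.finite(infusion_duration))) {
    stop_validation("dose event fields must be finite")
  }
  if (any(amount < 0)) stop_validation("dose amounts must be >= 0")
  if (any(infusion_duration <= 0)) stop_validation("infusion durations must be > 0")
  if (is.unsorted(start_time)) stop_validation("dose events must be sorted by start_time")
  structure(data.frame(start_time = as.numeric(start_time),
                       amount = as.numeric(amount),
                       infusion_duration = as.numeric(infusion_duration)),
            class = c("dose_events", "data.frame"))
}

#' Dosing regimen
#'
#' A weight-normalized repeated-dose regimen: `dose_per_kg` (mg/kg) given as
#' an infusion of `infusion_duration` hours every `interval` hours, either for
#' a finite number of doses or (the default) at steady state.
#'
#' @param dose_per_kg Dose, mg/kg (> 0).
#' @param interval Dosing interval tau, h.
#' @param infusion_duration Infusion duration, h; must satisfy
#'   `interval > infusion_duration > 0`.
#' @param n_doses Number of doses, or `NULL` (default) for steady state.
#' @return An object of class `regimen`.
#' @export
regimen <- function(dose_per_kg, interval, infusion_duration, n_doses = NULL) {
  if (!is.finite(dose_per_kg) || dose_per_kg <= 0) stop_validation("dose_per_kg must be > 0")
  if (!is.finite(interval) || !is.finite(infusion_duration) ||
      infusion_duration <= 0 || interval <= infusion_duration) {
    stop_validation("regimen requires interval > infusion_duration > 0")
  }
  if (!is.null(n_doses) && (n_doses < 1 || n_doses != round(n_doses))) {
    stop_validation("n_doses must be a positive integer or NULL for steady state")
  }
  structure(list(dose_per_kg = dose_per_kg, interval = interval,
                 infusion_duration = infusion_duration, n_doses = n_doses),
            class = "regimen")
}

## ---------------------------------------------------------------------------
## disposition constants

#' Derive micro and hybrid disposition constants
#'
#' Converts structural parameters to first-order micro rate constants
#' (`k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`) and the hybrid constants
#' `alpha >= beta`, the roots of `x^2 - (k10+k12+k21) x + k10 k21 = 0`. For a
#' one-compartment model `k12 = k21 = 0`, `alpha = k10` and `beta = 0`.
#'
#' @param params A [structural_params] object.
#' @return Object of class `disposition_constants` with fields `k10`, `k12`,
#'   `k21`, `alpha`, `beta`.
#' @examples
#' derive_disposition_constants(
#'   structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62))
#' @export
derive_disposition_constants <- function(params) {
  stopifnot(inherits(params, "structural_params"))
  d <- .disposition(params$CL, params$Vc,
                    params$Vp %||% NA_real_, params$Q %||% NA_real_,
                    two_cpt = params$n_compartments == 2L)
  structure(list(k10 = d$k10, k12 = d$k12, k21 = d$k21,
                 alpha = d$lam1, beta = d$lam2),
            class = "disposition_constants")
}

## Vectorized disposition machinery. CL, Vc (and for two-compartment Vp, Q)
## are equal-length vectors (one element per subject). Returns rate constants
## lam1 >= lam2 and the unit-impulse central-concentration coefficients
## C1, C2 such that a unit bolus gives C1 exp(-lam1 t) + C2 exp(-lam2 t).
## Repeated roots (alpha == beta) are separated by a relative 1e-9
## perturbation so a single biexponential code path serves everywhere.
.disposition <- function(CL, Vc, Vp, Q, two_cpt) {
  k10 <- CL / Vc
  if (!two_cpt) {
    z <- rep(0, length(k10))
    return(list(k10 = k10, k12 = z, k21 = z,
                lam1 = k10, lam2 = z, C1 = 1 / Vc, C2 = z))
  }
  k12 <- Q / Vc
  k21 <- Q / Vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- s * s - 4 * p
  disc[disc < 0] <- 0
  root <- sqrt(disc)
  lam1 <- (s + root) / 2
  lam2 <- (s - root) / 2
  ## guard the measure-zero repeated-root case with an epsilon split
  rep_root <- (lam1 - lam2) <= 1e-9 * lam1
  if (any(rep_root)) {
    eps <- 1e-9 * lam1[rep_root]
    lam1[rep_root] <- lam1[rep_root] + eps
    lam2[rep_root] <- pmax(lam2[rep_root] - eps, 0)
  }
  denom <- Vc * (lam1 - lam2)
  C1 <- (lam1 - k21) / denom
  C2 <- (k21 - lam2) / denom
  list(k10 = k10, k12 = k12, k21 = k21, lam1 = lam1, lam2 = lam2,
       C1 = C1, C2 = C2)
}

## Single-exponential infusion contribution at elapsed time te (since dose
## start), for rate R0, duration dur; vectorized over everything. C == 0 or
## te <= 0 contribute nothing (lam == 0 only ever occurs with C == 0).
.inf_term <- function(lam, C, R0, dur, te) {
  out <- numeric(length(te))
  act <- te > 0 & C != 0 & lam > 0
  if (!any(act)) return(out)
  l <- lam[act]; cc <- C[act]; r <- R0[act]; d <- dur[act]; t <- te[act]
  ti <- pmin(t, d)
  out[act] <- r * cc / l * (1 - exp(-l * ti)) * exp(-l * pmax(t - d, 0))
  out
}

#' Predict central-compartment concentrations
#'
#' Evaluates the closed-form concentration-time profile of a one- or
#' two-compartment IV infusion model under an arbitrary multi-dose schedule by
#' superposition of single-infusion solutions. Times before the first dose
#' return 0.
#'
#' @param params A [structural_params] object.
#' @param doses A [dose_events] table.
#' @param times Numeric vector of times, h (>= 0 not required; pre-dose times
#'   give 0).
#' @return Numeric vector of concentrations, mg/L, one per time.
#' @export
predict_concentrations <- function(params, doses, times) {
  stopifnot(inherits(params, "structural_params"))
  if (!inherits(doses, "dose_events")) {
    doses <- dose_events(doses$start_time, doses$amount, doses$infusion_duration)
  }
  if (any(!is.finite(times))) stop_validation("times must be finite")
  d <- .disposition(params$CL, params$Vc, params$Vp %||% NA_real_,
                    params$Q %||% NA_real_, params$n_compartments == 2L)
  nt <- length(times)
  nd <- nrow(doses)
  ## expand (time, dose) pairs and superpose
  te <- rep(times, times = nd) - rep(doses$start_time, each = nt)
  R0 <- rep(doses$amount / doses$infusion_duration, each = nt)
  dur <- rep(doses$infusion_duration, each = nt)
  one <- rep(1, nt * nd)
  contrib <- .inf_term(d$lam1 * one, d$C1 * one, R0, dur, te) +
    .inf_term(d$lam2 * one, d$C2 * one, R0, dur, te)
  .colsum_groups(contrib, rep(seq_len(nt), times = nd), nt)
}

## sum `x` within integer groups 1..n (fast rowsum wrapper)
.colsum_groups <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

## Vectorized steady-state peak/trough for repeated infusions: amt (mg), dur
## (h), tau (h) may be vectors matched to the disposition vectors. Peak is at
## infusion end (t = dur), trough at interval end (t = tau), both under the
## geometric-accumulation (infinite superposition) steady-state solution
##   Css(t >= dur) = R0 * C_i/lam_i (1-exp(-lam_i dur)) exp(-lam_i (t-dur)) /
##                   (1 - exp(-lam_i tau)).
.ss_metrics <- function(disp, amt, dur, tau) {
  R0 <- amt / dur
  term <- function(lam, C, t_after) {
    out <- numeric(length(R0))
    act <- C != 0 & lam > 0
    if (!any(act)) return(out)
    l <- lam[act]
    acc <- 1 - exp(-l * tau[act])
    out[act] <- R0[act] * C[act] / l * (1 - exp(-l * dur[act])) *
      exp(-l * t_after[act]) / acc
    out
  }
  zero <- numeric(length(R0))
  cmax <- term(disp$lam1, disp$C1, zero) + term(disp$lam2, disp$C2, zero)
  cmin <- term(disp$lam1, disp$C1, tau - dur) + term(disp$lam2, disp$C2, tau - dur)
  list(cmax = cmax, cmin = cmin)
}

#' Steady-state peak and trough under a repeated regimen
#'
#' Computes the steady-state concentration at the end of the infusion
#' (`Cmax_ss`) and at the end of the dosing interval (`Cmin_ss`) for a
#' weight-based regimen, using the closed-form infinite-superposition
#' (geometric accumulation) solution. For a regimen with finite `n_doses` the
#' metrics are evaluated after the last dose by explicit superposition.
#'
#' @param params A [structural_params] object.
#' @param reg A [regimen].
#' @param weight Body weight, kg (> 0); converts `dose_per_kg` to mg.
#' @return Named list with `cmax` and `cmin`, mg/L.
#' @export
steady_state_metrics <- function(params, reg, weight) {
  stopifnot(inherits(params, "structural_params"), inherits(reg, "regimen"))
  if (!is.finite(weight) || weight <= 0) stop_validation("weight must be > 0")
  amt <- reg$dose_per_kg * weight
  d <- .disposition(params$CL, params$Vc, params$Vp %||% NA_real_,
                    params$Q %||% NA_real_, params$n_compartments == 2L)
  if (is.null(reg$n_doses)) {
    ## infinite superposition requires every active exponential to decay
    if ((d$C2 != 0 && d$lam2 <= 0) || d$lam1 <= 0) {
      stop_domain("non-accumulating (zero terminal rate constant): ",
                  "steady state undefined for this parameter set")
    }
    m <- .ss_metrics(d, amt, reg$infusion_duration, reg$interval)
    return(list(cmax = m$cmax, cmin = m$cmin))
  }
  starts <- (seq_len(reg$n_doses) - 1) * reg$interval
  ev <- dose_events(starts, amt, reg$infusion_duration)
  t_last <- starts[reg$n_doses]
  conc <- predict_concentrations(params, ev,
                                 c(t_last + reg$infusion_duration,
                                   t_last + reg$interval))
  list(cmax = conc[1], cmin = conc[2])
}
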