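## Marginal likelihood by Laplace approximation.
##
## Per subject i with random effects eta (log-scale, diagonal Omega), the
## joint negative log density of (observations, eta) is
##   g_i(eta) = 1/2 sum_j [ r_ij^2 / v_ij + log(2 pi v_ij) ]
##            + 1/2 sum_p [ eta_p^2 / omega_p^2 + log(2 pi omega_p^2) ]
## with residuals r = DV - f(eta) and variance v from the residual model.
## The marginal contribution is the Laplace approximation around the mode
## eta~ (the empirical Bayes estimate):
##   -2 log L_i = 2 g_i(eta~) - d log(2 pi) + log det H_i,
## H_i the Hessian of g_i at the mode. Mode finding is a damped Newton
## iteration run simultaneously (vectorized) over all subjects, with
## finite-difference gradients/Hessians of g.

## ---------------------------------------------------------------------------
## panel: preprocessed dataset for fast repeated prediction

prepare_panel <- function(data) {
  validate_dataset(data)
  ids <- unique(data$ID)
  ns <- length(ids)
  sidx <- match(data$ID, ids)
  obs_rows <- which(data$EVID == 0)
  dose_rows <- which(data$EVID == 1)
  n_obs <- length(obs_rows)
  obs_subj <- sidx[obs_rows]
  obs_time <- data$TIME[obs_rows]
  ## (observation, dose) pairs within subject
  po <- integer(0); ps <- integer(0); pte <- numeric(0)
  pr0 <- numeric(0); pdur <- numeric(0)
  for (i in seq_len(ns)) {
    oi <- which(obs_subj == i)
    di <- dose_rows[sidx[dose_rows] == i]
    if (!length(oi) || !length(di)) next
    no <- length(oi); nd <- length(di)
    po <- c(po, rep(oi, times = nd))
    ps <- c(ps, rep.int(i, no * nd))
    pte <- c(pte, rep(obs_time[oi], times = nd) - rep(data$TIME[di], each = no))
    pr0 <- c(pr0, rep(data$AMT[di] / data$DUR[di], each = no))
    pdur <- c(pdur, rep(data$DUR[di], each = no))
  }
  first <- match(ids, data$ID)
  cov <- list(WT = data$WT[first], AGE = data$AGE[first],
              SEX = data$SEX[first], SCR = data$SCR[first])
  list(ids = ids, ns = ns, n_obs = n_obs,
       obs_subj = obs_subj, obs_time = obs_time,
       dv = data$DV[obs_rows], obs_class = data$OBSCLASS[obs_rows],
       pair_obs = po, pair_subj = ps, pair_te = pte,
       pair_R0 = pr0, pair_dur = pdur, cov = cov,
       fingerprint = c(ns = ns, n_obs = n_obs,
                       dv = sum(data$DV[obs_rows]), t = sum(obs_time)))
}

## predictions at all observation rows for per-subject structural parameters
panel_predict <- function(panel, CL, Vc, Vp = NULL, Q = NULL) {
  two <- !is.null(Vp)
  d <- .disposition(CL, Vc, Vp %||% NA_real_, Q %||% NA_real_, two)
  s <- panel$pair_subj
  contrib <- .inf_term(d$lam1[s], d$C1[s], panel$pair_R0, panel$pair_dur, panel$pair_te)
  if (two) {
    contrib <- contrib +
      .inf_term(d$lam2[s], d$C2[s], panel$pair_R0, panel$pair_dur, panel$pair_te)
  }
  .colsum_groups(contrib, panel$pair_obs, panel$n_obs)
}

## per-subject joint negative log density g at an eta matrix (ns x d).
## typ: list(CL, Vc[, Vp, Q]) vectors of covariate-adjusted typical values,
## om: named positive variances for the BSV parameters (columns of eta).
subject_g <- function(panel, typ, om, sigma_add, sigma_prop, etas) {
  mult <- function(p) {
    if (!is.null(etas) && p %in% colnames(etas)) exp(etas[, p]) else 1
  }
  pred <- panel_predict(panel,
                        CL = typ$CL * mult("CL"), Vc = typ$Vc * mult("Vc"),
                        Vp = if (is.null(typ$Vp)) NULL else typ$Vp * mult("Vp"),
                        Q = if (is.null(typ$Q)) NULL else typ$Q * mult("Q"))
  v <- sigma_add^2 + (sigma_prop * pred)^2
  ## candidate points where a prediction underflows (proportional-only error)
  ## or overflows get a large finite objective so the mode search backs off
  bad <- !is.finite(pred) | v <= 0
  if (any(bad)) {
    v[bad] <- 1
    pred[bad] <- 0
  }
  r <- panel$dv - pred
  gcontrib <- 0.5 * (r * r / v + log(2 * pi * v))
  gcontrib[bad] <- 1e10
  gobs <- .colsum_groups(gcontrib, panel$obs_subj, panel$ns)
  if (is.null(etas) || !length(om)) return(gobs)
  prior <- sweep(etas * etas, 2, 2 * om, `/`) +
    matrix(0.5 * log(2 * pi * om), nrow = nrow(etas), ncol = length(om), byrow = TRUE)
  gobs + rowSums(prior)
}

## per-subject least-squares misfit of log-concentrations with a weak prior:
## a well-conditioned surrogate used only to seed the mode search
loglsq_g <- function(panel, typ, om, etas) {
  mult <- function(p) {
    if (p %in% colnames(etas)) exp(etas[, p]) else 1
  }
  pred <- panel_predict(panel,
                        CL = typ$CL * mult("CL"), Vc = typ$Vc * mult("Vc"),
                        Vp = if (is.null(typ$Vp)) NULL else typ$Vp * mult("Vp"),
                        Q = if (is.null(typ$Q)) NULL else typ$Q * mult("Q"))
  r <- log(panel$dv + 1e-6) - log(pmax(pred, 0) + 1e-6)
  bad <- !is.finite(r)
  r[bad] <- 0
  contrib <- 0.5 * r * r / 0.01
  contrib[bad] <- 1e10
  .colsum_groups(contrib, panel$obs_subj, panel$ns) +
    0.005 * rowSums(sweep(etas * etas, 2, om, `/`))
}

## Vectorized damped Newton search for the per-subject mode of g, d in {1, 2}.
## Returns the modes, per-subject g and the FD Hessians at the modes.
find_modes <- function(gfun, etas, max_iter = 100L, grad_tol = 1e-8, h = 1e-4) {
  ns <- nrow(etas); d <- ncol(etas)
  shift <- function(k, delta) {
    e <- etas; e[, k] <- e[, k] + delta; e
  }
  H11 <- H22 <- H12 <- NULL
  lam <- rep(1e-4, ns)  # per-subject Levenberg damping
  for (iter in seq_len(max_iter)) {
    g0 <- gfun(etas)
    gp1 <- gfun(shift(1, h)); gm1 <- gfun(shift(1, -h))
    grad1 <- (gp1 - gm1) / (2 * h)
    H11 <- (gp1 - 2 * g0 + gm1) / h^2
    if (d == 2L) {
      gp2 <- gfun(shift(2, h)); gm2 <- gfun(shift(2, -h))
      grad2 <- (gp2 - gm2) / (2 * h)
      H22 <- (gp2 - 2 * g0 + gm2) / h^2
      epp <- etas; epp[, 1] <- epp[, 1] + h; epp[, 2] <- epp[, 2] + h
      emm <- etas; emm[, 1] <- emm[, 1] - h; emm[, 2] <- emm[, 2] - h
      epm <- etas; epm[, 1] <- epm[, 1] + h; epm[, 2] <- epm[, 2] - h
      emp <- etas; emp[, 1] <- emp[, 1] - h; emp[, 2] <- emp[, 2] + h
      H12 <- (gfun(epp) - gfun(epm) - gfun(emp) + gfun(emm)) / (4 * h^2)
    } else {
      grad2 <- H22 <- H12 <- numeric(ns)
    }
    gmax <- if (d == 2L) pmax(abs(grad1), abs(grad2)) else abs(grad1)
    if (max(gmax) < grad_tol) break
    ## damped Newton direction: shift each 2x2 Hessian to be safely positive
    ## definite (minimum eigenvalue at least the subject's damping lambda)
    if (d == 2L) {
      min_eig <- (H11 + H22) / 2 - sqrt(pmax((H11 - H22)^2 / 4 + H12^2, 0))
      ridge <- pmax(lam - min_eig, 0)
      a <- H11 + ridge; b <- H22 + ridge
      det_h <- a * b - H12 * H12
      d1 <- -(b * grad1 - H12 * grad2) / det_h
      d2 <- -(a * grad2 - H12 * grad1) / det_h
    } else {
      a <- pmax(H11, lam)
      d1 <- -grad1 / a
      d2 <- numeric(ns)
    }
    cand <- etas
    cand[, 1] <- pmin(pmax(etas[, 1] + d1, -20), 20)
    if (d == 2L) cand[, 2] <- pmin(pmax(etas[, 2] + d2, -20), 20)
    gn <- gfun(cand)
    ok <- is.finite(gn) & gn <= g0 + 1e-12
    ## classic Levenberg update: successful subjects relax the damping,
    ## failed subjects increase it (their next step bends toward steepest
    ## descent and shrinks) and keep their current iterate
    lam[ok] <- pmax(lam[ok] * 0.25, 1e-10)
    lam[!ok] <- pmin(lam[!ok] * 10, 1e10)
    if (any(ok)) etas[ok, ] <- cand[ok, , drop = FALSE]
  }
  list(etas = etas, g = gfun(etas), H11 = H11, H22 = H22, H12 = H12, d = d,
       iterations = iter)
}

## typical (covariate-adjusted, eta = 0) parameter vectors for a panel
panel_typicals <- function(model, panel) {
  cf <- covariate_factors(model, panel$cov)
  th <- model$theta
  typ <- list(CL = th[["CL"]] * cf[, "CL"], Vc = th[["Vc"]] * cf[, "Vc"])
  if (model$structure == "two_compartment") {
    typ$Vp <- th[["Vp"]] * cf[, "Vp"]
    typ$Q <- th[["Q"]] * cf[, "Q"]
  }
  typ
}

## core evaluation given prepared pieces; returns -2LL, modes, per-subject.
## The g evaluations and the mode search run in compiled code
## (src/laplace.cpp); R/likelihood.R keeps the reference implementation of g
## (subject_g) against which the compiled kernel is tested.
laplace_neg2ll <- function(panel, typ, om, sigma_add, sigma_prop,
                           etas_init = NULL) {
  if (!length(om)) {
    g <- subject_g(panel, typ, om, sigma_add, sigma_prop, NULL)
    return(list(neg2ll = 2 * sum(g), by_subject = 2 * g, etas = NULL))
  }
  d <- length(om)
  ns <- panel$ns
  two_cpt <- !is.null(typ$Vp)
  zero <- numeric(ns)
  tVp <- typ$Vp %||% zero
  tQ <- typ$Q %||% zero
  om_u <- unname(om)
  bsv_idx <- match(names(om), c("CL", "Vc", "Vp", "Q")) - 1L
  gfun <- function(e) {
    cpp_subject_g(panel, typ$CL, typ$Vc, tVp, tQ, two_cpt, om_u, bsv_idx,
                  sigma_add, sigma_prop, e)
  }
  modes_from <- function(start) {
    cpp_find_modes(panel, typ$CL, typ$Vc, tVp, tQ, two_cpt, om_u, bsv_idx,
                   sigma_add, sigma_prop, start, 100L, 1e-8, 1e-4)
  }
  warm <- !is.null(etas_init) && identical(dim(etas_init), c(ns, d))
  ## The inner posterior can be multimodal for sparse (2-observation)
  ## subjects. Cold evaluations therefore scan a coarse eta grid (scaled by
  ## omega) and start the Newton search from each subject's best grid point;
  ## warm evaluations track the supplied modes for continuity.
  mode_n2ll <- function(mode) {
    det_h <- if (d == 2L) mode$H11 * mode$H22 - mode$H12^2 else mode$H11
    out <- 2 * mode$g - d * log(2 * pi) + log(det_h)
    ## a non-positive-definite Hessian is an invalid contribution, not an
    ## infinitely good one
    bad <- !is.finite(out) | det_h <= 1e-12 | mode$H11 <= 0
    out[bad] <- 1e10
    out
  }
  if (warm) {
    mode <- modes_from(etas_init)
    by_subject <- mode_n2ll(mode)
    etas <- mode$etas
    colnames(etas) <- names(om)
    return(list(neg2ll = sum(by_subject), by_subject = by_subject,
                etas = etas))
  }
  ## Cold evaluation: candidate starts are a coarse omega-scaled eta grid
  ## plus the per-subject least-squares inversion of the observations on the
  ## log scale (whose basin is far wider than that of the sharp likelihood
  ## it seeds). The mode search runs from the best start and the best
  ## well-separated runner-up, and the two Laplace masses are summed: sparse
  ## (two-observation) posteriors are not rarely bimodal, and a single-mode
  ## Laplace misses up to log(2) of mass per subject.
  res <- cpp_laplace_cold(panel, typ$CL, typ$Vc, tVp, tQ, two_cpt, om_u,
                          bsv_idx, sigma_add, sigma_prop, 100L, 1e-8, 1e-4)
  etas <- res$etas
  colnames(etas) <- names(om)
  list(neg2ll = sum(res$by_subject), by_subject = res$by_subject, etas = etas)
}

#' Marginal -2 log-likelihood of a population model
#'
#' Evaluates the marginal likelihood of an event-record dataset under a
#' [population_model] by the Laplace approximation: per subject, the mode of
#' the joint density of (observations, random effects) is found by a damped
#' Newton search and the Gaussian integral is approximated around it. With
#' all BSV variances zero the result collapses exactly to the Gaussian
#' residual -2 log-density at the typical predictions.
#'
#' @param model A [population_model].
#' @param data An event-record dataset (see [read_dataset]).
#' @param etas_init Optional warm-start matrix of per-subject random effects.
#' @return List with `neg2ll`, per-subject contributions `by_subject`
#'   (summing to `neg2ll`), and `etas`, the empirical Bayes modes (or `NULL`
#'   when the model carries no BSV).
#' @export
marginal_neg2ll <- function(model, data, etas_init = NULL) {
  stopifnot(inherits(model, "population_model"))
  if (model$residual$sigma_add <= 0 && model$residual$sigma_prop <= 0) {
    stop_domain("degenerate likelihood: all residual sigmas are zero")
  }
  panel <- if (is.list(data) && !is.null(data$pair_obs)) data else prepare_panel(data)
  typ <- panel_typicals(model, panel)
  om <- model$omega2[model$omega2 > 0]
  res <- laplace_neg2ll(panel, typ, om,
                        model$residual$sigma_add, model$residual$sigma_prop,
                        etas_init)
  res$ids <- panel$ids
  res
}
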