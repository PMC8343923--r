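## Model evaluation: nonparametric bootstrap of the parameter estimates and
## visual predictive checks (VPC). The sparse peak/trough design has exactly
## two nominal sampling classes, so VPC stratifies by observation class
## rather than by time bins.

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement to the original subject count, refits
#' the model (warm-started from the reference estimates), and summarizes each
#' estimated parameter by its median and 2.5th/97.5th percentile across
#' successful replicates. Failed or non-converged replicates are dropped and
#' counted; more than 50% failures is treated as a model/data pathology and
#' raises an error.
#'
#' @param fit A converged `pk_fit` carrying its dataset.
#' @param n_replicates Number of bootstrap replicates (the reference analysis
#'   used 1000).
#' @param seed Integer seed.
#' @param control [fit_control] for the replicate fits.
#' @return A `pk_bootstrap` object: `table` (parameter, median, ci_low,
#'   ci_high), `estimates` matrix of replicate estimates, `n_requested`,
#'   `n_failed`, `seed`.
#' @export
pk_bootstrap <- function(fit, n_replicates = 1000L, seed = 1L,
                         control = fit_control(se = FALSE)) {
  stopifnot(inherits(fit, "pk_fit"))
  if (is.null(fit$data)) stop_validation("fit does not carry its dataset")
  data <- fit$data
  ids <- unique(data$ID)
  ns <- length(ids)
  draws <- with_seed(seed, {
    matrix(sample.int(ns, ns * n_replicates, replace = TRUE), nrow = n_replicates)
  })
  par_names <- fit$estimates$parameter
  est <- matrix(NA_real_, nrow = n_replicates, ncol = length(par_names),
                dimnames = list(NULL, par_names))
  n_failed <- 0L
  rows_by_id <- split(seq_len(nrow(data)), data$ID)
  for (b in seq_len(n_replicates)) {
    take <- draws[b, ]
    pieces <- lapply(seq_along(take), function(k) {
      d <- data[rows_by_id[[ids[take[k]]]], , drop = FALSE]
      d$ID <- sprintf("B%04d", k)
      d
    })
    bd <- do.call(rbind, pieces)
    class(bd) <- c("event_record", "data.frame")
    ft <- tryCatch(
      fit_model(fit$template, bd, fixed = fit$fixed,
                init = stats::setNames(fit$estimates$estimate, par_names),
                control = control),
      error = function(e) NULL)
    if (is.null(ft) || !ft$convergence) {
      n_failed <- n_failed + 1L
      next
    }
    est[b, ] <- ft$estimates$estimate
  }
  if (n_failed > n_replicates / 2) {
    stop_domain("bootstrap failure rate above 50% (", n_failed, "/", n_replicates,
                "): model/data pathology")
  }
  ok <- stats::complete.cases(est)
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(
    table = data.frame(parameter = par_names, median = qs[2, ],
                       ci_low = qs[1, ], ci_high = qs[3, ],
                       stringsAsFactors = FALSE),
    estimates = est[ok, , drop = FALSE],
    n_requested = n_replicates, n_failed = n_failed, seed = seed),
    class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged (seed %s)\n",
              nrow(x$estimates), x$n_requested, format(x$seed)))
  tab <- x$table
  tab$median <- signif(tab$median, 5)
  tab$ci_low <- signif(tab$ci_low, 5)
  tab$ci_high <- signif(tab$ci_high, 5)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write the bootstrap summary table as CSV
#'
#' Columns: `parameter`, `median`, `ci_low`, `ci_high`.
#'
#' @param boot A `pk_bootstrap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_table <- function(boot, path) {
  tab <- boot$table
  for (col in c("median", "ci_low", "ci_high")) tab[[col]] <- fmt_num(tab[[col]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## simulate one replicate of the observed design under a model: same
## subjects, covariates, doses and sampling times; fresh BSV and residual
## draws. Returns simulated DVs aligned with the panel's observation rows.
simulate_panel_dv <- function(model, panel) {
  etas <- sample_etas(model, panel$ns)
  typ <- panel_typicals(model, panel)
  mult <- function(p) if (p %in% colnames(etas)) exp(etas[, p]) else 1
  pred <- panel_predict(panel,
                        CL = typ$CL * mult("CL"), Vc = typ$Vc * mult("Vc"),
                        Vp = if (is.null(typ$Vp)) NULL else typ$Vp * mult("Vp"),
                        Q = if (is.null(typ$Q)) NULL else typ$Q * mult("Q"))
  n <- length(pred)
  dv <- pred * (1 + model$residual$sigma_prop * stats::rnorm(n)) +
    model$residual$sigma_add * stats::rnorm(n)
  pmax(dv, 0)
}

#' Visual predictive check
#'
#' Simulates `n_replicates` datasets under the fitted model on the exact
#' observed design (same subjects, covariates, dose histories and sampling
#' times, with between-subject variability and residual error), computes the
#' 5th/50th/95th percentile of the simulated observations per observation
#' class (peak/trough) in every replicate, and summarizes each simulated
#' quantile by its median and a 95% confidence band across replicates,
#' alongside the observed quantiles.
#'
#' @param fit A `pk_fit` (or a [population_model]) to simulate from.
#' @param data Event-record dataset; defaults to the fit's own data.
#' @param n_replicates Number of simulated replicates (reference: 1000).
#' @param seed Integer seed.
#' @return A `pk_vpc` object with a plot-ready `table`: columns `class`,
#'   `source` (`observed`/`simulated`), `quantile`, `value`, `ci_low`,
#'   `ci_high` (CI columns NA for observed rows).
#' @export
vpc <- function(fit, data = NULL, n_replicates = 1000L, seed = 1L) {
  model <- if (inherits(fit, "pk_fit")) fit$model else fit
  stopifnot(inherits(model, "population_model"))
  if (is.null(data)) {
    if (!inherits(fit, "pk_fit") || is.null(fit$data)) {
      stop_validation("no dataset supplied and the fit carries none")
    }
    data <- fit$data
  }
  panel <- prepare_panel(data)
  probs <- c(0.05, 0.5, 0.95)
  classes <- sort(unique(panel$obs_class))
  sim_q <- with_seed(seed, {
    out <- array(NA_real_, dim = c(n_replicates, length(classes), 3))
    for (r in seq_len(n_replicates)) {
      dv <- simulate_panel_dv(model, panel)
      for (k in seq_along(classes)) {
        out[r, k, ] <- stats::quantile(dv[panel$obs_class == classes[k]],
                                       probs, names = FALSE)
      }
    }
    out
  })
  rows <- list()
  for (k in seq_along(classes)) {
    obs_q <- stats::quantile(panel$dv[panel$obs_class == classes[k]],
                             probs, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      class = classes[k], source = "observed", quantile = probs,
      value = obs_q, ci_low = NA_real_, ci_high = NA_real_)
    med <- apply(sim_q[, k, , drop = FALSE], 3, stats::median)
    lo <- apply(sim_q[, k, , drop = FALSE], 3, stats::quantile, probs = 0.025,
                names = FALSE)
    hi <- apply(sim_q[, k, , drop = FALSE], 3, stats::quantile, probs = 0.975,
                names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      class = classes[k], source = "simulated", quantile = probs,
      value = med, ci_low = lo, ci_high = hi)
  }
  structure(list(table = do.call(rbind, rows), n_replicates = n_replicates,
                 seed = seed, replicate_quantiles = sim_q, classes = classes),
            class = "pk_vpc")
}

#' Write the VPC table as CSV
#'
#' Columns: `class`, `source`, `quantile`, `value`, `ci_low`, `ci_high`.
#'
#' @param v A `pk_vpc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vpc_table <- function(v, path) {
  tab <- v$table
  for (col in c("quantile", "value", "ci_low", "ci_high")) {
    tab[[col]] <- fmt_num(tab[[col]])
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
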