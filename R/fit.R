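#' Fit the abundance state-space model to one species
#'
#' The package's main entry point: runs the MCMC sampler (see [run_mcmc()])
#' for one species of a survey dataset and bundles draws, diagnostics and
#' data into a fitted-model object with the usual methods (`print`,
#' `summary`, `coef`, `plot`, `simulate`, `residuals`).
#'
#' @param data a [survey_dataset()].
#' @param species species label or index within `data` (default first).
#' @param priors a [ssm_priors()] object.
#' @param control an [ssm_control()] object; use
#'   `ssm_control(schedule = "desk")` for a reduced run.
#' @param fix passed to [run_mcmc()].
#' @return An object of class `ssm_fit` with elements `draws`
#'   (`posterior_draws`), `diagnostics` ([ssm_diagnostics()]), `data`,
#'   `species`, and `call`.
#' @examples
#' sim <- simulate_counts(sim_params(n_sites = 2, n_months = 6,
#'                                   species_list = "sp", seed = 7))
#' fit <- ssm_fit(sim$data, control = ssm_control(
#'   n_chains = 2, n_iterations = 2000, n_burnin = 1000,
#'   n_adapt = 500, thin = 5, schedule = "desk"))
#' summary(fit)
#' @export
ssm_fit <- function(data, species = 1L, priors = ssm_priors(),
                    control = ssm_control(), fix = list()) {
  draws <- run_mcmc(data, species, priors, control, fix)
  structure(list(draws = draws,
                 diagnostics = ssm_diagnostics(draws),
                 data = data, species = draws$species,
                 priors = priors, control = control,
                 call = match.call()),
            class = "ssm_fit")
}

#' Fit every analyzable species of a dataset
#'
#' Fits species independently with a shared schedule (so their draws stay
#' aligned for [cross_species_totals()]). Species observed fewer than
#' `min_observations` times in total are skipped, mirroring the practice
#' of not analyzing species seen only a handful of times.
#'
#' @inheritParams ssm_fit
#' @param min_observations minimum total count for a species to be fitted
#'   (default 3).
#' @return A named list of `ssm_fit` objects.
#' @export
ssm_fit_all <- function(data, priors = ssm_priors(),
                        control = ssm_control(), min_observations = 3L) {
  tot <- apply(data$counts, 3, sum, na.rm = TRUE)
  keep <- names(tot)[tot >= min_observations]
  if (!length(keep)) stop("no species reaches min_observations")
  fits <- lapply(keep, function(sp)
    ssm_fit(data, sp, priors = priors, control = control))
  stats::setNames(fits, keep)
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat("Effort-adjusted count state-space model fit\n")
  cat("  species:", x$species, " |  data:", x$draws$n_sites, "sites x",
      x$draws$n_months, "months\n")
  d <- x$diagnostics
  rh <- d$rhat[!is.na(d$rhat)]
  cat(sprintf("  chains: %d x %d retained draws  |  max Rhat %.3f (%s)\n",
              length(x$draws$chains), nrow(x$draws$chains[[1]]),
              max(rh), if (d$converged) "converged" else "NOT converged"))
  cat(sprintf("  P(error ratio > %g) = %.3f\n", d$ratio_threshold,
              d$p_error_ratio_gt_threshold))
  print(coef(x))
  invisible(x)
}

#' @export
coef.ssm_fit <- function(object, ...) {
  vapply(c("mu_r", "B", "sigma_proc", "sigma_obs"), function(p)
    stats::median(param_draws(object$draws, p)), numeric(1))
}

#' @export
summary.ssm_fit <- function(object, ...) {
  pars <- c("mu_r", "B", "sigma_proc", "sigma_obs")
  tab <- t(vapply(pars, function(p)
    .pctl(param_draws(object$draws, p)), numeric(3)))
  colnames(tab) <- c("pct_2_5", "median", "pct_97_5")
  out <- list(species = object$species, parameters = tab,
              abundance = species_relative_abundance(object),
              effort = effort_coefficient_summary(object),
              diagnostics = object$diagnostics)
  class(out) <- "summary.ssm_fit"
  out
}

#' @export
print.summary.ssm_fit <- function(x, ...) {
  cat("Species:", x$species, "\n\nPosterior parameter percentiles:\n")
  print(round(x$parameters, 4))
  cat("\nRelative abundance (pooled over sites, months, draws):\n")
  print(x$abundance)
  cat("\nEffort coefficient:\n")
  print(x$effort)
  cat("\n")
  print(x$diagnostics)
  invisible(x)
}

#' Trace plots of the model-level parameters
#'
#' @param x an `ssm_fit` object.
#' @param params parameters to plot.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ssm_fit <- function(x, params = c("mu_r", "B", "sigma_proc",
                                       "sigma_obs"), ...) {
  params <- intersect(params, x$draws$param_names)
  old <- graphics::par(mfrow = c(length(params), 1),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in params) {
    ch <- param_draws(x$draws, p, pooled = FALSE)
    graphics::matplot(do.call(cbind, ch), type = "l", lty = 1,
                      ylab = p, xlab = "", main = "", ...)
  }
  invisible(x)
}

#' Posterior-predictive count simulation from a fitted model
#'
#' For `nsim` retained draws (sampled without replacement), regenerates
#' counts through the observation model with fresh Poisson noise, holding
#' the drawn latent states, effort coefficient and observation noise.
#'
#' @param object an `ssm_fit` object.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` count matrices (`T x S`), `NA` where the data
#'   are missing.
#' @export
simulate.ssm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draws <- object$draws
  m <- .species_matrices(object$data, object$species)
  x <- m$x; x[is.na(x)] <- 0
  all <- do.call(rbind, draws$chains)
  N <- latent_draws(draws)
  idx <- sample.int(nrow(all), nsim, replace = nsim > nrow(all))
  lapply(idx, function(i) {
    Tm <- draws$n_months; S <- draws$n_sites
    eta <- matrix(all[i, grep("^eta\\[", draws$param_names)], Tm, S)
    lam <- N[i, , ] * exp(all[i, "B"] * x + eta)
    yy <- matrix(stats::rpois(Tm * S, lam), Tm, S)
    yy[is.na(m$y)] <- NA_integer_
    yy
  })
}

#' Pearson residuals of a fitted model
#'
#' `(y - lambda_hat) / sqrt(lambda_hat)` with `lambda_hat` the posterior
#' median of the Poisson mean per cell.
#'
#' @param object an `ssm_fit` object.
#' @param ... unused.
#' @return A `T x S` matrix, `NA` where the data are missing.
#' @export
residuals.ssm_fit <- function(object, ...) {
  draws <- object$draws
  m <- .species_matrices(object$data, object$species)
  x <- m$x; x[is.na(x)] <- 0
  lam <- .abundance_values(draws, expected_counts = TRUE,
                           data = object$data)
  lam_hat <- apply(lam, c(2, 3), stats::median)
  (m$y - lam_hat) / sqrt(lam_hat)
}
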