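#' State-space model parameters
#'
#' One species' full parameter set for the abundance state-space model.
#' Latent log-abundance follows a random walk with drift per site:
#' `log N[t+1, s] = log N[t, s] + r[t, s]`, with monthly growth deviations
#' `r[t, s] ~ Normal(mu_r, sigma_proc^2)`. Counts are observed through a
#' Poisson model whose log-mean adds the standardized effort covariate and
#' an observation-level noise term:
#' `log lambda[t, s] = log N[t, s] + B * x[t, s] + eta[t, s]`,
#' `eta[t, s] ~ Normal(0, sigma_obs^2)`.
#'
#' @param logN1 numeric vector of initial log-abundances, one per site.
#' @param r `(T-1) x S` matrix of monthly log-growth deviations.
#' @param mu_r mean monthly log-growth (drift), shared across sites.
#' @param sigma_proc process SD (> 0): SD of the growth deviations.
#' @param sigma_obs observation SD (> 0): SD of the log-scale count noise.
#' @param B effort coefficient, shared across sites and months.
#' @param eta `T x S` matrix of observation-level log-scale noise.
#' @return An object of class `ssm_params`.
#' @export
ssm_params <- function(logN1, r, mu_r, sigma_proc, sigma_obs, B, eta) {
  S <- length(logN1)
  r <- as.matrix(r); eta <- as.matrix(eta)
  Tm <- nrow(eta)
  if (ncol(eta) != S || ncol(r) != S || nrow(r) != Tm - 1L)
    stop("inconsistent parameter dimensions: need r (T-1) x S and eta T x S")
  stopifnot(length(mu_r) == 1L, length(B) == 1L,
            length(sigma_proc) == 1L, length(sigma_obs) == 1L)
  if (sigma_proc <= 0 || sigma_obs <= 0)
    stop("sigma_proc and sigma_obs must be > 0")
  structure(list(logN1 = as.numeric(logN1), r = r, mu_r = mu_r,
                 sigma_proc = sigma_proc, sigma_obs = sigma_obs,
                 B = B, eta = eta, n_months = Tm, n_sites = S),
            class = "ssm_params")
}

#' Latent abundance trajectory implied by the parameters
#'
#' @param params an [ssm_params()] object.
#' @return `T x S` matrix of strictly positive latent abundances `N[t, s]`,
#'   with `N[1, s] = exp(logN1[s])` and
#'   `N[t+1, s] = exp(log N[t, s] + r[t, s])`.
#' @export
latent_states <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  logN <- rbind(params$logN1,
                matrix(params$r, params$n_months - 1L, params$n_sites))
  matrix(exp(apply(logN, 2, cumsum)), params$n_months, params$n_sites)
}

# T x S count matrix (and effort) for one species of a survey_dataset
.species_matrices <- function(data, species) {
  stopifnot(inherits(data, "survey_dataset"))
  k <- if (is.character(species)) match(species, data$species) else
    as.integer(species)
  if (is.na(k) || k < 1L || k > length(data$species))
    stop("unknown species: ", species)
  yk <- data$counts[, , k, drop = FALSE]
  dim(yk) <- dim(data$effort_raw)
  list(y = t(yk), x = t(data$effort_std), label = data$species[k])
}

#' Observation-model log-likelihood
#'
#' Sum over surveyed site-months of the Poisson log-pmf of the observed
#' count given `log lambda = log N + B x + eta`. Missing cells contribute
#' nothing.
#'
#' @param params an [ssm_params()] object.
#' @param data a [survey_dataset()].
#' @param species species label or index within `data` (default first).
#' @return The log-likelihood, a single finite number for finite params.
#' @export
ssm_log_likelihood <- function(params, data, species = 1L) {
  m <- .species_matrices(data, species)
  if (!all(dim(m$y) == c(params$n_months, params$n_sites)))
    stop("parameter dimensions (", params$n_months, " x ", params$n_sites,
         ") do not match data (", nrow(m$y), " x ", ncol(m$y), ")")
  logN <- log(latent_states(params))
  loglam <- logN + params$B * m$x + params$eta
  ok <- !is.na(m$y)
  if (!any(ok)) return(0)
  sum(stats::dpois(m$y[ok], exp(loglam[ok]), log = TRUE))
}

#' Prior specification
#'
#' Vague priors for all parameters: normal priors for the drift `mu_r`,
#' effort coefficient `B` and initial log-abundances, and uniform priors
#' for the two SDs. Defaults are conventional weakly-informative choices —
#' `Normal(0, 10^2)` and `Uniform(0, 10)` — diffuse enough that the
#' posterior is dominated by the likelihood.
#'
#' @param mu_r_prior,B_prior,logN1_prior length-2 numeric `c(location, scale)`.
#' @param sigma_proc_prior,sigma_obs_prior length-2 numeric
#'   `c(lower, upper)` bounds of the uniform prior on each SD.
#' @return An object of class `prior_spec`.
#' @export
ssm_priors <- function(mu_r_prior = c(0, 10), B_prior = c(0, 10),
                       logN1_prior = c(0, 10),
                       sigma_proc_prior = c(0, 10),
                       sigma_obs_prior = c(0, 10)) {
  for (p in list(mu_r_prior, B_prior, logN1_prior))
    if (length(p) != 2L || p[2] <= 0) stop("normal priors need scale > 0")
  for (p in list(sigma_proc_prior, sigma_obs_prior))
    if (length(p) != 2L || p[1] >= p[2] || p[1] < 0)
      stop("uniform SD priors need 0 <= lower < upper")
  structure(list(mu_r_prior = mu_r_prior, B_prior = B_prior,
                 logN1_prior = logN1_prior,
                 sigma_proc_prior = sigma_proc_prior,
                 sigma_obs_prior = sigma_obs_prior),
            class = "prior_spec")
}

#' Read or write a prior specification as YAML
#' @param priors a [ssm_priors()] object.
#' @param path file path.
#' @return `priors_to_yaml` returns `path` invisibly; `priors_from_yaml`
#'   returns a `prior_spec`.
#' @export
priors_to_yaml <- function(priors, path) {
  stopifnot(inherits(priors, "prior_spec"))
  yaml::write_yaml(unclass(priors), path)
  invisible(path)
}

#' @rdname priors_to_yaml
#' @export
priors_from_yaml <- function(path) {
  do.call(ssm_priors, yaml::read_yaml(path))
}

#' Joint log-prior density
#'
#' @inheritParams ssm_log_likelihood
#' @param priors a [ssm_priors()] object.
#' @return Sum of the log prior densities of every parameter block,
#'   including the hierarchical terms `r ~ Normal(mu_r, sigma_proc^2)` and
#'   `eta ~ Normal(0, sigma_obs^2)`; `-Inf` when an SD falls outside its
#'   uniform support.
#' @export
ssm_log_prior <- function(params, priors = ssm_priors()) {
  stopifnot(inherits(params, "ssm_params"), inherits(priors, "prior_spec"))
  sp <- priors$sigma_proc_prior; so <- priors$sigma_obs_prior
  if (params$sigma_proc <= sp[1] || params$sigma_proc >= sp[2] ||
      params$sigma_obs <= so[1] || params$sigma_obs >= so[2])
    return(-Inf)
  sum(stats::dnorm(params$mu_r, priors$mu_r_prior[1], priors$mu_r_prior[2],
                   log = TRUE),
      stats::dnorm(params$B, priors$B_prior[1], priors$B_prior[2],
                   log = TRUE),
      stats::dnorm(params$logN1, priors$logN1_prior[1],
                   priors$logN1_prior[2], log = TRUE),
      stats::dnorm(params$r, params$mu_r, params$sigma_proc, log = TRUE),
      stats::dnorm(params$eta, 0, params$sigma_obs, log = TRUE),
      stats::dunif(params$sigma_proc, sp[1], sp[2], log = TRUE),
      stats::dunif(params$sigma_obs, so[1], so[2], log = TRUE))
}

#' Unnormalized log-posterior
#'
#' @inheritParams ssm_log_prior
#' @inheritParams ssm_log_likelihood
#' @return `ssm_log_likelihood(params, data, species) +
#'   ssm_log_prior(params, priors)`.
#' @export
ssm_log_posterior <- function(params, data, priors = ssm_priors(),
                              species = 1L) {
  lp <- ssm_log_prior(params, priors)
  if (!is.finite(lp)) return(lp)
  lp + ssm_log_likelihood(params, data, species)
}
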