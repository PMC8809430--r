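#' MCMC configuration
#'
#' The default schedule is the full survey-scale run: 3 chains of 300,000
#' iterations with 150,000 burn-in, 20,000 adaptation and thinning of 1 in
#' 50, retaining 3,000 draws per chain. `schedule = "desk"` selects a
#' reduced schedule (3 x 20,000 iterations, 10,000 burn-in, 5,000
#' adaptation, thin 10) that gives 1,000 retained draws per chain and is
#' adequate for simulation studies and tests.
#'
#' @param n_chains number of independent chains.
#' @param n_iterations iterations per chain.
#' @param n_burnin discarded initial iterations (`< n_iterations`).
#' @param n_adapt iterations during which proposal scales adapt; frozen
#'   afterwards so the retained chain is a valid Markov chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; the whole run is reproducible from it.
#' @param schedule `"full"` (the defaults above) or `"desk"`; explicit
#'   arguments override the preset.
#' @return An object of class `mcmc_config`.
#' @export
ssm_control <- function(n_chains = 3L, n_iterations = NULL, n_burnin = NULL,
                        n_adapt = NULL, thin = NULL, seed = 1L,
                        schedule = c("full", "desk")) {
  schedule <- match.arg(schedule)
  preset <- if (schedule == "full")
    list(n_iterations = 300000L, n_burnin = 150000L, n_adapt = 20000L,
         thin = 50L)
  else
    list(n_iterations = 20000L, n_burnin = 10000L, n_adapt = 5000L,
         thin = 10L)
  n_iterations <- as.integer(n_iterations %||% preset$n_iterations)
  n_burnin <- as.integer(n_burnin %||% preset$n_burnin)
  n_adapt <- as.integer(n_adapt %||% preset$n_adapt)
  thin <- as.integer(thin %||% preset$thin)
  if (n_burnin >= n_iterations) stop("n_burnin must be < n_iterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (n_adapt < 0L || n_burnin < 0L) stop("negative schedule component")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = n_iterations, n_burnin = n_burnin,
                 n_adapt = n_adapt, thin = thin, seed = as.integer(seed),
                 schedule = schedule),
            class = "mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retained draws per chain implied by a schedule
#' @param config an [ssm_control()] object.
#' @return `floor((n_iterations - n_burnin) / thin)`.
#' @export
n_retained <- function(config) {
  stopifnot(inherits(config, "mcmc_config"))
  (config$n_iterations - config$n_burnin) %/% config$thin
}

.param_names <- function(Tm, S) {
  c(sprintf("logN1[%d]", seq_len(S)),
    as.vector(vapply(seq_len(S), function(s)
      sprintf("r[%d,%d]", seq_len(Tm - 1L), s), character(Tm - 1L))),
    as.vector(vapply(seq_len(S), function(s)
      sprintf("eta[%d,%d]", seq_len(Tm), s), character(Tm))),
    "mu_r", "B", "sigma_proc", "sigma_obs")
}

#' Sample the posterior of the state-space model by MCMC
#'
#' Runs an adaptive random-walk Metropolis-within-Gibbs sampler over scalar
#' parameter blocks (initial log-abundances, growth deviations, observation
#' noise, effort coefficient, the two SDs), with an exact conjugate Gibbs
#' draw for the drift `mu_r`. Proposal scales adapt toward moderate
#' acceptance only during the first `n_adapt` iterations. Chains run
#' sequentially from a deterministically derived seed, so a run is
#' byte-identical given `config$seed`.
#'
#' @param data a [survey_dataset()] with at least 2 months.
#' @param species species label or index within `data`.
#' @param priors a [ssm_priors()] object.
#' @param config an [ssm_control()] object.
#' @param fix optional named list holding parameter blocks fixed at given
#'   values during sampling (names among `logN1`, `r`, `eta`, `mu_r`, `B`,
#'   `sigma_proc`, `sigma_obs`); e.g. `fix = list(B = 0)` drops the effort
#'   term. Fixed blocks are recorded at their fixed value in every draw.
#' @return An object of class `posterior_draws`: a list with `chains` (one
#'   draws-by-parameters matrix per chain, columns named `logN1[s]`,
#'   `r[t,s]`, `eta[t,s]`, `mu_r`, `B`, `sigma_proc`, `sigma_obs`),
#'   `acceptance` rates per block and chain, and the run metadata.
#' @export
run_mcmc <- function(data, species = 1L, priors = ssm_priors(),
                     config = ssm_control(), fix = list()) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  m <- .species_matrices(data, species)
  y <- m$y; x <- m$x
  Tm <- nrow(y); S <- ncol(y)
  if (Tm < 2L) stop("need at least 2 months of data")
  if (!any(!is.na(y))) stop("degenerate data: all counts missing")
  if (isTRUE(attr(data, "degenerate_effort")) && is.null(fix$B))
    fix$B <- 0  # constant effort carries no information about B

  bad <- setdiff(names(fix), c("logN1", "r", "eta", "mu_r", "B",
                               "sigma_proc", "sigma_obs"))
  if (length(bad)) stop("unknown fix block(s): ", paste(bad, collapse = ", "))

  ybar <- pmax(apply(y, 2, function(v) mean(v, na.rm = TRUE)), 0.5)
  ybar[is.nan(ybar)] <- 0.5
  init <- list(logN1 = log(ybar),
               r = matrix(0, Tm - 1L, S), eta = matrix(0, Tm, S),
               mu_r = 0, B = 0, sigma_proc = 0.3, sigma_obs = 0.3)
  for (nm in names(fix)) {
    v <- fix[[nm]]
    init[[nm]] <- if (nm %in% c("r", "eta"))
      matrix(v, nrow(init[[nm]]), S) else v
  }
  fixed <- lapply(stats::setNames(nm = names(init)),
                  function(nm) nm %in% names(fix))

  nk <- n_retained(config)
  pn <- .param_names(Tm, S)
  chains <- vector("list", config$n_chains)
  acceptance <- vector("list", config$n_chains)
  set.seed(derive_seed(config$seed, "chain"))
  for (ch in seq_len(config$n_chains)) {
    # overdispersed starts, identical under one seed
    init_ch <- init
    if (!fixed$mu_r) init_ch$mu_r <- stats::rnorm(1, 0, 0.05)
    if (!fixed$B) init_ch$B <- stats::rnorm(1, 0, 0.1)
    # SD starts must lie inside the uniform prior support
    sp_b <- priors$sigma_proc_prior; so_b <- priors$sigma_obs_prior
    if (!fixed$sigma_proc)
      init_ch$sigma_proc <- sp_b[1] +
        stats::runif(1, 0.01, 0.06) * (sp_b[2] - sp_b[1])
    if (!fixed$sigma_obs)
      init_ch$sigma_obs <- so_b[1] +
        stats::runif(1, 0.01, 0.06) * (so_b[2] - so_b[1])
    if (!fixed$logN1)
      init_ch$logN1 <- init$logN1 + stats::rnorm(S, 0, 0.2)
    res <- .sample_ssm_chain(y, x, init_ch, unclass(priors), fixed,
                             config$n_iterations, config$n_burnin,
                             config$n_adapt, config$thin)
    dr <- res$draws
    colnames(dr) <- pn
    chains[[ch]] <- dr
    acceptance[[ch]] <- res$acceptance
  }
  structure(list(chains = chains, param_names = pn,
                 n_months = Tm, n_sites = S,
                 sites = data$sites, months = data$months,
                 species = m$label, acceptance = acceptance,
                 config = config, priors = priors, fix = fix),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws for species '", x$species, "': ",
      length(x$chains), " chains x ", nrow(x$chains[[1]]),
      " retained draws x ", length(x$param_names), " parameters\n", sep = "")
  cat("  schedule:", x$config$n_iterations, "iterations,",
      x$config$n_burnin, "burn-in, thin", x$config$thin, "\n")
  invisible(x)
}

#' Extract a parameter's draws from all chains
#' @param draws a `posterior_draws` object.
#' @param param a column name, e.g. `"mu_r"` or `"r[2,1]"`.
#' @param pooled if `TRUE` return one vector over all chains, else a list.
#' @return Numeric vector or list of per-chain vectors.
#' @export
param_draws <- function(draws, param, pooled = TRUE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!param %in% draws$param_names) stop("unknown parameter: ", param)
  per <- lapply(draws$chains, function(m) m[, param])
  if (pooled) unlist(per, use.names = FALSE) else per
}

#' Latent abundance draws
#'
#' Reconstructs `N[t, s] = exp(logN1[s] + cumsum r[., s])` for every
#' retained draw.
#'
#' @param draws a `posterior_draws` object.
#' @return An array `n_draws_total x T x S` of latent abundances, draws
#'   pooled over chains in chain order.
#' @export
latent_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  Tm <- draws$n_months; S <- draws$n_sites
  all <- do.call(rbind, draws$chains)
  nd <- nrow(all)
  out <- array(NA_real_, c(nd, Tm, S))
  for (s in seq_len(S)) {
    logN1 <- all[, sprintf("logN1[%d]", s)]
    if (Tm > 1L) {
      rcols <- all[, sprintf("r[%d,%d]", seq_len(Tm - 1L), s), drop = FALSE]
      cum <- t(apply(rcols, 1, cumsum))
      if (Tm == 2L) cum <- matrix(cum, nd, 1L)
      out[, , s] <- exp(cbind(logN1, logN1 + cum))
    } else {
      out[, 1L, s] <- exp(logN1)
    }
  }
  dimnames(out) <- list(NULL, draws$months, draws$sites)
  out
}
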