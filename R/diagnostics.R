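#' Gelman-Rubin potential scale reduction factor
#'
#' The classical (unsplit) form: with `m` chains of length `n`, within-chain
#' variance `W` = mean of the chain sample variances and between-chain
#' variance `B = n * var(chain means)`,
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)`.
#' Values near 1 (conventionally below 1.1) indicate the chains have mixed.
#'
#' @param chains a list of (at least 2) equal-length numeric vectors, the
#'   retained draws of one scalar parameter per chain, or a
#'   `posterior_draws` object together with `param`.
#' @param param parameter name when `chains` is a `posterior_draws` object.
#' @param split if `TRUE`, each chain is split in half first (the modern
#'   variant, more sensitive to within-chain trends).
#' @return The scalar `Rhat`.
#' @export
gelman_rubin <- function(chains, param = NULL, split = FALSE) {
  if (inherits(chains, "posterior_draws")) {
    if (is.null(param)) stop("supply a parameter name")
    chains <- param_draws(chains, param, pooled = FALSE)
  }
  stopifnot(is.list(chains), length(chains) >= 2L)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths")
  if (n < 2L) stop("chains must have length >= 2")
  if (split) {
    h <- n %/% 2L
    chains <- c(lapply(chains, function(v) v[seq_len(h)]),
                lapply(chains, function(v) v[(n - h + 1L):n]))
    n <- h
    if (n < 2L) stop("chains too short to split")
  }
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) stop("undefined Gelman-Rubin statistic: ",
                   "zero within-chain variance")
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rhat for every stored parameter
#' @param draws a `posterior_draws` object.
#' @return Named numeric vector of Rhat values; parameters whose draws are
#'   constant in every chain (e.g. fixed blocks) are `NA`.
#' @export
rhat_all <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  vapply(draws$param_names, function(p) {
    ch <- param_draws(draws, p, pooled = FALSE)
    if (mean(vapply(ch, stats::var, numeric(1))) == 0) return(NA_real_)
    gelman_rubin(ch)
  }, numeric(1))
}

#' Posterior probability that the error ratio exceeds a threshold
#'
#' The error ratio is the observation-error SD divided by the process-error
#' SD, `sigma_obs / sigma_proc`, computed per retained draw and pooled over
#' chains. A model-adequacy convention for count state-space models asks
#' for the posterior probability that this ratio exceeds 10.
#'
#' @param draws a `posterior_draws` object.
#' @param threshold positive ratio threshold (default 10).
#' @return A list with `ratios` (one per pooled draw) and `probability`,
#'   the exact fraction of draws whose ratio exceeds `threshold`.
#' @export
error_ratio_probability <- function(draws, threshold = 10) {
  ratios <- param_draws(draws, "sigma_obs") /
    param_draws(draws, "sigma_proc")
  list(ratios = ratios, probability = mean(ratios > threshold))
}

#' Convergence and adequacy diagnostics for a fitted model
#'
#' @param draws a `posterior_draws` object.
#' @param rhat_limit convergence rule: all Rhat below this (default 1.1).
#' @param ratio_threshold,ratio_prob adequacy rule: the posterior
#'   probability that `sigma_obs / sigma_proc` exceeds `ratio_threshold`
#'   must exceed `ratio_prob` (defaults 10 and 0.90).
#' @return An object of class `ssm_diagnostics`: `rhat` (named vector),
#'   `converged`, `error_ratio_draws`, `p_error_ratio_gt_threshold`,
#'   `adequate`, and per-chain `acceptance` rates.
#' @export
ssm_diagnostics <- function(draws, rhat_limit = 1.1, ratio_threshold = 10,
                            ratio_prob = 0.90) {
  rh <- rhat_all(draws)
  er <- error_ratio_probability(draws, ratio_threshold)
  structure(list(rhat = rh,
                 converged = all(rh[!is.na(rh)] < rhat_limit),
                 rhat_limit = rhat_limit,
                 error_ratio_draws = er$ratios,
                 ratio_threshold = ratio_threshold,
                 p_error_ratio_gt_threshold = er$probability,
                 adequate = er$probability > ratio_prob,
                 acceptance = draws$acceptance),
            class = "ssm_diagnostics")
}

#' @export
print.ssm_diagnostics <- function(x, ...) {
  rh <- x$rhat[!is.na(x$rhat)]
  cat("MCMC diagnostics\n")
  cat(sprintf("  max Rhat: %.4f over %d parameters -> %s (rule: < %.2f)\n",
              max(rh), length(rh),
              if (x$converged) "converged" else "NOT converged",
              x$rhat_limit))
  cat(sprintf("  P(error ratio > %g) = %.3f -> %s\n", x$ratio_threshold,
              x$p_error_ratio_gt_threshold,
              if (x$adequate) "adequate" else "not adequate"))
  invisible(x)
}

#' Export MCMC traces to CSV
#'
#' Writes a long-format trace table (`parameter, chain, iteration, value`)
#' for visual convergence assessment; values round-trip to at least 6
#' significant digits.
#'
#' @param draws a `posterior_draws` object.
#' @param path output CSV path.
#' @param params parameters to export (default: the four model-level
#'   parameters `mu_r`, `B`, `sigma_proc`, `sigma_obs`).
#' @return `path`, invisibly.
#' @export
export_traces <- function(draws, path,
                          params = c("mu_r", "B", "sigma_proc",
                                     "sigma_obs")) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!nrow(draws$chains[[1]])) stop("no retained draws to export")
  params <- intersect(params, draws$param_names)
  if (!length(params)) stop("no matching parameters")
  nk <- nrow(draws$chains[[1]])
  tab <- do.call(rbind, lapply(params, function(p) {
    do.call(rbind, lapply(seq_along(draws$chains), function(ch)
      data.frame(parameter = p, chain = ch, iteration = seq_len(nk),
                 value = signif(draws$chains[[ch]][, p], 12))))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
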