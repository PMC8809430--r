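# Percentile convention throughout: linear interpolation between order
# statistics (stats::quantile type 7, R's default).
.pctl <- function(v, p = c(0.025, 0.5, 0.975)) {
  stats::quantile(v, p, names = FALSE, type = 7)
}

.summary_row <- function(species, site, n_obs, values) {
  q <- .pctl(values)
  data.frame(species = species, site = site,
             n_observations = as.integer(n_obs),
             pct_2_5 = q[1], median = q[2], pct_97_5 = q[3],
             stringsAsFactors = FALSE)
}

.as_abundance_summary <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("abundance_summary", "data.frame")
  out
}

.resolve_draws <- function(object) {
  if (inherits(object, "ssm_fit")) {
    list(draws = object$draws, data = object$data)
  } else if (inherits(object, "posterior_draws")) {
    list(draws = object, data = NULL)
  } else stop("need an ssm_fit or posterior_draws object")
}

.n_obs_species <- function(data, species, site = NULL) {
  if (is.null(data)) return(NA_integer_)
  k <- match(species, data$species)
  if (is.na(k)) return(NA_integer_)
  m <- data$counts[, , k, drop = FALSE]
  if (!is.null(site)) m <- m[match(site, data$sites), , , drop = FALSE]
  as.integer(sum(m, na.rm = TRUE))
}

#' Survey-wide relative abundance of one species
#'
#' Pools the latent abundance `N[t, s]` over all sites, months, chains and
#' retained draws and reports the 2.5th, 50th and 97.5th percentiles — the
#' posterior distribution of the species' relative abundance during an
#' individual survey.
#'
#' @param object an `ssm_fit` or `posterior_draws` object.
#' @param expected_counts if `TRUE`, pool expected counts
#'   `N * exp(B x + eta)` instead of latent abundance.
#' @return A one-row `abundance_summary` data frame (site `"ALL"`).
#' @export
species_relative_abundance <- function(object, expected_counts = FALSE) {
  rd <- .resolve_draws(object)
  v <- .abundance_values(rd$draws, expected_counts, rd$data)
  .as_abundance_summary(list(.summary_row(
    rd$draws$species, "ALL",
    .n_obs_species(rd$data, rd$draws$species), as.vector(v))))
}

.abundance_values <- function(draws, expected_counts = FALSE, data = NULL) {
  N <- latent_draws(draws)  # n_draws x T x S
  if (!expected_counts) return(N)
  all <- do.call(rbind, draws$chains)
  Tm <- draws$n_months; S <- draws$n_sites
  B <- all[, "B"]
  x <- if (!is.null(data)) t(data$effort_std) else matrix(0, Tm, S)
  x[is.na(x)] <- 0
  for (s in seq_len(S)) {
    eta <- all[, sprintf("eta[%d,%d]", seq_len(Tm), s), drop = FALSE]
    N[, , s] <- N[, , s] *
      exp(eta + outer(B, x[, s]))  # lambda = N exp(B x + eta)
  }
  N
}

#' Per-site relative abundance of one species
#'
#' @inheritParams species_relative_abundance
#' @param sites site labels to report (default all).
#' @return An `abundance_summary` with one row per site, percentiles pooled
#'   within each site over months, chains and draws.
#' @export
site_relative_abundance <- function(object, sites = NULL,
                                    expected_counts = FALSE) {
  rd <- .resolve_draws(object)
  draws <- rd$draws
  sites <- sites %||% draws$sites
  bad <- setdiff(sites, draws$sites)
  if (length(bad)) stop("unknown site label(s): ", paste(bad, collapse = ", "))
  N <- .abundance_values(draws, expected_counts, rd$data)
  .as_abundance_summary(lapply(sites, function(st) {
    s <- match(st, draws$sites)
    .summary_row(draws$species, st,
                 .n_obs_species(rd$data, draws$species, st),
                 as.vector(N[, , s]))
  }))
}

#' Cross-species total relative abundance per site
#'
#' For every retained draw and site-month, sums the latent abundances over
#' species, then summarizes the totals: summation precedes summarization,
#' so the reported percentiles describe the posterior of the total, not a
#' sum of per-species percentiles. Species fitted separately are paired
#' draw-by-draw in chain order; when retained counts differ, draws are
#' truncated to the shortest.
#'
#' @param fits a named list of `ssm_fit` or `posterior_draws` objects, one
#'   per species, sharing the same sites and months.
#' @return An `abundance_summary` with one row per site (species `"ALL"`)
#'   plus a final row pooling all sites.
#' @export
cross_species_totals <- function(fits) {
  stopifnot(length(fits) >= 1L)
  rds <- lapply(fits, .resolve_draws)
  draws <- lapply(rds, `[[`, "draws")
  ref <- draws[[1]]
  for (d in draws)
    if (d$n_months != ref$n_months || !identical(d$sites, ref$sites))
      stop("species fits have misaligned site/month dimensions")
  nd <- min(vapply(draws, function(d)
    nrow(d$chains[[1]]) * length(d$chains), numeric(1)))
  tot <- NULL
  n_obs_site <- rep(0L, length(ref$sites))
  have_data <- TRUE
  for (i in seq_along(draws)) {
    N <- latent_draws(draws[[i]])[seq_len(nd), , , drop = FALSE]
    tot <- if (is.null(tot)) N else tot + N
    no <- vapply(ref$sites, function(st)
      .n_obs_species(rds[[i]]$data, draws[[i]]$species, st), integer(1))
    if (anyNA(no)) have_data <- FALSE else n_obs_site <- n_obs_site + no
  }
  if (!have_data) n_obs_site <- rep(NA_integer_, length(ref$sites))
  rows <- lapply(seq_along(ref$sites), function(s)
    .summary_row("ALL", ref$sites[s], n_obs_site[s], as.vector(tot[, , s])))
  rows <- c(rows, list(.summary_row("ALL", "ALL", sum(n_obs_site),
                                    as.vector(tot))))
  .as_abundance_summary(rows)
}

#' Posterior summary of the effort coefficient
#'
#' @param object an `ssm_fit` or `posterior_draws` object.
#' @return A one-row data frame: species, 2.5th/50th/97.5th percentiles of
#'   `B`, the exact draw fractions `p_gt_0` and `p_lt_0`, and
#'   `positive_lower_bound` (`TRUE` iff the 2.5th percentile exceeds 0 —
#'   i.e. clear evidence that longer surveys yield higher counts).
#' @export
effort_coefficient_summary <- function(object) {
  rd <- .resolve_draws(object)
  b <- param_draws(rd$draws, "B")
  q <- .pctl(b)
  data.frame(species = rd$draws$species,
             pct_2_5 = q[1], median = q[2], pct_97_5 = q[3],
             p_gt_0 = mean(b > 0), p_lt_0 = mean(b < 0),
             positive_lower_bound = q[1] > 0,
             stringsAsFactors = FALSE)
}
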