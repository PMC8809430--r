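# Shared fixtures, built in code at test time.

# A minimal raw-records table in the canonical CSV dialect.
make_records <- function() {
  data.frame(
    site_id = rep(c("A", "A", "B"), each = 4),
    station_id = rep(c("s1", "s2", "s1"), each = 4),
    survey_date = rep(c("2016-09-10", "2016-09-10", "2016-09-12"), each = 4),
    interval_index = rep(1:2, 6),
    species = rep(rep(c("WRV", "EV"), each = 2), 3),
    count = c(4, 7, 1, 0,  3, 2, 5, 2,  0, 1, 2, 2),
    effort_minutes = rep(c(180, 180, 210), each = 4),
    stringsAsFactors = FALSE)
}

write_records_csv <- function(rec = make_records()) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rec, f, row.names = FALSE)
  f
}

# Assemble a posterior_draws object directly from per-chain parameter
# matrices (columns must follow countssm:::.param_names(Tm, S)).
make_draws <- function(chains, Tm, S, species = "spX",
                       sites = sprintf("site_%02d", seq_len(S))) {
  pn <- countssm:::.param_names(Tm, S)
  chains <- lapply(chains, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == length(pn))
    colnames(m) <- pn
    m
  })
  structure(list(chains = chains, param_names = pn, n_months = Tm,
                 n_sites = S, sites = sites, months = seq_len(Tm),
                 species = species, acceptance = NULL,
                 config = ssm_control(n_iterations = 100, n_burnin = 0,
                                      n_adapt = 0, thin = 1),
                 priors = ssm_priors(), fix = list()),
            class = "posterior_draws")
}

# Draws object whose latent abundance pools to exactly `values` (one site,
# one month): logN1 = log(values), everything else inert.
draws_from_values <- function(values, n_chains = 1) {
  Tm <- 1L; S <- 1L
  per <- split(values, rep(seq_len(n_chains), length.out = length(values)))
  chains <- lapply(per, function(v)
    cbind(log(v), 0, 0, 0, 0.5, 0.5))
  # columns: logN1[1], eta[1,1], mu_r, B, sigma_proc, sigma_obs
  make_draws(chains, Tm, S)
}

# One small cached model fit shared by method tests.
small_fit_cache <- new.env(parent = emptyenv())
get_small_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    sim <- simulate_counts(sim_params(n_sites = 3, n_months = 8,
                                      species_list = "sp", seed = 11))
    small_fit_cache$sim <- sim
    small_fit_cache$fit <- ssm_fit(
      sim$data, control = ssm_control(n_chains = 2, n_iterations = 4000,
                                      n_burnin = 2000, n_adapt = 1000,
                                      thin = 4, seed = 3,
                                      schedule = "desk"))
  }
  small_fit_cache
}

# Independent linear-interpolation percentile (sort-and-index oracle).
percentile_oracle <- function(v, p) {
  v <- sort(v); n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Independent two-tailed Fisher p through stats::dhyper enumeration.
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact permutation p-value for the two-group Kruskal-Wallis statistic.
kw_perm_oracle <- function(g1, g2) {
  v <- c(g1, g2); n1 <- length(g1); n <- length(v)
  h_of <- function(idx) {
    kruskal_wallis(list(v[idx], v[-idx]))$statistic
  }
  h_obs <- kruskal_wallis(list(g1, g2))$statistic
  combos <- utils::combn(n, n1)
  hs <- apply(combos, 2, h_of)
  mean(hs >= h_obs - 1e-12)
}
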