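small_data <- function(seed = 13, S = 2, Tm = 6) {
  simulate_counts(sim_params(n_sites = S, n_months = Tm,
                             species_list = "sp", seed = seed))$data
}

tiny_control <- function(seed = 1, n_chains = 2)
  ssm_control(n_chains = n_chains, n_iterations = 600, n_burnin = 200,
              n_adapt = 200, thin = 4, seed = seed, schedule = "desk")

test_that("retained-draw count follows the burn-in/thinning law", {
  # the survey-scale schedule retains 3000 draws per chain
  expect_equal(n_retained(ssm_control()), 3000L)
  expect_equal(n_retained(ssm_control(schedule = "desk")), 1000L)
  set.seed(1)
  d <- small_data()
  for (i in 1:4) {
    it <- sample(200:800, 1); bu <- sample(0:150, 1)
    th <- sample(1:7, 1)
    ctl <- ssm_control(n_chains = 1, n_iterations = it, n_burnin = bu,
                       n_adapt = 100, thin = th, seed = i)
    dr <- run_mcmc(d, config = ctl)
    expect_equal(nrow(dr$chains[[1]]), (it - bu) %/% th)
    expect_equal(nrow(dr$chains[[1]]), n_retained(ctl))
  }
})

test_that("sampling is reproducible and schedule validation fires", {
  d <- small_data()
  ctl <- tiny_control(seed = 42)
  expect_identical(run_mcmc(d, config = ctl), run_mcmc(d, config = ctl))
  expect_false(identical(run_mcmc(d, config = ctl),
                         run_mcmc(d, config = tiny_control(seed = 43))))
  expect_error(ssm_control(n_iterations = 100, n_burnin = 100), "burnin")
  expect_error(ssm_control(thin = 0), "thin")
})

test_that("degenerate data and unknown fix blocks are rejected", {
  d <- survey_dataset("A", 1:3, "sp", array(NA_real_, c(1, 3, 1)),
                      matrix(NA_real_, 1, 3))
  expect_error(run_mcmc(d, config = tiny_control()), "all counts missing")
  expect_error(run_mcmc(small_data(), config = tiny_control(),
                        fix = list(bogus = 1)), "unknown fix block")
})

test_that("every retained draw satisfies parameter validity", {
  dr <- run_mcmc(small_data(), config = tiny_control())
  for (ch in dr$chains) {
    expect_true(all(ch[, "sigma_proc"] > 0))
    expect_true(all(ch[, "sigma_obs"] > 0))
    expect_true(all(ch[, "sigma_proc"] < 10))
  }
  expect_equal(nrow(dr$chains[[1]]), nrow(dr$chains[[2]]))
})

test_that("conditional mu_r draws match the conjugate closed form", {
  sim <- simulate_counts(sim_params(n_sites = 3, n_months = 6,
                                    species_list = "sp", seed = 4))
  tr <- sim$truth$params$sp
  ctl <- ssm_control(n_chains = 1, n_iterations = 2500, n_burnin = 500,
                     n_adapt = 0, thin = 1, seed = 9, schedule = "desk")
  dr <- run_mcmc(sim$data, config = ctl,
                 fix = list(logN1 = tr$logN1, r = tr$r, eta = tr$eta,
                            sigma_proc = 0.2, sigma_obs = 0.3))
  draws <- param_draws(dr, "mu_r")
  # with everything else fixed, mu_r ~ N(m*, v*) in closed form
  n <- length(tr$r); s0 <- 10; sp <- 0.2
  v <- 1 / (1 / s0^2 + n / sp^2)
  m <- v * sum(tr$r) / sp^2
  ks <- suppressWarnings(ks.test(draws, "pnorm", m, sqrt(v)))
  expect_gt(ks$p.value, 0.01)
  # fixed blocks are recorded at their fixed values
  expect_equal(unique(param_draws(dr, "sigma_proc")), 0.2)
})

test_that("fixing B drops the effort term, as for degenerate effort", {
  d <- small_data()
  dr <- run_mcmc(d, config = tiny_control(), fix = list(B = 0))
  expect_true(all(param_draws(dr, "B") == 0))
  # constant-effort data fixes B automatically
  sim <- simulate_counts(sim_params(n_sites = 2, n_months = 5,
                                    species_list = "sp",
                                    effort_hours = matrix(3, 2, 5),
                                    seed = 2))
  expect_true(isTRUE(attr(sim$data, "degenerate_effort")))
  dr2 <- run_mcmc(sim$data, config = tiny_control())
  expect_true(all(param_draws(dr2, "B") == 0))
})

test_that("Gelman-Rubin matches its defining formula", {
  # identical chains: zero between-chain variance forces sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               sqrt(3 / 4), tolerance = 1e-12)
  # hand-computed offset chains: W = 1/150, B = 200
  rh <- gelman_rubin(list(c(0, 0.1, -0.1, 0), c(10, 10.1, 9.9, 10)))
  expect_equal(rh, sqrt((0.75 * (1 / 150) + 50) / (1 / 150)),
               tolerance = 1e-12)
  expect_lt(abs(rh - 86.6), 0.1)
  # degenerate: zero within-chain variance
  expect_error(gelman_rubin(list(c(2, 2, 2), c(2, 2, 2))), "undefined")
  expect_error(gelman_rubin(list(1:3)), "length")
  # split variant detects a trend invisible to the classical form
  trend <- list(seq(0, 1, length.out = 40), seq(1, 0, length.out = 40))
  expect_gt(gelman_rubin(trend, split = TRUE), 1)
})

test_that("error-ratio probability is an exact draw fraction", {
  Tm <- 1L; S <- 1L
  m <- cbind(0, 0, 0, 0, c(0.4, 0.4, 0.4), c(5, 5, 2))
  dr <- make_draws(list(m), Tm, S)
  er <- error_ratio_probability(dr)
  expect_equal(er$ratios, c(12.5, 12.5, 5))
  expect_equal(er$probability, 2 / 3)
  expect_equal(error_ratio_probability(dr, threshold = 100)$probability, 0)
  expect_equal(error_ratio_probability(dr, threshold = 0)$probability, 1)
  # invariant to draw order
  perm <- make_draws(list(m[c(3, 1, 2), ]), Tm, S)
  expect_equal(sort(error_ratio_probability(perm)$ratios),
               sort(er$ratios))
  expect_equal(error_ratio_probability(perm)$probability, er$probability)
})

test_that("diagnostics bundle convergence and adequacy rules", {
  fit_env <- get_small_fit()
  d <- fit_env$fit$diagnostics
  expect_type(d$rhat, "double")
  expect_identical(d$converged, all(d$rhat[!is.na(d$rhat)] < 1.1))
  expect_equal(d$p_error_ratio_gt_threshold,
               mean(d$error_ratio_draws > 10))
  expect_identical(d$adequate, d$p_error_ratio_gt_threshold > 0.9)
})

test_that("posterior latent abundance tracks the data as the observation
           noise prior tightens", {
  # large counts keep Poisson noise small relative to the trend; B = 0
  # so the latent state is directly comparable to the observed count
  sim <- simulate_counts(sim_params(n_sites = 2, n_months = 8,
                                    species_list = "sp", B = 0,
                                    initial_logN = rep(log(100), 2),
                                    seed = 31))
  y <- t(sim$data$counts[, , 1])
  ctl <- ssm_control(n_chains = 2, n_iterations = 3000, n_burnin = 1500,
                     n_adapt = 1000, thin = 5, seed = 7,
                     schedule = "desk")
  err <- vapply(c(5, 0.2, 0.02), function(up) {
    pr <- ssm_priors(sigma_obs_prior = c(0, up))
    dr <- run_mcmc(sim$data, priors = pr, config = ctl,
                   fix = list(B = 0))
    Nhat <- apply(latent_draws(dr), c(2, 3), median)
    mean(abs(log(Nhat[y > 0]) - log(y[y > 0])))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("traces export to CSV and round-trip", {
  dr <- run_mcmc(small_data(), config = tiny_control())
  f <- tempfile(fileext = ".csv")
  export_traces(dr, f, params = c("mu_r", "B", "sigma_obs"))
  tr <- read.csv(f)
  expect_equal(nrow(tr), 3 * 2 * nrow(dr$chains[[1]]))
  got <- tr$value[tr$parameter == "mu_r" & tr$chain == 1]
  expect_equal(signif(got, 6), signif(unname(dr$chains[[1]][, "mu_r"]), 6))
  expect_error(export_traces(dr, f, params = "nope"), "no matching")
})
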