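make_params <- function(logN1, r, mu_r = 0, sigma_proc = 0.2,
                        sigma_obs = 0.3, B = 0, eta = NULL) {
  r <- as.matrix(r)
  if (is.null(eta)) eta <- matrix(0, nrow(r) + 1L, length(logN1))
  ssm_params(logN1, r, mu_r, sigma_proc, sigma_obs, B, eta)
}

one_cell_data <- function(y, effort = c(3, 4)) {
  # 2 months x 1 site; only month 1 carries the count of interest
  survey_dataset("A", 1:2, "sp", array(c(y, 0), c(1, 2, 1)),
                 matrix(effort, 1, 2))
}

test_that("latent states follow the random walk and stay positive", {
  # identity walk
  p <- make_params(0, matrix(0, 3, 1))
  expect_equal(unname(latent_states(p)), matrix(1, 4, 1))
  # deterministic doubling
  p2 <- make_params(log(10), matrix(log(2), 2, 1))
  expect_equal(as.vector(latent_states(p2)), c(10, 20, 40))
  # positivity and scale equivariance under arbitrary parameters
  set.seed(42)
  for (i in 1:20) {
    S <- sample(1:4, 1); Tm <- sample(2:8, 1)
    p3 <- make_params(rnorm(S, 0, 3), matrix(rnorm((Tm - 1) * S, 0, 1),
                                             Tm - 1, S))
    N <- latent_states(p3)
    expect_true(all(N > 0))
    c0 <- rnorm(1)
    p4 <- make_params(p3$logN1 + c0, p3$r)
    expect_equal(latent_states(p4), N * exp(c0), tolerance = 1e-12)
  }
})

test_that("log-likelihood equals the Poisson log-pmf cell by cell", {
  # lambda = 1, y = 0 -> -1
  d <- one_cell_data(0)
  p <- make_params(0, matrix(0, 1, 1))
  ll_both <- ssm_log_likelihood(p, d)
  expect_equal(ll_both, dpois(0, 1, log = TRUE) * 2)  # both cells lambda=1
  # y = 2, lambda = 1 -> -1 - log 2 for that cell
  d2 <- one_cell_data(2)
  expect_equal(ssm_log_likelihood(p, d2) - dpois(0, 1, log = TRUE),
               -1 - log(2), tolerance = 1e-12)
  # missing cells contribute nothing, all-missing data gives 0
  d3 <- survey_dataset("A", 1:2, "sp", array(c(NA, 4), c(1, 2, 1)),
                       matrix(c(NA, 3), 1, 2))
  p_eta <- make_params(0, matrix(0, 1, 1),
                       eta = matrix(c(99, 0), 2, 1))
  expect_equal(ssm_log_likelihood(p_eta, d3),
               dpois(4, 1, log = TRUE))  # missing cell's eta irrelevant
  d4 <- survey_dataset("A", 1:2, "sp", array(NA_real_, c(1, 2, 1)),
                       matrix(NA_real_, 1, 2))
  expect_identical(ssm_log_likelihood(p_eta, d4), 0)
})

test_that("likelihood reduces to the plain Poisson random-walk form", {
  # with eta = 0 and B = 0, agree with a direct product of Poisson pmfs
  set.seed(7)
  for (i in 1:25) {
    S <- sample(1:3, 1); Tm <- sample(2:6, 1)
    logN1 <- rnorm(S, 1, 0.5)
    r <- matrix(rnorm((Tm - 1) * S, 0, 0.3), Tm - 1, S)
    N <- vapply(seq_len(S), function(s)
      exp(cumsum(c(logN1[s], r[, s]))), numeric(Tm))
    y <- matrix(rpois(Tm * S, as.vector(N)), Tm, S)
    d <- survey_dataset(sprintf("s%d", 1:S), seq_len(Tm), "sp",
                        array(t(y), c(S, Tm, 1)),
                        matrix(runif(S * Tm, 2, 4), S, Tm))
    p <- make_params(logN1, r)
    oracle <- sum(log(dpois(as.vector(y), as.vector(N))))
    expect_equal(ssm_log_likelihood(p, d), oracle, tolerance = 1e-10)
  }
})

test_that("likelihood falls monotonically as log N moves away from y", {
  d <- one_cell_data(5)
  lls <- vapply(seq(log(5), log(5) + 3, length.out = 12), function(ln) {
    ssm_log_likelihood(make_params(ln, matrix(-ln, 1, 1)), d)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("log-prior sums its blocks and respects uniform support", {
  pr <- ssm_priors()
  p <- make_params(c(0, 0), matrix(0, 2, 2), sigma_proc = 11)  # outside U(0,10)
  expect_identical(ssm_log_prior(p, pr), -Inf)

  # at prior locations with unit scales each normal term is -log(2*pi)/2
  pr1 <- ssm_priors(mu_r_prior = c(0, 1), B_prior = c(0, 1),
                    logN1_prior = c(0, 1))
  S <- 2; Tm <- 3
  p1 <- ssm_params(rep(0, S), matrix(0, Tm - 1, S), mu_r = 0,
                   sigma_proc = 1, sigma_obs = 1, B = 0,
                   eta = matrix(0, Tm, S))
  n_normal <- 1 + 1 + S + (Tm - 1) * S + Tm * S
  expect_equal(ssm_log_prior(p1, pr1),
               n_normal * (-0.5 * log(2 * pi)) + 2 * log(1 / 10),
               tolerance = 1e-12)

  # additivity across independent blocks: doubling the sites doubles the
  # site-indexed contributions exactly
  p_a <- ssm_params(0, matrix(0, 1, 1), 0, 1, 1, 0, matrix(0, 2, 1))
  p_b <- ssm_params(c(0, 0), matrix(0, 1, 2), 0, 1, 1, 0, matrix(0, 2, 2))
  shared <- sum(dnorm(c(0, 0), 0, c(1, 1), log = TRUE)) + 2 * log(1 / 10)
  expect_equal(ssm_log_prior(p_b, pr1) - shared,
               2 * (ssm_log_prior(p_a, pr1) - shared), tolerance = 1e-12)
})

test_that("log-posterior composes likelihood and prior", {
  d <- one_cell_data(3)
  p <- make_params(log(3), matrix(0, 1, 1))
  pr <- ssm_priors()
  expect_equal(ssm_log_posterior(p, d, pr),
               ssm_log_likelihood(p, d) + ssm_log_prior(p, pr),
               tolerance = 1e-12)
  p_bad <- make_params(log(3), matrix(0, 1, 1), sigma_obs = 20)
  expect_identical(ssm_log_posterior(p_bad, d, pr), -Inf)
})

test_that("prior specifications serialize through YAML", {
  pr <- ssm_priors(mu_r_prior = c(0.1, 2), sigma_obs_prior = c(0, 5))
  f <- tempfile(fileext = ".yaml")
  priors_to_yaml(pr, f)
  expect_equal(priors_from_yaml(f), pr)
  expect_error(ssm_priors(sigma_proc_prior = c(5, 1)), "lower < upper")
})
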