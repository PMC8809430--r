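.default_species <- c("White-rumped Vulture", "Egyptian Vulture",
                      "Himalayan Vulture", "Red-headed Vulture",
                      "Slender-billed Vulture", "Cinereous Vulture",
                      "Griffon Vulture")

#' Simulation parameters for survey counts
#'
#' Describes a forward simulation of the exact generative model the
#' analysis assumes (see [ssm_params()]). Defaults mirror the study design
#' the package targets: 11 survey sites followed over 12 monthly surveys,
#' 7 analyzable vulture species, and session effort drawn uniformly on
#' 2-4 hours. Per-species dynamics default to a gently increasing
#' population (`mu_r = 0.02`) with process SD 0.2, observation SD 0.3 and
#' effort coefficient 0.3.
#'
#' @param n_sites,n_months positive integers.
#' @param species_list character vector of species labels.
#' @param mu_r,sigma_proc,sigma_obs,B per-species scalars, recycled across
#'   species when length 1.
#' @param initial_logN `NULL` (drawn per species and site from
#'   `Normal(log 8, 0.7^2)`, i.e. around 8 birds per site), a length-
#'   `n_sites` vector shared by all species, or an `n_sites x n_species`
#'   matrix.
#' @param effort_hours `NULL` (drawn `Uniform(2, 4)` per site-month) or an
#'   `n_sites x n_months` matrix of positive hours.
#' @param missing `S x T` logical matrix of site-months to mark as not
#'   surveyed, or `NULL` for complete coverage.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_sites = 11L, n_months = 12L,
                       species_list = .default_species,
                       mu_r = 0.02, sigma_proc = 0.2, sigma_obs = 0.3,
                       B = 0.3, initial_logN = NULL, effort_hours = NULL,
                       missing = NULL, seed = 1L) {
  stopifnot(n_sites >= 1L, n_months >= 1L, length(species_list) >= 1L)
  K <- length(species_list)
  rec <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, K)
    if (length(v) != K) stop(what, " must have length 1 or n_species")
    v
  }
  mu_r <- rec(mu_r, "mu_r"); B <- rec(B, "B")
  sigma_proc <- rec(sigma_proc, "sigma_proc")
  sigma_obs <- rec(sigma_obs, "sigma_obs")
  if (any(sigma_proc < 0) || any(sigma_obs < 0))
    stop("sigma_proc and sigma_obs must be >= 0")
  if (!is.null(effort_hours)) {
    effort_hours <- as.matrix(effort_hours)
    if (!all(dim(effort_hours) == c(n_sites, n_months)))
      stop("effort_hours must be n_sites x n_months")
    if (any(effort_hours <= 0)) stop("effort_hours must be positive")
  }
  if (!is.null(initial_logN)) {
    initial_logN <- if (is.matrix(initial_logN)) initial_logN else
      matrix(initial_logN, n_sites, K)
    if (!all(dim(initial_logN) == c(n_sites, K)))
      stop("initial_logN must be length n_sites or n_sites x n_species")
  }
  if (!is.null(missing)) {
    missing <- as.matrix(missing)
    if (!all(dim(missing) == c(n_sites, n_months)))
      stop("missing must be n_sites x n_months logical")
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_months = as.integer(n_months),
                 species_list = as.character(species_list),
                 mu_r = mu_r, sigma_proc = sigma_proc,
                 sigma_obs = sigma_obs, B = B,
                 initial_logN = initial_logN, effort_hours = effort_hours,
                 missing = missing, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a survey dataset from the state-space model
#'
#' Forward-simulates latent log-abundance random walks and Poisson counts
#' through the effort-adjusted observation model, per species. The ground
#' truth (latent states and generating parameters) is returned alongside
#' the observable dataset but never written into it, so parameter-recovery
#' tests cannot leak.
#'
#' @param params a [sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{data}{a [survey_dataset()] of observed counts and effort;}
#'     \item{truth}{a list with per-species [ssm_params()] objects
#'       (`params`), the `S x T x K` latent abundance array (`N`), and the
#'       generating `sim_params`.}
#'   }
#' @examples
#' sim <- simulate_counts(sim_params(n_sites = 3, n_months = 6,
#'                                   species_list = "sp1", seed = 42))
#' sim$data
#' @export
simulate_counts <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, "simulate"))
  S <- params$n_sites; Tm <- params$n_months
  K <- length(params$species_list)
  sites <- sprintf("site_%02d", seq_len(S))
  effort_raw <- if (is.null(params$effort_hours))
    matrix(stats::runif(S * Tm, 2, 4), S, Tm) else params$effort_hours
  x <- if (stats::sd(effort_raw) > 0)
    standardize_effort(effort_raw) else matrix(0, S, Tm)
  logN1 <- if (is.null(params$initial_logN))
    matrix(stats::rnorm(S * K, log(8), 0.7), S, K) else params$initial_logN

  counts <- array(NA_real_, c(S, Tm, K))
  N_true <- array(NA_real_, c(S, Tm, K))
  truth_params <- vector("list", K)
  for (k in seq_len(K)) {
    r <- matrix(stats::rnorm((Tm - 1L) * S, params$mu_r[k],
                             params$sigma_proc[k]), Tm - 1L, S)
    eta <- matrix(stats::rnorm(Tm * S, 0, params$sigma_obs[k]), Tm, S)
    logN <- apply(rbind(logN1[, k], r), 2, cumsum)
    logN <- matrix(logN, Tm, S)
    lam <- exp(logN + params$B[k] * t(x) + eta)
    counts[, , k] <- t(matrix(stats::rpois(Tm * S, lam), Tm, S))
    N_true[, , k] <- t(exp(logN))
    truth_params[[k]] <- ssm_params(
      logN1 = logN1[, k], r = r, mu_r = params$mu_r[k],
      sigma_proc = max(params$sigma_proc[k], 1e-12),
      sigma_obs = max(params$sigma_obs[k], 1e-12),
      B = params$B[k], eta = eta)
  }
  if (!is.null(params$missing)) {
    effort_raw[params$missing] <- NA_real_
    for (k in seq_len(K)) {
      ck <- counts[, , k]; ck[params$missing] <- NA_real_
      counts[, , k] <- ck
    }
  }
  names(truth_params) <- params$species_list
  dimnames(N_true) <- list(sites, seq_len(Tm), params$species_list)
  data <- survey_dataset(sites, seq_len(Tm), params$species_list,
                         counts, effort_raw)
  list(data = data,
       truth = list(params = truth_params, N = N_true,
                    sim_params = params))
}

#' Simulation parameters for questionnaire respondents
#'
#' Emulates the structure of a 300-household perception survey: one adult
#' (over 16 years old) per household, with education level, gender, age
#' and binary knowledge/perception responses. Ages are drawn from a
#' discretized log-normal per education group, truncated at 17 years, so
#' medians are configurable while keeping a demographically plausible
#' right tail. Binary response probabilities may differ by education
#' group. Default medians (31 formal, 44 nonformal) and response rates
#' reflect a population where formal education is more common among
#' younger respondents and men, nearly everyone has seen wild vultures,
#' nest sightings are rare, and diclofenac awareness is very low.
#'
#' @param n_respondents positive integer (default 300).
#' @param p_formal_by_gender named probabilities `c(male = , female = )`
#'   of formal education given gender.
#' @param p_male probability a respondent is male.
#' @param age_median named numeric `c(formal = , nonformal = )` target
#'   age medians in years.
#' @param age_sdlog named numeric log-scale SDs per education group.
#' @param response_probs named list: one entry per question key, each a
#'   numeric `c(formal = , nonformal = )` probability of a "yes".
#' @param seed integer seed.
#' @return An object of class `respondent_sim_params`.
#' @export
respondent_sim_params <- function(
    n_respondents = 300L,
    p_formal_by_gender = c(male = 0.78, female = 0.62),
    p_male = 0.5,
    age_median = c(formal = 31, nonformal = 44),
    age_sdlog = c(formal = 0.32, nonformal = 0.28),
    response_probs = list(
      identified_pictures = c(formal = 0.97, nonformal = 0.93),
      seen_vulture        = c(formal = 0.99, nonformal = 0.95),
      seen_nest           = c(formal = 0.086, nonformal = 0.033),
      vultures_useful     = c(formal = 0.98, nonformal = 0.98),
      aware_diclofenac    = c(formal = 0.04, nonformal = 0.01),
      believes_declining  = c(formal = 0.96, nonformal = 0.96)),
    seed = 1L) {
  probs <- c(p_formal_by_gender, p_male, unlist(response_probs))
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  stopifnot(n_respondents >= 1L, all(age_median > 17), all(age_sdlog > 0))
  structure(list(n_respondents = as.integer(n_respondents),
                 p_formal_by_gender = p_formal_by_gender, p_male = p_male,
                 age_median = age_median, age_sdlog = age_sdlog,
                 response_probs = response_probs, seed = as.integer(seed)),
            class = "respondent_sim_params")
}

#' Simulate a questionnaire respondent table
#'
#' @param params a [respondent_sim_params()] object.
#' @return A `data.frame` of class `respondent_table`: `respondent_id`,
#'   `age` (integer years, > 16), `gender` (`male`/`female`), `education`
#'   (`formal`/`nonformal`), and one binary `"yes"`/`"no"` column per
#'   question key.
#' @export
simulate_respondents <- function(params = respondent_sim_params()) {
  stopifnot(inherits(params, "respondent_sim_params"))
  set.seed(derive_seed(params$seed, "respondents"))
  n <- params$n_respondents
  gender <- ifelse(stats::runif(n) < params$p_male, "male", "female")
  p_edu <- params$p_formal_by_gender[gender]
  education <- ifelse(stats::runif(n) < p_edu, "formal", "nonformal")
  age <- integer(n)
  for (g in c("formal", "nonformal")) {
    idx <- which(education == g)
    if (!length(idx)) next
    draw <- function(m) round(stats::rlnorm(m, log(params$age_median[[g]]),
                                            params$age_sdlog[[g]]))
    a <- draw(length(idx))
    while (any(a < 17)) a[a < 17] <- draw(sum(a < 17))  # adults only
    age[idx] <- a
  }
  out <- data.frame(respondent_id = sprintf("r%04d", seq_len(n)),
                    age = as.integer(age), gender = gender,
                    education = education, stringsAsFactors = FALSE)
  for (q in names(params$response_probs)) {
    p <- params$response_probs[[q]][education]
    out[[q]] <- ifelse(stats::runif(n) < p, "yes", "no")
  }
  class(out) <- c("respondent_table", "data.frame")
  out
}
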