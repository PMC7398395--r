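# Shared builders for the test suite. Everything is generated in code;
# no fixture files.

# covariate-free hair model (the "base" model of the covariate analyses).
# sd_add stays fixed at its generating value: with no covariate spread in
# the predictions the additive/proportional decomposition is a likelihood
# ridge, so the calibration fits estimate an identifiable set.
base_model_atv <- function(frac_pop = 0.16, sd_add = 0.30, sd_prop = 0.50) {
  hair_model("ATV", dose_regimen(300, 24), plasma_defaults("ATV"),
             frac_pop = frac_pop, covariates = character(),
             sd_add = sd_add, sd_prop = sd_prop,
             estimated = c("frac_pop", "sd_prop"))
}

# base model plus an occasion effect
occasion_model_atv <- function(beta_occasion = -0.30) {
  hair_model("ATV", dose_regimen(300, 24), plasma_defaults("ATV"),
             frac_pop = 0.16, betas = c(beta_occasion = beta_occasion),
             covariates = "occasion", sd_add = 0.30, sd_prop = 0.50,
             estimated = c("frac_pop", "beta_occasion", "sd_prop"))
}

# cohort spec simulating ATV only from a given truth model
atv_cohort_spec <- function(n, seed, truth = base_model_atv()) {
  cohort_spec(n_subjects = n, seed = seed, analytes = "ATV",
              truth = list(ATV = truth))
}

# individual-link model with a single live eta (on CL) so the quadrature
# oracle (<= 2 dims) applies
one_eta_model_atv <- function(omega2_CL = 0.05) {
  hair_model("ATV", dose_regimen(300, 24), plasma_defaults("ATV"),
             frac_pop = 0.16, covariates = character(),
             omega2 = c(k12 = 0, CL = omega2_CL, Vc = 0),
             sd_add = 0.10, sd_prop = 0.20,
             estimated = c("frac_pop", "omega2_CL", "sd_add", "sd_prop"),
             link = "individual")
}

# linear-in-eta toy data: y_ij = theta + eta_i + eps_ij
sim_linear_toy <- function(n_subj, n_obs, theta, omega2, sd_add, seed) {
  withr::with_seed(seed, {
    eta <- rnorm(n_subj, 0, sqrt(omega2))
    data.frame(
      subject = rep(seq_len(n_subj), each = n_obs),
      conc = theta + rep(eta, each = n_obs) + rnorm(n_subj * n_obs, 0, sd_add))
  })
}

# exact -2 log marginal likelihood of the linear toy (independent oracle:
# per-subject multivariate normal with compound-symmetric covariance)
analytic_linear_ofv <- function(d, theta, omega2, sd_add) {
  ofv <- 0
  for (s in split(d, d$subject)) {
    n <- nrow(s)
    V <- omega2 * matrix(1, n, n) + diag(sd_add^2, n)
    r <- s$conc - theta
    ofv <- ofv - 2 * (-n / 2 * log(2 * pi) -
                        0.5 * as.numeric(determinant(V)$modulus) -
                        0.5 * as.numeric(t(r) %*% solve(V) %*% r))
  }
  ofv
}

# fast optimiser settings for calibration loops (dOFV precision ~1e-3)
fast_ctl <- list(rel.tol = 1e-8)
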