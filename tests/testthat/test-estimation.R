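# Laplace marginal likelihood, conditional modes, quadrature oracle and
# the outer fit.

test_that("subject joint log-likelihood matches closed forms and an independent re-implementation", {
  # no observations: the log-prior of a standard normal at zero
  m1 <- toy_model(theta = 0, omega2 = 1, sd_add = 1)
  empty <- data.frame(subject = integer(0), conc = numeric(0))
  expect_equal(subject_joint_loglik(empty, m1, 0), dnorm(0, log = TRUE))

  # one observation, additive error: Gaussian log-density plus prior
  d1 <- data.frame(subject = 1, conc = 1.3)
  m2 <- toy_model(theta = 1, omega2 = 0.5, sd_add = 0.2)
  expect_equal(subject_joint_loglik(d1, m2, 0.1),
               dnorm(1.3, 1.1, 0.2, log = TRUE) +
                 dnorm(0.1, 0, sqrt(0.5), log = TRUE),
               tolerance = 1e-12)

  # duplicate-implementation oracle on a random individual-link hair
  # instance: recompute every term from first principles
  m3 <- hair_model("ATV", dose_regimen(300, 24), plasma_defaults("ATV"),
                   frac_pop = 0.16, covariates = character(),
                   omega2 = c(k12 = 0.1, CL = 0.3, Vc = 0.2),
                   sd_add = 0.25, sd_prop = 0.4, link = "individual")
  d3 <- data.frame(subject = "S1", occasion = c("enrolment", "followup"),
                   conc = c(2.1, 3.4), weight = 55,
                   adherence_vas = 80)
  eta <- c(k12 = 0.05, CL = -0.2, Vc = 0.1)
  tr <- steady_state_trough(
    dose_regimen(300, 24),
    individual_plasma_params(plasma_defaults("ATV"), eta, weight = 55,
                             ref_weight = 70))
  f_ref <- 0.16 * tr * 100
  ll_ref <- sum(dnorm(d3$conc, f_ref, sqrt(0.25^2 + (0.4 * f_ref)^2),
                      log = TRUE)) +
    sum(dnorm(eta, 0, sqrt(c(0.1, 0.3, 0.2)), log = TRUE))
  expect_equal(subject_joint_loglik(d3, m3, eta), ll_ref, tolerance = 1e-10)
})

test_that("conditional modes solve the inner problem deterministically", {
  # no random-effect dimensions: empty mode
  m0 <- toy_model(theta = 1, omega2 = 0, sd_add = 0.3)
  d <- data.frame(subject = 1, conc = c(0.8, 1.4))
  eb0 <- estimate_ebe(d, m0)
  expect_length(eb0$eta, 0)
  expect_true(eb0$converged)

  # linear toy: the mode is the closed-form ridge solution
  m <- toy_model(theta = 1, omega2 = 0.5, sd_add = 0.3)
  d <- data.frame(subject = 1, conc = c(0.7, 1.6, 1.1))
  ridge <- (sum(d$conc - 1) / 0.09) / (3 / 0.09 + 1 / 0.5)
  eb <- estimate_ebe(d, m)
  expect_equal(unname(eb$eta), ridge, tolerance = 1e-7)

  # permutation symmetry of the observations
  d_rev <- d[rev(seq_len(nrow(d))), ]
  expect_equal(estimate_ebe(d_rev, m)$eta, eb$eta, tolerance = 1e-10)
})

test_that("Laplace OFV is exact without random effects and for linear-in-eta models", {
  # omega2 = 0: no integral to approximate
  m0 <- toy_model(theta = 1, omega2 = 0, sd_add = 0.3)
  d <- data.frame(subject = rep(1:3, each = 2),
                  conc = c(0.8, 1.4, 1.1, 0.9, 1.3, 1.0))
  expect_equal(as.numeric(laplace_ofv(d, m0)),
               -2 * sum(dnorm(d$conc, 1, 0.3, log = TRUE)),
               tolerance = 1e-12)

  # linear toy: Laplace equals the exact Gaussian marginal
  d_lin <- sim_linear_toy(8, 3, theta = 1, omega2 = 0.5, sd_add = 0.3,
                          seed = 1)
  m <- toy_model(theta = 1, omega2 = 0.5, sd_add = 0.3)
  expect_equal(as.numeric(laplace_ofv(d_lin, m)),
               analytic_linear_ofv(d_lin, 1, 0.5, 0.3), tolerance = 1e-6)

  # additivity: duplicating every subject doubles the OFV
  d_dup <- d_lin
  d_dup$subject <- d_dup$subject + 100
  expect_equal(as.numeric(laplace_ofv(rbind(d_lin, d_dup), m)),
               2 * as.numeric(laplace_ofv(d_lin, m)), tolerance = 1e-8)

  # invariance under subject relabeling and record reordering
  d_shuf <- d_lin[withr::with_seed(2, sample(nrow(d_lin))), ]
  d_shuf$subject <- match(d_shuf$subject, unique(d_shuf$subject)) * 7
  expect_equal(as.numeric(laplace_ofv(d_shuf, m)),
               as.numeric(laplace_ofv(d_lin, m)), tolerance = 1e-8)
})

test_that("adaptive Gauss-Hermite quadrature converges and bounds the Laplace error", {
  m <- toy_model(theta = 2, omega2 = 0.3, sd_add = 0.2, sd_prop = 0.1,
                 predict = function(data, eta, theta)
                   rep(theta * exp(eta), nrow(data)))
  d <- withr::with_seed(3, data.frame(
    subject = rep(1:5, each = 2),
    conc = 2 * exp(rep(rnorm(5, 0, sqrt(0.3)), each = 2)) *
      (1 + rnorm(10, 0, 0.1)) + rnorm(10, 0, 0.2)))

  expect_error(quadrature_ofv(d, m, n_nodes = 1), ">= 2")

  # node-count convergence (Cauchy criterion)
  q8 <- quadrature_ofv(d, m, 8)
  q16 <- quadrature_ofv(d, m, 16)
  q32 <- quadrature_ofv(d, m, 32)
  expect_lt(abs(q32 - q16), 1e-4)
  expect_lte(abs(q32 - q16), abs(q16 - q8) + 1e-10)

  # Laplace within its advertised tolerance of the quadrature limit
  expect_lt(abs(as.numeric(laplace_ofv(d, m)) - q32), 0.5)

  # linear toy: quadrature is exact to machine-level accuracy
  d_lin <- sim_linear_toy(6, 2, theta = 1, omega2 = 0.4, sd_add = 0.25,
                          seed = 4)
  m_lin <- toy_model(theta = 1, omega2 = 0.4, sd_add = 0.25)
  expect_equal(quadrature_ofv(d_lin, m_lin, 16),
               analytic_linear_ofv(d_lin, 1, 0.4, 0.25), tolerance = 1e-8)

  # with no random effects the two objectives coincide exactly
  m00 <- toy_model(theta = 1, omega2 = 0, sd_add = 0.25)
  expect_equal(quadrature_ofv(d_lin, m00, 8),
               as.numeric(laplace_ofv(d_lin, m00)), tolerance = 1e-12)

  # individual-link hair model with one live eta: Laplace vs quadrature
  m1 <- one_eta_model_atv(omega2_CL = 0.05)
  co <- simulate_cohort(atv_cohort_spec(8, seed = 5, truth = m1))
  d1 <- analysis_dataset(co, "ATV")
  expect_lt(abs(as.numeric(laplace_ofv(d1, m1)) -
                  quadrature_ofv(d1, m1, 32)), 0.5)
})

test_that("the outer fit is a fixed point, respects masks, and scales with data duplication", {
  truth <- occasion_model_atv(-0.30)
  co <- simulate_cohort(atv_cohort_spec(60, seed = 6, truth = truth))
  d <- analysis_dataset(co, "ATV")
  fit <- fit_hair_model(d, truth, se = TRUE)
  expect_true(fit$convergence)

  # refitting from the optimum barely moves the objective
  fit2 <- fit_hair_model(d, fit$model, se = FALSE)
  expect_lt(abs(fit$ofv - fit2$ofv), 0.01)

  # SEs present exactly for estimated parameters
  est <- fit$estimates
  expect_true(all(is.finite(est$se[est$estimated])))
  expect_true(all(is.na(est$se[!est$estimated])))

  # fixing the fraction removes its SE and leaves it at the start value
  fitf <- fit_hair_model(d, truth,
                         estimate = c("beta_occasion", "sd_prop"), se = TRUE)
  expect_equal(fitf$model$params[["frac_pop"]], 0.16)
  expect_true(is.na(fitf$estimates$se[fitf$estimates$parameter == "frac_pop"]))

  # duplicated dataset: OFV doubles, estimates unchanged
  d_dup <- d
  d_dup$subject <- paste0(d_dup$subject, "_b")
  fit_dd <- fit_hair_model(rbind(d, d_dup), truth, se = FALSE)
  expect_equal(fit_dd$ofv, 2 * fit$ofv, tolerance = 0.05 / abs(2 * fit$ofv))
  expect_equal(fit_dd$model$params[fit$model$estimated],
               fit$model$params[fit$model$estimated], tolerance = 1e-3)

  # nested models: the richer model can only improve the optimum
  richer <- hair_model("ATV", dose_regimen(300, 24), plasma_defaults("ATV"),
                       frac_pop = 0.16,
                       betas = c(beta_occasion = -0.30,
                                 beta_adherence = 0),
                       covariates = c("occasion", "adherence"),
                       sd_add = 0.30, sd_prop = 0.50,
                       estimated = c("frac_pop", "beta_occasion",
                                     "beta_adherence", "sd_prop"))
  fit_rich <- fit_hair_model(d, richer, se = FALSE)
  expect_lte(fit_rich$ofv, fit$ofv + 0.01)
})

test_that("estimating a variance component works under the individual link", {
  m <- one_eta_model_atv(omega2_CL = 0.08)
  co <- simulate_cohort(atv_cohort_spec(40, seed = 7, truth = m))
  d <- analysis_dataset(co, "ATV")
  fit <- fit_hair_model(d, m, se = FALSE, control = list(rel.tol = 1e-7))
  expect_true(fit$convergence)
  # broad recovery checks at this small n
  expect_equal(fit$model$params[["frac_pop"]], 0.16, tolerance = 0.15)
  expect_gt(fit$model$params[["omega2_CL"]], 0.005)
  expect_lt(fit$model$params[["omega2_CL"]], 0.5)
  # EBEs are produced for every subject with data
  expect_setequal(unique(fit$ebes$component), "CL")
  expect_equal(length(unique(fit$ebes$subject)), fit$n_subjects)
})
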