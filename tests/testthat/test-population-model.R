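# Covariate and random-effect mapping to individual parameters, and the
# residual-error model.

test_that("allometric scaling and log-normal effects map population to individual plasma parameters", {
  pop <- plasma_defaults("ATV")

  id <- individual_plasma_params(pop, c(k12 = 0, CL = 0, Vc = 0),
                                 weight = 70, ref_weight = 70)
  expect_equal(c(id$k12, id$CL, id$Vc), c(0.44, 10, 63.4))

  half <- individual_plasma_params(pop, weight = 35, ref_weight = 70)
  expect_equal(half$CL, 10 * 0.5^0.75, tolerance = 1e-12)   # 5.946 L/h
  expect_equal(half$Vc, 63.4 * 0.5, tolerance = 1e-12)

  dbl <- individual_plasma_params(pop, c(CL = log(2)), weight = 70)
  expect_equal(dbl$CL, 20, tolerance = 1e-12)

  # doubling weight multiplies CL by 2^0.75 and Vc by 2 exactly
  w1 <- individual_plasma_params(pop, weight = 40)
  w2 <- individual_plasma_params(pop, weight = 80)
  expect_equal(w2$CL / w1$CL, 2^0.75, tolerance = 1e-12)
  expect_equal(w2$Vc / w1$Vc, 2, tolerance = 1e-12)

  expect_error(individual_plasma_params(pop, weight = 0), "> 0")
})

test_that("individual fraction multiplies covariate factors with the documented reference levels", {
  fe <- c(frac_pop = 0.16, beta_occasion = -0.30, beta_adherence = 0.02,
          beta_bmi_thin = 0.54, beta_bmi_overweight = -0.21,
          beta_cg_parent = 0.53, beta_cg_uncle_aunt = 0.12,
          beta_cg_sibling = -0.54)

  # enrolment at reference adherence/BMI/caregiver: 0.16 * 0.70
  d1 <- data.frame(occasion = "enrolment", adherence_vas = 84.2,
                   bmi = "normal", caregiver = "grandparent")
  expect_equal(individual_frac(fe, d1), 0.112, tolerance = 1e-12)

  # everything at reference: the population value
  d2 <- data.frame(occasion = "followup", adherence_vas = 84.2,
                   bmi = "normal", caregiver = "grandparent")
  expect_equal(individual_frac(fe, d2), 0.16, tolerance = 1e-12)

  # thin + sibling at follow-up: 0.16 * 1.54 * 0.46
  d3 <- data.frame(occasion = "followup", adherence_vas = 84.2,
                   bmi = "thin", caregiver = "sibling")
  expect_equal(individual_frac(fe, d3), 0.16 * 1.54 * 0.46,
               tolerance = 1e-12)

  # adherence acts exponentially: one VAS unit scales by exp(beta)
  d4 <- d2; d4$adherence_vas <- 85.2
  expect_equal(individual_frac(fe, d4) / individual_frac(fe, d2),
               exp(0.02), tolerance = 1e-12)

  # multiplicativity: switching one covariate scales by exactly its factor,
  # independent of the others
  withr::with_seed(42, {
    for (k in 1:10) {
      base <- data.frame(
        occasion = sample(c("enrolment", "followup"), 1),
        adherence_vas = runif(1, 30, 100),
        bmi = sample(c("normal", "thin", "overweight"), 1),
        caregiver = "grandparent")
      alt <- base; alt$caregiver <- "sibling"
      expect_equal(individual_frac(fe, alt) / individual_frac(fe, base),
                   0.46, tolerance = 1e-12)
    }
  })

  # a factor driven non-positive names the offending covariate
  fe_bad <- fe; fe_bad["beta_occasion"] <- -1.2
  expect_error(individual_frac(fe_bad, d1), "occasion")
  expect_error(individual_frac(fe, data.frame(occasion = "baseline")),
               "occasion level")
  expect_error(individual_frac(fe, data.frame(bmi = "obese")), "bmi level")
})

test_that("residual SD combines additive and proportional components", {
  r <- c(sd_add = 0.30, sd_prop = 0.50)
  expect_equal(residual_sd(2.5, r), sqrt(1.5625 + 0.09), tolerance = 1e-12)
  expect_equal(residual_sd(0, r), 0.30)
  expect_equal(residual_sd(1, c(sd_add = 0, sd_prop = 0.50)), 0.50)
  expect_error(residual_sd(1, c(sd_add = 0, sd_prop = 0)), "not both 0")
  expect_error(residual_sd(-1, r), ">= 0")
})

test_that("simulated observations are deterministic under a seed and match the error model", {
  f <- rep(2.5, 1e5)
  r <- c(sd_add = 0.30, sd_prop = 0.50)

  # degenerate noise reproduces the prediction bit-for-bit
  expect_identical(simulate_observation(c(1.5, 2), c(sd_add = 0, sd_prop = 0)),
                   c(1.5, 2))

  expect_identical(simulate_observation(f[1:10], r, seed = 9),
                   simulate_observation(f[1:10], r, seed = 9))

  # Monte-Carlo SD matches the residual-SD formula within 2%
  y <- simulate_observation(f, r, seed = 11)
  expect_equal(sd(y), residual_sd(2.5, r), tolerance = 0.02)
  expect_equal(mean(y), 2.5, tolerance = 0.01)
})
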