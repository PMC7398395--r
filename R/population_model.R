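#' Individual plasma parameters from population values
#'
#' Applies allometric body-weight scaling (exponent 0.75 on clearance, 1 on
#' volume) and log-normal random effects to the population plasma
#' parameters:
#' \deqn{CL_i = CL\,(W/W_{ref})^{0.75} e^{\eta_{CL}},\quad
#'       V_{c,i} = V_c\,(W/W_{ref})\, e^{\eta_{Vc}},\quad
#'       k_{12,i} = k_{12}\, e^{\eta_{k12}}.}
#'
#' @param pop A [plasma_params()] object with population values.
#' @param eta Named numeric vector of random effects; any of `k12`, `CL`,
#'   `Vc` (missing components are treated as 0).
#' @param weight Body weight (kg), > 0.
#' @param ref_weight Reference body weight (kg), > 0 (default 70).
#' @return A [plasma_params()] object with individual values.
#' @examples
#' individual_plasma_params(plasma_defaults("ATV"),
#'                          c(CL = log(2)), weight = 70)
#' @export
individual_plasma_params <- function(pop, eta = c(k12 = 0, CL = 0, Vc = 0),
                                     weight, ref_weight = 70) {
  stopifnot(inherits(pop, "plasma_params"))
  if (!is.numeric(weight) || any(weight <= 0))
    stop("weight must be > 0", call. = FALSE)
  if (ref_weight <= 0) stop("ref_weight must be > 0", call. = FALSE)
  e <- function(nm) if (nm %in% names(eta)) unname(eta[[nm]]) else 0
  plasma_params(k12 = pop$k12 * exp(e("k12")),
                CL = pop$CL * (weight / ref_weight)^0.75 * exp(e("CL")),
                Vc = pop$Vc * (weight / ref_weight) * exp(e("Vc")))
}

#' Individual hair-to-plasma fraction from covariates
#'
#' Maps the population fraction and covariate coefficients to the
#' individual fraction. Categorical covariates act as proportional-linear
#' factors `(1 + beta)` relative to their reference level (follow-up
#' occasion, normal BMI-for-age, grandparent caregiver); the continuous
#' adherence score acts through the always-positive exponential form
#' `exp(beta_adherence * (VAS - adherence_ref))`, which reads as a
#' `beta_adherence`-per-unit proportional change near the reference score.
#'
#' @param fe Named list or vector of fixed effects: `frac_pop` plus any of
#'   `beta_occasion` (enrolment vs follow-up), `beta_adherence` (per VAS
#'   unit), `beta_bmi_thin`, `beta_bmi_overweight`, `beta_cg_parent`,
#'   `beta_cg_uncle_aunt`, `beta_cg_sibling`. Missing coefficients are 0.
#' @param cov Data frame of covariates with columns `occasion`
#'   (`"enrolment"`/`"followup"`), `bmi` (`"normal"`/`"thin"`/
#'   `"overweight"`), `caregiver` (`"grandparent"`/`"parent"`/
#'   `"uncle_aunt"`/`"sibling"`) and `adherence_vas` (0-100). Columns
#'   without a matching coefficient may be omitted.
#' @param adherence_ref Centering value for the adherence score (default
#'   84.2, the cohort mean); `frac_pop` is the typical fraction at this
#'   score for the reference categories.
#' @return Numeric vector of individual fractions, one per row of `cov`.
#' @examples
#' individual_frac(c(frac_pop = 0.16, beta_occasion = -0.30),
#'                 data.frame(occasion = "enrolment"))
#' @export
individual_frac <- function(fe, cov, adherence_ref = 84.2) {
  fe <- as.list(fe)
  if (is.null(fe$frac_pop) || fe$frac_pop <= 0)
    stop("frac_pop must be present and > 0", call. = FALSE)
  g <- function(nm) if (!is.null(fe[[nm]])) fe[[nm]] else 0
  n <- nrow(cov)
  fac_occ <- rep(1, n)
  if (!is.null(cov$occasion)) {
    bad <- setdiff(unique(cov$occasion), c("enrolment", "followup"))
    if (length(bad)) stop("unknown occasion level: ", bad[1], call. = FALSE)
    fac_occ <- 1 + g("beta_occasion") * (cov$occasion == "enrolment")
  }
  fac_adh <- rep(1, n)
  if (!is.null(cov$adherence_vas)) {
    if (any(cov$adherence_vas < 0 | cov$adherence_vas > 100))
      stop("adherence_vas must lie in [0, 100]", call. = FALSE)
    fac_adh <- exp(g("beta_adherence") * (cov$adherence_vas - adherence_ref))
  }
  fac_bmi <- rep(1, n)
  if (!is.null(cov$bmi)) {
    bad <- setdiff(unique(cov$bmi), c("normal", "thin", "overweight"))
    if (length(bad)) stop("unknown bmi level: ", bad[1], call. = FALSE)
    fac_bmi <- 1 + g("beta_bmi_thin") * (cov$bmi == "thin") +
      g("beta_bmi_overweight") * (cov$bmi == "overweight")
  }
  fac_cg <- rep(1, n)
  if (!is.null(cov$caregiver)) {
    bad <- setdiff(unique(cov$caregiver),
                   c("grandparent", "parent", "uncle_aunt", "sibling"))
    if (length(bad)) stop("unknown caregiver level: ", bad[1], call. = FALSE)
    fac_cg <- 1 + g("beta_cg_parent") * (cov$caregiver == "parent") +
      g("beta_cg_uncle_aunt") * (cov$caregiver == "uncle_aunt") +
      g("beta_cg_sibling") * (cov$caregiver == "sibling")
  }
  for (nm in c("occasion", "bmi", "caregiver")) {
    fac <- switch(nm, occasion = fac_occ, bmi = fac_bmi, caregiver = fac_cg)
    if (any(fac <= 0))
      stop("covariate effect for '", nm,
           "' drives the fraction non-positive", call. = FALSE)
  }
  fe$frac_pop * fac_occ * fac_adh * fac_bmi * fac_cg
}

#' Residual error standard deviation
#'
#' Combined additive and proportional residual error:
#' `sd = sqrt((sd_prop * f)^2 + sd_add^2)`.
#'
#' @param f Model prediction(s), >= 0.
#' @param r Named list or vector with `sd_add` and `sd_prop` (both >= 0,
#'   not both 0).
#' @return Observation standard deviation, same length as `f`.
#' @examples
#' residual_sd(2.5, c(sd_add = 0.30, sd_prop = 0.50))
#' @export
residual_sd <- function(f, r) {
  r <- as.list(r)
  if (r$sd_add < 0 || r$sd_prop < 0 || (r$sd_add == 0 && r$sd_prop == 0))
    stop("sd_add and sd_prop must be >= 0 and not both 0", call. = FALSE)
  if (any(f < 0)) stop("prediction f must be >= 0", call. = FALSE)
  sqrt((r$sd_prop * f)^2 + r$sd_add^2)
}

#' Simulate hair observations from predictions
#'
#' Draws `y = f * (1 + eps_prop) + eps_add` with independent zero-mean
#' normal errors. Negative draws are retained (they are censored against
#' the assay lower limit downstream, and truncating here would bias
#' residual-error recovery).
#'
#' @param f Vector of model predictions.
#' @param r Residual specification as in [residual_sd()].
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return Simulated concentrations, same length as `f`.
#' @export
simulate_observation <- function(f, r, seed = NULL) {
  r <- as.list(r)
  draw <- function() {
    f * (1 + stats::rnorm(length(f), 0, r$sd_prop)) +
      stats::rnorm(length(f), 0, r$sd_add)
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}
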