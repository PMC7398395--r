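#' Joint plasma-hair population model specification
#'
#' Bundles the structural plasma model (fixed literature parameters with
#' allometric weight scaling), the hair-fraction parameter with its
#' covariate coefficients, the random-effect variances and the residual
#' error model into a single object used by the simulator, the estimator,
#' the covariate-selection and bootstrap routines, and the diagnostics.
#'
#' The hair observation model is
#' \deqn{y_{ij} = f_{ij}(1+\varepsilon_{prop}) + \varepsilon_{add},\qquad
#'       f_{ij} = F_{rac,ij}\; T_i / V_h,}
#' where \eqn{F_{rac,ij}} is the covariate-adjusted hair-to-plasma
#' fraction ([individual_frac()]) and \eqn{T_i} a steady-state plasma
#' trough in the model's internal concentration unit (µg/dL, i.e. the
#' mg/L trough times `trough_scale = 100`; any remaining absolute scale is
#' absorbed into the fraction).
#'
#' Two link conventions are supported for \eqn{T_i}:
#' \describe{
#'   \item{`"population"` (default)}{the subject's *typical* trough from
#'     the weight-scaled plasma parameters. The hair fraction is then a
#'     ratio against the typical trough and plasma inter-individual
#'     variability does not propagate into the hair prediction, mirroring
#'     the near-total insensitivity of steady-state hair deposition to
#'     plasma disposition (the amount transferred per dosing interval at
#'     steady state is \eqn{F_{rac} D} regardless of CL, Vc, k12).}
#'   \item{`"individual"`}{the trough is computed from eta-perturbed
#'     individual plasma parameters, so the `omega2_*` variances enter the
#'     marginal likelihood and are estimable.}
#' }
#'
#' @param analyte Label, e.g. `"ATV"` or `"RTV"`.
#' @param regimen A [dose_regimen()].
#' @param plasma A [plasma_params()] with population values.
#' @param frac_pop Population hair-to-plasma fraction.
#' @param betas Named numeric vector of covariate coefficients on the
#'   fraction (see [individual_frac()]); only coefficients of covariates
#'   listed in `covariates` are active.
#' @param covariates Character subset of
#'   `c("occasion", "adherence", "bmi", "caregiver")` naming the
#'   covariate-fraction relations present in the model.
#' @param omega2 Named vector `c(k12=, CL=, Vc=)` of variances of the
#'   log-normal inter-individual effects on the plasma parameters.
#' @param omega2_frac_iov Inter-occasion variance of a log-normal effect
#'   on the fraction (default 0 = off).
#' @param sd_add,sd_prop Additive (hair-unit) and proportional residual
#'   error SDs.
#' @param estimated Character vector of parameter names to estimate; the
#'   remainder are fixed. Parameter names are `frac_pop`, the `beta_*`
#'   names, `omega2_k12`, `omega2_CL`, `omega2_Vc`, `omega2_frac_iov`,
#'   `sd_add`, `sd_prop`.
#' @param link `"population"` or `"individual"` (see Details).
#' @param blq_method Handling of assay truncation in the likelihood.
#'   Only quantifiable records enter the fit in either mode. `"M2"`
#'   (default) uses the conditional likelihood of a quantifiable record
#'   — each observation density is divided by `P(y >= LLOQ)` — which is
#'   consistent under left-truncation at the assay limit; `"M1"` uses the
#'   plain density (simple exclusion), which is biased when the censored
#'   fraction is appreciable. The adjustment activates only when the data
#'   carry an `lloq` column.
#' @param ref_weight Allometric reference weight (kg), default 70.
#' @param adherence_ref Adherence-score centering value, default 84.2.
#' @param trough_scale Factor converting the mg/L trough to the internal
#'   concentration unit (default 100, i.e. µg/dL).
#' @param Vh Apparent hair volume, fixed to 1 by default.
#' @return An object of class `hair_model`.
#' @seealso [atv_model()], [rtv_model()], [fit_hair_model()]
#' @export
hair_model <- function(analyte,
                       regimen,
                       plasma,
                       frac_pop,
                       betas = c(beta_occasion = 0, beta_adherence = 0,
                                 beta_bmi_thin = 0, beta_bmi_overweight = 0,
                                 beta_cg_parent = 0, beta_cg_uncle_aunt = 0,
                                 beta_cg_sibling = 0),
                       covariates = character(),
                       omega2 = c(k12 = 0, CL = 0, Vc = 0),
                       omega2_frac_iov = 0,
                       sd_add = 0.3,
                       sd_prop = 0.5,
                       estimated = c("frac_pop", "sd_add", "sd_prop"),
                       link = c("population", "individual"),
                       blq_method = c("M2", "M1"),
                       ref_weight = 70,
                       adherence_ref = 84.2,
                       trough_scale = 100,
                       Vh = 1) {
  link <- match.arg(link)
  blq_method <- match.arg(blq_method)
  stopifnot(inherits(regimen, "dose_regimen"), inherits(plasma, "plasma_params"))
  cov_choices <- c("occasion", "adherence", "bmi", "caregiver")
  if (length(covariates) && length(setdiff(covariates, cov_choices)))
    stop("unknown covariate relation: ",
         setdiff(covariates, cov_choices)[1], call. = FALSE)
  if (frac_pop <= 0) stop("frac_pop must be > 0", call. = FALSE)
  if (any(omega2 < 0) || omega2_frac_iov < 0)
    stop("random-effect variances must be >= 0", call. = FALSE)
  beta_names <- c("beta_occasion", "beta_adherence", "beta_bmi_thin",
                  "beta_bmi_overweight", "beta_cg_parent",
                  "beta_cg_uncle_aunt", "beta_cg_sibling")
  b <- stats::setNames(numeric(length(beta_names)), beta_names)
  b[names(betas)] <- betas
  params <- c(frac_pop = frac_pop, b,
              omega2_k12 = unname(omega2[["k12"]]),
              omega2_CL = unname(omega2[["CL"]]),
              omega2_Vc = unname(omega2[["Vc"]]),
              omega2_frac_iov = omega2_frac_iov,
              sd_add = sd_add, sd_prop = sd_prop)
  bad <- setdiff(estimated, names(params))
  if (length(bad)) stop("unknown parameter in 'estimated': ", bad[1],
                        call. = FALSE)
  structure(list(analyte = analyte, regimen = regimen, plasma = plasma,
                 params = params, covariates = covariates,
                 estimated = estimated, link = link,
                 blq_method = blq_method,
                 ref_weight = ref_weight, adherence_ref = adherence_ref,
                 trough_scale = trough_scale, Vh = Vh),
            class = "hair_model")
}

#' Final published atazanavir hair model
#'
#' The fitted atazanavir model: 300 mg once daily, fixed plasma parameters
#' (k12 0.44/h, CL/F 10 L/h, Vc 63.4 L), hair fraction 0.16 with
#' covariate effects (enrolment occasion -30\%, adherence +2\% per VAS
#' unit, thin BMI +54\%, overweight -21\%, parent caregiver +53\%,
#' uncle/aunt +12\%, sibling -54\%), plasma IIV variances
#' (k12 0.45, CL 1.04, Vc 0.50) and combined residual error
#' (additive SD 0.30, proportional SD 0.50).
#'
#' Under the default `"population"` link the plasma IIV variances are
#' carried as fixed descriptors (they do not enter the hair likelihood);
#' the estimated parameters are the fraction, its covariate coefficients
#' and the residual error SDs.
#'
#' @param link Hair-trough link convention, see [hair_model()].
#' @return A `hair_model`.
#' @export
atv_model <- function(link = "population") {
  hair_model(
    analyte = "ATV",
    regimen = dose_regimen(300, 24),
    plasma = plasma_defaults("ATV"),
    frac_pop = 0.16,
    betas = c(beta_occasion = -0.30, beta_adherence = 0.02,
              beta_bmi_thin = 0.54, beta_bmi_overweight = -0.21,
              beta_cg_parent = 0.53, beta_cg_uncle_aunt = 0.12,
              beta_cg_sibling = -0.54),
    covariates = c("occasion", "adherence", "bmi", "caregiver"),
    omega2 = c(k12 = 0.45, CL = 1.04, Vc = 0.50),
    sd_add = 0.30, sd_prop = 0.50,
    estimated = c("frac_pop", "beta_occasion", "beta_adherence",
                  "beta_bmi_thin", "beta_bmi_overweight", "beta_cg_parent",
                  "beta_cg_uncle_aunt", "beta_cg_sibling",
                  "sd_add", "sd_prop"),
    link = link)
}

#' Final published ritonavir hair model
#'
#' The fitted ritonavir model: 100 mg once daily, fixed plasma parameters
#' (k12 2.31/h, CL/F 12.8 L/h, Vc 105 L), hair fraction 0.18 with
#' enrolment-occasion (-42\%) and adherence (+2\% per VAS unit) effects,
#' plasma IIV variances (k12 0.45, CL 0.28, Vc 0.50) and combined residual
#' error (additive SD 0.34, proportional SD 0.26).
#'
#' @inheritParams atv_model
#' @return A `hair_model`.
#' @export
rtv_model <- function(link = "population") {
  hair_model(
    analyte = "RTV",
    regimen = dose_regimen(100, 24),
    plasma = plasma_defaults("RTV"),
    frac_pop = 0.18,
    betas = c(beta_occasion = -0.42, beta_adherence = 0.02),
    covariates = c("occasion", "adherence"),
    omega2 = c(k12 = 0.45, CL = 0.28, Vc = 0.50),
    sd_add = 0.34, sd_prop = 0.26,
    estimated = c("frac_pop", "beta_occasion", "beta_adherence",
                  "sd_add", "sd_prop"),
    link = link)
}

#' Update model parameter values
#'
#' @param model A `hair_model`.
#' @param values Named numeric vector of parameter values to set.
#' @return The updated model.
#' @export
set_params <- function(model, values) {
  stopifnot(inherits(model, "hair_model"))
  bad <- setdiff(names(values), names(model$params))
  if (length(bad)) stop("unknown parameter: ", bad[1], call. = FALSE)
  model$params[names(values)] <- values
  model
}

# Fixed-effect list (frac_pop + active betas) for individual_frac().
# Inactive covariate relations contribute factor 1.
active_fixed_effects <- function(model) {
  p <- model$params
  fe <- list(frac_pop = unname(p[["frac_pop"]]))
  if ("occasion" %in% model$covariates)
    fe$beta_occasion <- unname(p[["beta_occasion"]])
  if ("adherence" %in% model$covariates)
    fe$beta_adherence <- unname(p[["beta_adherence"]])
  if ("bmi" %in% model$covariates) {
    fe$beta_bmi_thin <- unname(p[["beta_bmi_thin"]])
    fe$beta_bmi_overweight <- unname(p[["beta_bmi_overweight"]])
  }
  if ("caregiver" %in% model$covariates) {
    fe$beta_cg_parent <- unname(p[["beta_cg_parent"]])
    fe$beta_cg_uncle_aunt <- unname(p[["beta_cg_uncle_aunt"]])
    fe$beta_cg_sibling <- unname(p[["beta_cg_sibling"]])
  }
  fe
}

#' Residual-error specification of a model (estimation interface)
#'
#' @param model A `hair_model` or `toy_model`.
#' @return List with `sd_add` and `sd_prop`.
#' @export
residual_spec <- function(model) UseMethod("residual_spec")

#' @export
residual_spec.hair_model <- function(model) {
  list(sd_add = unname(model$params[["sd_add"]]),
       sd_prop = unname(model$params[["sd_prop"]]))
}

#' Random-effect structure of one subject's inner problem
#'
#' Which plasma components carry an eta (individual link only, components
#' with positive variance) and whether each occasion carries an
#' inter-occasion eta on the fraction.
#'
#' @param model A `hair_model` or `toy_model`.
#' @param occasions Occasions present for the subject.
#' @return List: `plasma`, `iov`, `vars` (prior variances), `names`,
#'   `ndim`.
#' @export
eta_structure <- function(model, occasions = character())
  UseMethod("eta_structure")

#' @export
eta_structure.hair_model <- function(model, occasions = character()) {
  plasma <- character()
  if (model$link == "individual") {
    for (nm in c("k12", "CL", "Vc"))
      if (model$params[[paste0("omega2_", nm)]] > 0)
        plasma <- c(plasma, nm)
  }
  iov <- if (model$params[["omega2_frac_iov"]] > 0) occasions else character()
  v_plasma <- if (length(plasma))
    stats::setNames(unname(model$params[paste0("omega2_", plasma)]), plasma)
  else stats::setNames(numeric(0), character(0))
  v_iov <- if (length(iov))
    stats::setNames(rep(model$params[["omega2_frac_iov"]], length(iov)),
                    paste0("iov_", iov))
  else stats::setNames(numeric(0), character(0))
  vars <- c(v_plasma, v_iov)
  list(plasma = plasma, iov = iov, vars = unname(vars),
       names = names(vars), ndim = length(vars))
}

#' Model predictions for a covariate/observation table
#'
#' Computes the structural hair prediction `f` for each row of `data`,
#' optionally under given random effects.
#'
#' @param model A `hair_model`.
#' @param data Data frame with one row per observation; required columns
#'   depend on the active covariates (`occasion`, `adherence_vas`, `bmi`,
#'   `caregiver`) plus `weight` and, for eta-bearing models, `subject`.
#' @param eta Optional named numeric vector of random effects shared by
#'   all rows (used for single-subject evaluation): plasma components
#'   `k12`, `CL`, `Vc` and/or inter-occasion components
#'   `iov_enrolment`, `iov_followup`.
#' @return Numeric vector of predictions (internal hair units).
#' @export
predict_f <- function(model, data, eta = NULL) {
  stopifnot(inherits(model, "hair_model"))
  frac_i <- individual_frac(active_fixed_effects(model), data,
                            adherence_ref = model$adherence_ref)
  w <- data$weight %||% rep(model$ref_weight, nrow(data))
  sc <- (w / model$ref_weight)
  k12 <- rep(model$plasma$k12, nrow(data))
  CL <- model$plasma$CL * sc^0.75
  Vc <- model$plasma$Vc * sc
  if (!is.null(eta) && model$link == "individual") {
    e <- function(nm) if (nm %in% names(eta)) eta[[nm]] else 0
    k12 <- k12 * exp(e("k12"))
    CL <- CL * exp(e("CL"))
    Vc <- Vc * exp(e("Vc"))
  }
  trough <- .trough_value(model$regimen$dose_amount, model$regimen$interval,
                          k12, CL, Vc)
  f <- frac_i * trough * model$trough_scale / model$Vh
  if (!is.null(eta)) {
    iov <- paste0("iov_", data$occasion %||% rep("", nrow(data)))
    has <- iov %in% names(eta)
    if (any(has)) f[has] <- f[has] * exp(unlist(eta[iov[has]]))
  }
  f
}

#' @export
print.hair_model <- function(x, ...) {
  cat("<hair_model> analyte:", x$analyte,
      sprintf("| %g mg q%gh | link: %s\n",
              x$regimen$dose_amount, x$regimen$interval, x$link))
  cat(sprintf("  plasma: k12=%.3g CL=%.3g Vc=%.3g (ref weight %g kg)\n",
              x$plasma$k12, x$plasma$CL, x$plasma$Vc, x$ref_weight))
  cat("  covariates on fraction:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  est <- names(x$params) %in% x$estimated
  cat("  parameters (* = estimated):\n")
  for (i in seq_along(x$params))
    cat(sprintf("    %-22s %9.4g%s\n", names(x$params)[i], x$params[i],
                if (est[i]) " *" else ""))
  invisible(x)
}

#' Write / read a model configuration as YAML
#'
#' Flat key-value serialisation of a `hair_model`: parameter values,
#' estimated flags and the structural settings.
#'
#' @param model A `hair_model`.
#' @param path File path.
#' @return `write_model_yaml` returns `path` invisibly;
#'   `read_model_yaml` returns a `hair_model`.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "hair_model"))
  obj <- list(
    analyte = model$analyte,
    dose_amount = model$regimen$dose_amount,
    interval = model$regimen$interval,
    plasma = list(k12 = model$plasma$k12, CL = model$plasma$CL,
                  Vc = model$plasma$Vc),
    link = model$link,
    blq_method = model$blq_method,
    ref_weight = model$ref_weight,
    adherence_ref = model$adherence_ref,
    trough_scale = model$trough_scale,
    Vh = model$Vh,
    covariates = as.list(model$covariates),
    params = as.list(model$params),
    estimated = as.list(model$estimated))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- unlist(obj$params)
  hair_model(analyte = obj$analyte,
             regimen = dose_regimen(obj$dose_amount, obj$interval),
             plasma = plasma_params(obj$plasma$k12, obj$plasma$CL,
                                    obj$plasma$Vc),
             frac_pop = p[["frac_pop"]],
             betas = p[grep("^beta_", names(p))],
             covariates = unlist(obj$covariates) %||% character(),
             omega2 = c(k12 = p[["omega2_k12"]], CL = p[["omega2_CL"]],
                        Vc = p[["omega2_Vc"]]),
             omega2_frac_iov = p[["omega2_frac_iov"]],
             sd_add = p[["sd_add"]], sd_prop = p[["sd_prop"]],
             estimated = unlist(obj$estimated),
             link = obj$link, blq_method = obj$blq_method %||% "M2",
             ref_weight = obj$ref_weight,
             adherence_ref = obj$adherence_ref,
             trough_scale = obj$trough_scale, Vh = obj$Vh)
}
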