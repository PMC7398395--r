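# A minimal single-eta model class used to validate the estimation and
# diagnostics machinery against analytic results (closed-form posterior
# modes, exact Gaussian marginals, quadrature limits). It shares the
# hair_model's estimation interface: model_predict(), eta_structure(),
# residual_spec().

#' Minimal one-random-effect model for estimator validation
#'
#' A deliberately simple mixed model with one random effect per subject:
#' by default the linear form `f = theta + eta` (whose marginal
#' likelihood is exactly Gaussian, giving an analytic oracle for the
#' Laplace and quadrature objective functions), or any user-supplied
#' prediction function for nonlinear cases.
#'
#' @param theta Fixed effect (scalar).
#' @param omega2 Variance of the subject-level random effect (>= 0; 0
#'   disables it).
#' @param sd_add,sd_prop Residual error SDs, as in [residual_sd()].
#' @param predict Optional `function(data, eta, theta)` returning a
#'   prediction per row of `data`; `eta` is a scalar. Default
#'   `theta + eta`.
#' @return An object of class `toy_model`.
#' @examples
#' m <- toy_model(theta = 1, omega2 = 0.5, sd_add = 0.3)
#' laplace_ofv(data.frame(subject = 1, conc = c(0.9, 1.2)), m)
#' @export
toy_model <- function(theta, omega2, sd_add, sd_prop = 0, predict = NULL) {
  stopifnot(omega2 >= 0, sd_add >= 0, sd_prop >= 0)
  structure(list(theta = theta, omega2 = omega2,
                 sd_add = sd_add, sd_prop = sd_prop,
                 blq_method = "M1",
                 predict_fun = predict %||%
                   function(data, eta, theta) rep(theta + eta, nrow(data))),
            class = "toy_model")
}

#' Model predictions (estimation interface)
#'
#' Dispatches the per-record structural prediction for the model classes
#' the estimator understands.
#'
#' @param model A `hair_model` or `toy_model`.
#' @param data Observation rows.
#' @param eta Named random-effect vector (possibly empty).
#' @return Numeric vector of predictions.
#' @export
model_predict <- function(model, data, eta = NULL) UseMethod("model_predict")

#' @export
model_predict.hair_model <- function(model, data, eta = NULL) {
  predict_f(model, data, eta = eta)
}

#' @export
model_predict.toy_model <- function(model, data, eta = NULL) {
  e <- if (!is.null(eta) && "eta" %in% names(eta)) eta[["eta"]] else 0
  model$predict_fun(data, e, model$theta)
}

#' @export
eta_structure.toy_model <- function(model, occasions = character()) {
  if (model$omega2 > 0)
    list(plasma = character(), iov = character(),
         vars = model$omega2, names = "eta", ndim = 1L)
  else
    list(plasma = character(), iov = character(),
         vars = numeric(0), names = character(0), ndim = 0L)
}

#' @export
residual_spec.toy_model <- function(model) {
  list(sd_add = model$sd_add, sd_prop = model$sd_prop)
}

# does any record-level random effect exist?
.has_eta <- function(model, ...) UseMethod(".has_eta")

#' @export
.has_eta.hair_model <- function(model, ...) {
  eta_structure(model)$ndim > 0L || model$params[["omega2_frac_iov"]] > 0
}

#' @export
.has_eta.toy_model <- function(model, ...) model$omega2 > 0
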