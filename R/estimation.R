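# Marginal-likelihood estimation by Laplace approximation at the
# per-subject conditional modes, with an adaptive Gauss-Hermite quadrature
# oracle and empirical Bayes estimates.

# parameter transforms used by the outer optimiser: positive parameters are
# estimated on the log scale, covariate coefficients on the natural scale
# with box constraints keeping every proportional factor positive
.par_transform <- function(names) {
  ifelse(grepl("^(frac_pop|omega2_|sd_)", names), "log", "identity")
}

.par_bounds <- function(names) {
  lo <- ifelse(grepl("^(frac_pop|omega2_|sd_)", names), log(1e-6),
               ifelse(names == "beta_adherence", -0.3, -0.99))
  hi <- ifelse(grepl("^(frac_pop|omega2_|sd_)", names), log(1e4),
               ifelse(names == "beta_adherence", 0.3, 20))
  list(lower = lo, upper = hi)
}

.to_transformed <- function(values, trans) {
  out <- values
  out[trans == "log"] <- log(values[trans == "log"])
  out
}

.from_transformed <- function(values, trans) {
  out <- values
  out[trans == "log"] <- exp(values[trans == "log"])
  out
}

# per-record observation log-density; under the M2 convention the density
# of a quantifiable record is conditioned on y >= LLOQ (left-truncation)
.obs_loglik <- function(y, f, model, lloq = NULL) {
  sd <- .resid_sd(f, residual_spec(model))
  ll <- stats::dnorm(y, f, sd, log = TRUE)
  if (identical(model$blq_method, "M2") && !is.null(lloq) &&
      all(is.finite(lloq)))
    ll <- ll - stats::pnorm(lloq, f, sd, lower.tail = FALSE, log.p = TRUE)
  ll
}

# order eta by the model's structure, tolerating unnamed vectors
.eta_named <- function(eta, es) {
  if (es$ndim == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(eta)) || !all(nzchar(names(eta))))
    return(stats::setNames(as.numeric(eta), es$names))
  stats::setNames(as.numeric(eta[es$names]), es$names)
}

# Fast per-subject negative joint log-likelihood closure. For hair models
# all eta-free quantities (covariate-adjusted fractions, weight-scaled
# plasma parameters) are precomputed so the inner optimiser evaluates only
# the trough formula and the Gaussian terms. Equivalent to
# -subject_joint_loglik(); the generic path remains the reference.
.subject_nll_factory <- function(model, sdata, es) {
  if (!inherits(model, "hair_model")) {
    return(function(eta) {
      v <- tryCatch(-subject_joint_loglik(sdata, model,
                                          stats::setNames(eta, es$names)),
                    error = function(e) NA_real_)
      # smooth penalty where the optimiser probes an overflow region
      if (!is.finite(v)) 1e10 + sum(eta^2) else v
    })
  }
  frac_i <- individual_frac(active_fixed_effects(model), sdata,
                            adherence_ref = model$adherence_ref)
  w <- sdata$weight %||% rep(model$ref_weight, nrow(sdata))
  sc <- w / model$ref_weight
  k12_0 <- rep(model$plasma$k12, nrow(sdata))
  CL_0 <- model$plasma$CL * sc^0.75
  Vc_0 <- model$plasma$Vc * sc
  D <- model$regimen$dose_amount
  tau <- model$regimen$interval
  scale <- model$trough_scale / model$Vh
  i_k12 <- match("k12", es$plasma)
  i_CL <- match("CL", es$plasma)
  i_Vc <- match("Vc", es$plasma)
  # per-row index into eta for the occasion-level fraction effect (NA: none)
  iov_idx <- if (length(es$iov))
    match(paste0("iov_", sdata$occasion), es$names)
  else rep(NA_integer_, nrow(sdata))
  r <- residual_spec(model)
  conc <- sdata$conc
  lloq <- if (identical(model$blq_method, "M2") && !is.null(sdata$lloq) &&
              all(is.finite(sdata$lloq))) sdata$lloq else NULL
  sd_vars <- sqrt(es$vars)
  function(eta) {
    k12v <- if (is.na(i_k12)) k12_0 else k12_0 * exp(eta[i_k12])
    CLv <- if (is.na(i_CL)) CL_0 else CL_0 * exp(eta[i_CL])
    Vcv <- if (is.na(i_Vc)) Vc_0 else Vc_0 * exp(eta[i_Vc])
    tr <- .trough_value(D, tau, k12v, CLv, Vcv)
    f <- frac_i * tr * scale
    has_iov <- !is.na(iov_idx)
    if (any(has_iov)) f[has_iov] <- f[has_iov] * exp(eta[iov_idx[has_iov]])
    sd <- sqrt((r$sd_prop * f)^2 + r$sd_add^2)
    ll <- sum(stats::dnorm(conc, f, sd, log = TRUE))
    if (!is.null(lloq))
      ll <- ll - sum(stats::pnorm(lloq, f, sd, lower.tail = FALSE,
                                  log.p = TRUE))
    v <- -(ll + sum(stats::dnorm(eta, 0, sd_vars, log = TRUE)))
    if (!is.finite(v)) 1e10 + sum(eta^2) else v
  }
}

#' Joint log-likelihood of one subject's data and random effects
#'
#' `log p(y | eta) + log p(eta)`: the sum of the observation log-densities
#' under the combined residual-error model plus the log-density of the
#' random-effect vector under its (diagonal) normal prior. This is the
#' inner objective of conditional estimation. Under the model's `"M2"`
#' BLQ convention (and only when the data carry an `lloq` column) each
#' observation density is conditioned on the record being quantifiable,
#' i.e. divided by `P(y >= LLOQ)`.
#'
#' @param sdata One subject's quantifiable observations: a data frame with
#'   `conc` plus the covariate columns the model needs (BLQ rows must be
#'   excluded upstream).
#' @param model A [hair_model()].
#' @param eta Random-effect vector, in the order given by the model's eta
#'   structure (plasma components with positive variance under the
#'   individual link, then per-occasion fraction effects if the
#'   inter-occasion variance is positive). May be empty.
#' @return The joint log-likelihood (scalar).
#' @export
subject_joint_loglik <- function(sdata, model, eta = numeric(0)) {
  es <- eta_structure(model, unique(sdata$occasion))
  eta <- .eta_named(eta, es)
  f <- model_predict(model, sdata, eta = eta)
  if (any(!is.finite(f)))
    stop("non-finite prediction for subject ",
         sdata$subject[1] %||% "?", call. = FALSE)
  ll <- sum(.obs_loglik(sdata$conc, f, model, sdata$lloq))
  if (es$ndim > 0L)
    ll <- ll + sum(stats::dnorm(eta, 0, sqrt(es$vars), log = TRUE))
  ll
}

#' Empirical Bayes estimate (conditional mode) for one subject
#'
#' Maximises [subject_joint_loglik()] over the random-effect vector,
#' starting from `eta = 0` (deterministic, no warm start).
#'
#' @inheritParams subject_joint_loglik
#' @param grad_tol Gradient-norm tolerance used to flag convergence.
#' @return List with `eta` (named), `loglik`, `converged`, `grad_norm`.
#' @export
estimate_ebe <- function(sdata, model, grad_tol = 1e-4) {
  es <- eta_structure(model, unique(sdata$occasion))
  if (es$ndim == 0L)
    return(list(eta = stats::setNames(numeric(0), character(0)),
                loglik = subject_joint_loglik(sdata, model),
                converged = TRUE, grad_norm = 0))
  neg <- .subject_nll_factory(model, sdata, es)
  opt <- stats::optim(rep(0, es$ndim), neg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  g <- pracma::grad(neg, opt$par)
  list(eta = stats::setNames(opt$par, es$names), loglik = -opt$value,
       converged = opt$convergence == 0 && sqrt(sum(g^2)) <= grad_tol *
         max(1, abs(opt$value)),
       grad_norm = sqrt(sum(g^2)))
}

# mode plus Hessian of the negative joint log-likelihood, regularised to
# positive definiteness if needed
.inner_solve <- function(model, sdata, es) {
  neg <- .subject_nll_factory(model, sdata, es)
  opt <- stats::optim(rep(0, es$ndim), neg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- pracma::hessian(neg, opt$par)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  reg <- FALSE
  if (any(ev <= 0)) {
    H <- H + diag(abs(min(ev)) + 1e-6, nrow(H))
    reg <- TRUE
  }
  list(eta = opt$par, loglik = -opt$value, nll = neg, H = H,
       logdet = as.numeric(determinant(H, logarithm = TRUE)$modulus),
       regularised = reg)
}

#' Laplace objective function value (-2 log marginal likelihood)
#'
#' Approximates each subject's marginal likelihood by a second-order
#' Laplace expansion at the conditional mode and returns
#' \deqn{OFV = \sum_i -2\left[\ell_i(\hat\eta_i) + \tfrac{d}{2}\log 2\pi
#'   - \tfrac12 \log\det H_i\right],}
#' with \eqn{H_i} the negative Hessian of the joint log-likelihood at the
#' mode. Interaction is respected: the residual SD depends on the
#' random effects through the prediction. With no active random effects
#' the OFV is the exact \eqn{-2\sum \log N(y; f, sd^2)}.
#'
#' @param data Quantifiable observations for all subjects (long format;
#'   BLQ rows are dropped if a `blq` column is present).
#' @param model A [hair_model()].
#' @return The OFV (scalar), with attribute `"n_regularised"` counting
#'   subjects whose inner Hessian needed regularisation.
#' @export
laplace_ofv <- function(data, model) {
  if (!is.null(data$blq)) data <- data[!data$blq, , drop = FALSE]
  if (nrow(data) == 0L) stop("no quantifiable observations", call. = FALSE)
  if (!.has_eta(model)) {
    f <- model_predict(model, data)
    return(structure(-2 * sum(.obs_loglik(data$conc, f, model, data$lloq)),
                     n_regularised = 0L))
  }
  n_reg <- 0L
  ofv <- 0
  for (sdata in split(data, data$subject)) {
    es <- eta_structure(model, unique(sdata$occasion))
    sol <- .inner_solve(model, sdata, es)
    if (sol$regularised) n_reg <- n_reg + 1L
    ofv <- ofv - 2 * (sol$loglik + es$ndim / 2 * log(2 * pi) -
                        sol$logdet / 2)
  }
  if (n_reg > 0L)
    warning(n_reg, " subject(s) required inner-Hessian regularisation",
            call. = FALSE)
  structure(ofv, n_regularised = n_reg)
}

#' Adaptive Gauss-Hermite objective function value
#'
#' Independent oracle for [laplace_ofv()]: computes each subject's
#' marginal likelihood by adaptive Gauss-Hermite quadrature centred and
#' scaled at the conditional mode. Intended for models with at most two
#' random-effect dimensions per subject (test scale).
#'
#' @inheritParams laplace_ofv
#' @param n_nodes Number of quadrature nodes per dimension (>= 2).
#' @return The OFV (scalar).
#' @export
quadrature_ofv <- function(data, model, n_nodes = 32) {
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  if (!is.null(data$blq)) data <- data[!data$blq, , drop = FALSE]
  gh <- pracma::gaussHermite(n_nodes)
  ofv <- 0
  for (sdata in split(data, data$subject)) {
    es <- eta_structure(model, unique(sdata$occasion))
    if (es$ndim == 0L) {
      ofv <- ofv - 2 * subject_joint_loglik(sdata, model)
      next
    }
    if (es$ndim > 2L)
      stop("quadrature_ofv supports at most 2 random-effect dimensions",
           call. = FALSE)
    sol <- .inner_solve(model, sdata, es)
    L <- t(chol(solve(sol$H)))          # lower factor of H^{-1}
    if (es$ndim == 1L) {
      Z <- matrix(gh$x, ncol = 1)
      lw <- log(gh$w)
    } else {
      g <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
      Z <- cbind(gh$x[g$i], gh$x[g$j])
      lw <- log(gh$w[g$i]) + log(gh$w[g$j])
    }
    lvals <- vapply(seq_len(nrow(Z)), function(k) {
      e <- sol$eta + sqrt(2) * as.numeric(L %*% Z[k, ])
      -sol$nll(e) + sum(Z[k, ]^2)
    }, numeric(1))
    m <- max(lvals + lw)
    logint <- es$ndim / 2 * log(2) +
      sum(log(diag(L))) + m + log(sum(exp(lvals + lw - m)))
    ofv <- ofv - 2 * logint
  }
  ofv
}

#' Fit a hair population model by Laplace marginal likelihood
#'
#' Minimises [laplace_ofv()] over the model's estimated parameters.
#' Positive parameters (fraction, variances, error SDs) are estimated on
#' the log scale; covariate coefficients are box-constrained so every
#' proportional factor stays positive. BLQ records are excluded from the
#' likelihood (M1 method). Standard errors come from the inverse of the
#' numerically differentiated outer Hessian.
#'
#' @param data Long-format observations with covariates: columns
#'   `subject`, `conc`, `blq` (optional), `weight`, and the covariate
#'   columns required by the model's active relations.
#' @param model A [hair_model()] holding the starting values; its
#'   `estimated` field names the free parameters unless `estimate` is
#'   given.
#' @param estimate Optional character vector of parameter names to
#'   estimate, overriding the model's `estimated` set.
#' @param se Compute standard errors (default TRUE).
#' @param control Passed to [stats::nlminb()] (defaults:
#'   `iter.max = 500`, `eval.max = 2000`, `rel.tol = 1e-10`).
#' @param quiet Suppress progress messages.
#' @return An object of class `hairpk_fit`: estimates table (with SEs as
#'   % of the estimate for estimated parameters), OFV, convergence flag,
#'   per-subject empirical Bayes estimates, counts of observations and
#'   excluded BLQ records, and the updated model.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 40, seed = 1))
#' fit <- fit_hair_model(analysis_dataset(cohort, "ATV"), atv_model(),
#'                       se = FALSE)
#' fit$ofv
#' }
#' @export
fit_hair_model <- function(data, model, estimate = NULL, se = TRUE,
                           control = list(), quiet = TRUE) {
  stopifnot(inherits(model, "hair_model"))
  req <- c("subject", "conc")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("data lacks column ", miss[1], call. = FALSE)
  n_blq <- if (!is.null(data$blq)) sum(data$blq) else 0L
  if (n_blq > 0L) {
    data <- data[!data$blq, , drop = FALSE]
    if (!quiet) message("excluding ", n_blq, " BLQ record(s) (M1)")
  }
  if (nrow(data) == 0L) stop("no quantifiable observations", call. = FALSE)

  est <- estimate %||% model$estimated
  bad <- setdiff(est, names(model$params))
  if (length(bad)) stop("unknown parameter: ", bad[1], call. = FALSE)
  if (model$link == "population") {
    inert <- intersect(est, c("omega2_k12", "omega2_CL", "omega2_Vc"))
    if (length(inert)) {
      warning("dropping ", paste(inert, collapse = ", "),
              " from estimation: plasma IIV variances do not enter the ",
              "likelihood under the population-trough link", call. = FALSE)
      est <- setdiff(est, inert)
    }
  }
  if (length(est) == 0L) stop("no parameters to estimate", call. = FALSE)
  model$estimated <- est

  trans <- .par_transform(est)
  bounds <- .par_bounds(est)
  start_t <- .to_transformed(model$params[est], trans)
  obj <- function(par_t) {
    vals <- .from_transformed(par_t, trans)
    m <- set_params(model, stats::setNames(vals, est))
    out <- tryCatch(suppressWarnings(as.numeric(laplace_ofv(data, m))),
                    error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  ctl <- utils::modifyList(list(iter.max = 500, eval.max = 2000,
                                rel.tol = 1e-10), control)
  res <- stats::nlminb(start_t, obj, lower = bounds$lower,
                       upper = bounds$upper, control = ctl)
  # polish: restart from the optimum until the objective stabilises, so
  # nested-model comparisons are reliable at the dOFV ~ 0.01 level
  iters <- res$iterations
  last_gain <- Inf
  for (k in 1:2) {
    res2 <- stats::nlminb(res$par, obj, lower = bounds$lower,
                          upper = bounds$upper, control = ctl)
    iters <- iters + res2$iterations
    last_gain <- res$objective - res2$objective
    if (res2$objective <= res$objective) res <- res2
    if (last_gain < 1e-3) break
  }
  res$iterations <- iters
  # nlminb's "false"/"singular" codes at a stable optimum (common when a
  # coefficient starts exactly at a flat point) still count as converged
  converged <- res$convergence == 0 ||
    (grepl("false|singular", res$message) && last_gain < 0.01)
  final_vals <- .from_transformed(res$par, trans)
  model <- set_params(model, stats::setNames(final_vals, est))

  se_nat <- rep(NA_real_, length(est))
  if (se) {
    H <- tryCatch(pracma::hessian(obj, res$par), error = function(e) NULL)
    if (!is.null(H)) {
      cov_t <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) {
        warning("outer Hessian singular; using pseudo-inverse for SEs",
                call. = FALSE)
        2 * MASS::ginv((H + t(H)) / 2)
      })
      v <- diag(as.matrix(cov_t))
      se_t <- rep(NA_real_, length(v))
      se_t[v > 0] <- sqrt(v[v > 0])
      # delta method back to the natural scale for log-transformed terms
      se_nat <- ifelse(trans == "log", se_t * final_vals, se_t)
    }
  }
  all_names <- names(model$params)
  estimates <- tibble::tibble(
    parameter = all_names,
    estimate = unname(model$params),
    estimated = all_names %in% est,
    se = NA_real_, se_pct = NA_real_)
  estimates$se[match(est, all_names)] <- se_nat
  estimates$se_pct <- ifelse(
    estimates$estimated & abs(estimates$estimate) > 0,
    100 * estimates$se / abs(estimates$estimate), NA_real_)

  ebes <- tibble::tibble(subject = character(0), component = character(0),
                         eta = numeric(0))
  if (eta_structure(model)$ndim > 0L ||
      model$params[["omega2_frac_iov"]] > 0) {
    ebes <- dplyr::bind_rows(lapply(split(data, data$subject), function(sd_) {
      eb <- estimate_ebe(sd_, model)
      if (length(eb$eta) == 0L) return(NULL)
      tibble::tibble(subject = as.character(sd_$subject[1]),
                     component = names(eb$eta), eta = unname(eb$eta))
    }))
  }

  structure(list(model = model, estimates = estimates,
                 ofv = res$objective,
                 convergence = converged,
                 message = res$message,
                 iterations = res$iterations,
                 n_obs = nrow(data),
                 n_subjects = length(unique(data$subject)),
                 n_blq_excluded = n_blq,
                 ebes = ebes),
            class = "hairpk_fit")
}

#' @export
print.hairpk_fit <- function(x, ...) {
  cat(sprintf("<hairpk_fit> %s | OFV %.3f | %s (%d iterations)\n",
              x$model$analyte, x$ofv,
              if (x$convergence) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  %d observations, %d subjects, %d BLQ excluded\n",
              x$n_obs, x$n_subjects, x$n_blq_excluded))
  est <- x$estimates[x$estimates$estimated, ]
  for (i in seq_len(nrow(est)))
    cat(sprintf("    %-22s %9.4g%s\n", est$parameter[i], est$estimate[i],
                if (is.finite(est$se_pct[i]))
                  sprintf("  (SE %.0f%%)", est$se_pct[i]) else ""))
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Machine-readable record of a fit: estimates with SEs, OFV, convergence
#' status and data counts.
#'
#' @param fit A `hairpk_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hairpk_fit"))
  obj <- list(analyte = fit$model$analyte,
              ofv = fit$ofv,
              convergence = fit$convergence,
              n_obs = fit$n_obs,
              n_subjects = fit$n_subjects,
              n_blq_excluded = fit$n_blq_excluded,
              estimates = fit$estimates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
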