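# Goodness-of-fit computations: population and individual predictions,
# individually weighted residuals, and FOCE-linearised conditional
# weighted residuals, plus the standard four-panel plot.

#' Population predictions (random effects at zero)
#'
#' @param data Analysis dataset (quantifiable rows; BLQ rows dropped if
#'   flagged).
#' @param model A `hair_model` with fitted parameter values.
#' @return Numeric vector of per-record population predictions.
#' @export
population_predictions <- function(data, model) {
  if (!is.null(data$blq)) data <- data[!data$blq, , drop = FALSE]
  model_predict(model, data)
}

# per-subject empirical Bayes eta as a named vector, from a fit's ebes
# table or recomputed
.subject_eta <- function(sdata, model, ebes = NULL) {
  id <- as.character(sdata$subject[1])
  if (!is.null(ebes) && nrow(ebes)) {
    e <- ebes[ebes$subject == id, ]
    if (nrow(e)) return(stats::setNames(e$eta, e$component))
  }
  estimate_ebe(sdata, model)$eta
}

#' Individually weighted residuals
#'
#' `IWRES = (y - f(eta_hat)) / sd(f(eta_hat))`, the residual standardised
#' by the individual prediction's error SD.
#'
#' @inheritParams population_predictions
#' @param ebes Optional empirical Bayes estimates table (from a
#'   `hairpk_fit`); recomputed when absent.
#' @return Numeric vector of per-record IWRES, in `data` row order.
#' @export
iwres <- function(data, model, ebes = NULL) {
  if (!is.null(data$blq)) data <- data[!data$blq, , drop = FALSE]
  out <- numeric(nrow(data))
  for (sdata in split(seq_len(nrow(data)), data$subject)) {
    d <- data[sdata, , drop = FALSE]
    eta <- .subject_eta(d, model, ebes)
    f <- model_predict(model, d, eta = eta)
    s <- .resid_sd(f, residual_spec(model))
    if (any(s == 0)) stop("zero residual SD", call. = FALSE)
    out[sdata] <- (d$conc - f) / s
  }
  out
}

#' Conditional weighted residuals (FOCE linearisation)
#'
#' Per-subject decorrelated residual vector
#' \deqn{CWRES = V^{-1/2}\,(y - f(\hat\eta) + G\hat\eta),\qquad
#'   V = G\,\Omega\,G^\top + \mathrm{diag}(sd(f(\hat\eta))^2),}
#' with \eqn{G = \partial f/\partial\eta} at the conditional mode
#' (central finite differences) and the matrix square root taken by
#' symmetric eigendecomposition. With no random effects this reduces to
#' the weighted residual `(y - f)/sd`.
#'
#' @inheritParams iwres
#' @param fd_step Relative finite-difference step for the Jacobian.
#' @return Numeric vector of per-record CWRES, in `data` row order.
#' @export
cwres <- function(data, model, ebes = NULL, fd_step = 1e-5) {
  if (!is.null(data$blq)) data <- data[!data$blq, , drop = FALSE]
  out <- numeric(nrow(data))
  for (idx in split(seq_len(nrow(data)), data$subject)) {
    d <- data[idx, , drop = FALSE]
    es <- eta_structure(model, unique(d$occasion))
    if (es$ndim == 0L) {
      f <- model_predict(model, d)
      out[idx] <- (d$conc - f) / .resid_sd(f, residual_spec(model))
      next
    }
    eta <- .subject_eta(d, model, ebes)[es$names]
    f <- model_predict(model, d, eta = eta)
    sd2 <- .resid_sd(f, residual_spec(model))^2
    G <- matrix(0, nrow(d), es$ndim)
    for (j in seq_len(es$ndim)) {
      h <- fd_step * max(1, abs(eta[j]))
      ep <- em <- eta
      ep[j] <- ep[j] + h
      em[j] <- em[j] - h
      G[, j] <- (model_predict(model, d, eta = ep) -
                   model_predict(model, d, eta = em)) / (2 * h)
    }
    V <- G %*% diag(es$vars, es$ndim) %*% t(G) + diag(sd2, nrow(d))
    res <- d$conc - f + as.numeric(G %*% eta)
    out[idx] <- as.numeric(sym_inv_sqrt(V) %*% res)
  }
  out
}

#' Goodness-of-fit table
#'
#' One row per quantifiable observation with the population prediction
#' (PRED), individual prediction (IPRED), IWRES and CWRES.
#'
#' @param data Analysis dataset.
#' @param fit A `hairpk_fit` (or a `hair_model` with final values, in
#'   which case EBEs are recomputed).
#' @return Tibble: `subject`, `occasion`, `time_h`, `dv`, `pred`,
#'   `ipred`, `iwres`, `cwres`.
#' @export
gof_table <- function(data, fit) {
  model <- if (inherits(fit, "hairpk_fit")) fit$model else fit
  ebes <- if (inherits(fit, "hairpk_fit")) fit$ebes else NULL
  if (!is.null(data$blq)) data <- data[!data$blq, , drop = FALSE]
  ipred <- numeric(nrow(data))
  for (idx in split(seq_len(nrow(data)), data$subject)) {
    d <- data[idx, , drop = FALSE]
    ipred[idx] <- model_predict(model, d, eta = .subject_eta(d, model, ebes))
  }
  tibble::tibble(
    subject = as.character(data$subject),
    occasion = data$occasion %||% NA_character_,
    time_h = data$time_h %||% NA_real_,
    dv = data$conc,
    pred = population_predictions(data, model),
    ipred = ipred,
    iwres = iwres(data, model, ebes),
    cwres = cwres(data, model, ebes))
}

#' Four-panel goodness-of-fit plot
#'
#' Observations vs population predictions, observations vs individual
#' predictions, IWRES vs individual predictions, and CWRES vs time, each
#' with a LOESS smoother (dashed) and the identity or zero reference
#' line (solid).
#'
#' @param gof A tibble from [gof_table()].
#' @return A patchwork of four ggplots.
#' @export
plot_gof <- function(gof) {
  base <- function(p, x) {
    p <- p + ggplot2::geom_point(shape = 1) + ggplot2::theme_bw()
    # a smoother needs enough distinct abscissae (hair designs often have
    # only two sampling times)
    if (length(unique(x)) >= 5)
      p <- p + ggplot2::geom_smooth(method = "loess", formula = y ~ x,
                                    se = FALSE, linetype = "dashed",
                                    colour = "black")
    p
  }
  rng <- range(c(gof$dv, gof$pred, gof$ipred), finite = TRUE)
  p1 <- base(ggplot2::ggplot(gof, ggplot2::aes(.data$pred, .data$dv)), gof$pred) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::coord_cartesian(xlim = rng, ylim = rng) +
    ggplot2::labs(x = "Population prediction", y = "Observation")
  p2 <- base(ggplot2::ggplot(gof, ggplot2::aes(.data$ipred, .data$dv)), gof$ipred) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::coord_cartesian(xlim = rng, ylim = rng) +
    ggplot2::labs(x = "Individual prediction", y = "Observation")
  p3 <- base(ggplot2::ggplot(gof, ggplot2::aes(.data$ipred, .data$iwres)), gof$ipred) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Individual prediction", y = "IWRES")
  p4 <- base(ggplot2::ggplot(gof, ggplot2::aes(.data$time_h, .data$cwres)), gof$time_h) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Time (h)", y = "CWRES")
  patchwork::wrap_plots(p1, p2, p3, p4, ncol = 2)
}
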