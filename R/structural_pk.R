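#' Dosing regimen
#'
#' A repeated oral dosing schedule: dose amount, dosing interval and the
#' number of doses given before the observation of interest (or steady
#' state, the default, in which case the analytic superposition limit is
#' used wherever a multiple-dose quantity is needed).
#'
#' @param dose_amount Drug mass per dose (mg). Must be >= 0.
#' @param interval Dosing interval tau (h). Must be > 0.
#' @param n_doses Number of doses administered before observation, or
#'   `Inf` for steady state (default).
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(300, 24)   # 300 mg once daily, steady state
#' @export
dose_regimen <- function(dose_amount, interval = 24, n_doses = Inf) {
  stopifnot(is.numeric(dose_amount), length(dose_amount) == 1L,
            is.numeric(interval), length(interval) == 1L)
  if (dose_amount < 0) stop("dose_amount must be >= 0", call. = FALSE)
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  if (!(is.infinite(n_doses) || (n_doses >= 1 && n_doses == floor(n_doses))))
    stop("n_doses must be a positive integer or Inf", call. = FALSE)
  structure(list(dose_amount = dose_amount, interval = interval,
                 n_doses = n_doses),
            class = "dose_regimen")
}

#' Plasma disposition parameters
#'
#' One-compartment, first-order absorption parameters: absorption rate
#' constant `k12` (1/h), apparent clearance `CL` (CL/F, L/h) and apparent
#' central volume `Vc` (L). The elimination rate constant `k20 = CL/Vc`
#' is always derived, never stored independently.
#'
#' @param k12 First-order absorption rate constant (1/h).
#' @param CL Apparent clearance CL/F (L/h).
#' @param Vc Apparent central volume of distribution (L).
#' @return An object of class `plasma_params` with a derived `k20` field.
#' @examples
#' plasma_params(k12 = 0.44, CL = 10, Vc = 63.4)  # atazanavir defaults
#' @export
plasma_params <- function(k12, CL, Vc) {
  vals <- c(k12 = k12, CL = CL, Vc = Vc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("plasma parameters k12, CL, Vc must all be strictly positive",
         call. = FALSE)
  structure(list(k12 = k12, CL = CL, Vc = Vc, k20 = CL / Vc),
            class = "plasma_params")
}

#' Published plasma parameter sets
#'
#' Fixed literature values used for the plasma side of the joint model:
#' atazanavir k12 = 0.44/h, CL/F = 10 L/h, Vc = 63.4 L; ritonavir
#' k12 = 2.31/h, CL/F = 12.8 L/h, Vc = 105 L.
#'
#' @param analyte `"ATV"` or `"RTV"`.
#' @return A [plasma_params()] object.
#' @export
plasma_defaults <- function(analyte = c("ATV", "RTV")) {
  analyte <- match.arg(analyte)
  switch(analyte,
         ATV = plasma_params(k12 = 0.44, CL = 10, Vc = 63.4),
         RTV = plasma_params(k12 = 2.31, CL = 12.8, Vc = 105))
}

#' Hair compartment parameters
#'
#' The hair-to-plasma fraction `frac` (dimensionless ratio of the hair
#' concentration to the steady-state plasma trough) and the apparent hair
#' volume `Vh`, fixed to 1 unless explicitly overridden.
#'
#' @param frac Hair-to-plasma fraction, >= 0.
#' @param Vh Apparent hair volume, > 0 (default 1).
#' @return An object of class `hair_params`.
#' @export
hair_params <- function(frac, Vh = 1) {
  stopifnot(is.numeric(frac), length(frac) == 1L, is.numeric(Vh))
  if (!is.finite(frac) || frac < 0) stop("frac must be >= 0", call. = FALSE)
  if (!is.finite(Vh) || Vh <= 0) stop("Vh must be > 0", call. = FALSE)
  structure(list(frac = frac, Vh = Vh), class = "hair_params")
}

# tolerance below which |k12 - k20| triggers the degenerate Bateman limit
.BATEMAN_TOL <- 1e-8

#' Single-dose plasma concentration (Bateman function)
#'
#' Closed-form plasma concentration after one oral dose under first-order
#' absorption and elimination:
#' \deqn{C(t) = \frac{D}{V_c}\,\frac{k_{12}}{k_{12}-k_{20}}
#'   \left(e^{-k_{20} t} - e^{-k_{12} t}\right).}
#' When `|k12 - k20|` falls below an internal tolerance the analytic limit
#' \eqn{(D/V_c)\,k\,t\,e^{-kt}} is used instead.
#'
#' @param t Time since dose (h), vectorised, all >= 0.
#' @param regimen A [dose_regimen()]; only `dose_amount` is used.
#' @param p A [plasma_params()].
#' @return Plasma concentration (mg/L), same length as `t`.
#' @examples
#' bateman_concentration(24, dose_regimen(300), plasma_defaults("ATV"))
#' @export
bateman_concentration <- function(t, regimen, p) {
  stopifnot(inherits(regimen, "dose_regimen"), inherits(p, "plasma_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  D <- regimen$dose_amount
  k12 <- p$k12; k20 <- p$k20
  if (abs(k12 - k20) < .BATEMAN_TOL) {
    k <- (k12 + k20) / 2
    (D / p$Vc) * k * t * exp(-k * t)
  } else {
    (D / p$Vc) * k12 / (k12 - k20) * (exp(-k20 * t) - exp(-k12 * t))
  }
}

# Vectorised steady-state trough on raw parameter values (internal).
# Superposition limit of the Bateman curve at t = tau:
#   (D/Vc) * k12/(k12-k20) * [E20/(1-E20) - E12/(1-E12)],  E = exp(-k tau)
.trough_value <- function(D, tau, k12, CL, Vc) {
  k20 <- CL / Vc
  deg <- abs(k12 - k20) < .BATEMAN_TOL
  out <- numeric(length(k20))
  if (any(!deg)) {
    E12 <- exp(-k12[!deg] * tau)
    E20 <- exp(-k20[!deg] * tau)
    out[!deg] <- (D / Vc[!deg]) * k12[!deg] / (k12[!deg] - k20[!deg]) *
      (E20 / (1 - E20) - E12 / (1 - E12))
  }
  if (any(deg)) {
    k <- (k12[deg] + k20[deg]) / 2
    r <- exp(-k * tau)
    # sum_m (D/Vc) k (tau + m tau) e^{-k(tau + m tau)}
    out[deg] <- (D / Vc[deg]) * k * exp(-k * tau) *
      (tau / (1 - r) + tau * r / (1 - r)^2)
  }
  out
}

#' Steady-state plasma trough concentration
#'
#' Trough (pre-dose) plasma concentration at `t = interval` after a dose
#' under repeated dosing. For a steady-state regimen the analytic
#' superposition closed form is returned; for a finite `n_doses` the
#' finite superposition sum is used.
#'
#' @inheritParams bateman_concentration
#' @return Trough plasma concentration (mg/L).
#' @examples
#' steady_state_trough(dose_regimen(300, 24), plasma_defaults("ATV"))
#' @export
steady_state_trough <- function(regimen, p) {
  stopifnot(inherits(regimen, "dose_regimen"), inherits(p, "plasma_params"))
  D <- regimen$dose_amount; tau <- regimen$interval
  if (D == 0) return(0)
  if (is.infinite(regimen$n_doses)) {
    .trough_value(D, tau, p$k12, p$CL, p$Vc)
  } else {
    # finite superposition: doses at 0, tau, ..., (n-1) tau, observed at n tau
    tt <- tau * seq_len(regimen$n_doses)
    sum(bateman_concentration(tt, regimen, p))
  }
}

#' Integrate the depot-central-hair compartment system
#'
#' Numerically integrates
#' \deqn{dA_1/dt = -k_{12} A_1,\quad
#'       dA_2/dt = k_{12} A_1 - k_{20} A_2,\quad
#'       dA_3/dt = F_{rac}\,k_{20}\,A_2,}
#' with doses applied as instantaneous bolus additions to the depot
#' compartment at multiples of the dosing interval. Returns the compartment
#' amounts, the plasma concentration `C2 = A2/Vc`, and the hair-scale
#' prediction `C_hair = A3/Vh`.
#'
#' @inheritParams bateman_concentration
#' @param h A [hair_params()].
#' @param t_grid Sorted, non-negative time grid (h). Doses are given at
#'   `0, interval, ...` up to `n_doses` (1 dose if `n_doses` is `Inf`,
#'   since an infinite schedule cannot be integrated; use
#'   [steady_state_trough()] for steady-state quantities).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A tibble with columns `time`, `A1`, `A2`, `A3`, `C2`, `C_hair`.
#' @export
integrate_system <- function(regimen, p, h, t_grid,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(regimen, "dose_regimen"), inherits(p, "plasma_params"),
            inherits(h, "hair_params"))
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("t_grid must be sorted and non-negative", call. = FALSE)
  n_doses <- if (is.infinite(regimen$n_doses)) 1L else regimen$n_doses
  dose_times <- regimen$interval * (seq_len(n_doses) - 1L)
  dose_times <- dose_times[dose_times <= max(t_grid)]
  times <- sort(unique(c(t_grid, dose_times)))
  rhs <- function(t, A, pars) {
    list(c(-p$k12 * A[1],
           p$k12 * A[1] - p$k20 * A[2],
           h$frac * p$k20 * A[2]))
  }
  # the dose at t = 0 goes into the initial condition; later doses are
  # instantaneous additions to the depot via solver events
  y0 <- c(A1 = if (0 %in% dose_times) regimen$dose_amount else 0,
          A2 = 0, A3 = 0)
  later <- dose_times[dose_times > 0]
  ev <- if (length(later))
    list(data = data.frame(var = "A1", time = later,
                           value = regimen$dose_amount, method = "add"))
  else NULL
  sol <- try(deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol, events = ev),
             silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol)))
    stop("ODE integration failed: ", attr(sol, "condition")$message,
         call. = FALSE)
  sol <- as.data.frame(sol)
  sol <- sol[sol$time %in% t_grid, , drop = FALSE]
  tibble::tibble(time = sol$time, A1 = sol$A1, A2 = sol$A2, A3 = sol$A3,
                 C2 = sol$A2 / p$Vc, C_hair = sol$A3 / h$Vh)
}

#' Hair-scale prediction from an individual fraction and a plasma trough
#'
#' The structural hair observation model: the predicted hair concentration
#' is the individual hair-to-plasma fraction times the steady-state plasma
#' trough, divided by the apparent hair volume (fixed to 1 by default).
#'
#' @param frac_i Individual hair-to-plasma fraction (>= 0), vectorised.
#' @param trough Steady-state plasma trough, in the model's internal
#'   concentration unit (>= 0), vectorised.
#' @param h A [hair_params()]; only `Vh` is used.
#' @return `frac_i * trough / Vh`.
#' @export
predict_hair <- function(frac_i, trough, h = hair_params(0, 1)) {
  stopifnot(inherits(h, "hair_params"))
  if (any(frac_i < 0) || any(trough < 0))
    stop("frac_i and trough must be >= 0", call. = FALSE)
  frac_i * trough / h$Vh
}
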