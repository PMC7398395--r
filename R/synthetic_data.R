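#' Specification of a virtual cohort
#'
#' Defines the statistical structure of a simulated adolescent cohort on
#' once-daily boosted atazanavir with hair sampling at two occasions:
#' covariate distributions, occasion days, analytes with their generating
#' models, and assay quantification limits. The defaults emulate the
#' source study's cohort: n = 50 subjects, 54\% female, BMI-for-age
#' normal/thin/overweight at the published 54/30/15 percentages
#' (renormalised to sum to one), caregiver grandparent/parent/uncle-aunt/
#' sibling at 40/20/30/10\%, adherence VAS normal with mean 84.2 and SD
#' 18.1 truncated to 30-100, hair sampling at days 0 (enrolment) and
#' 90 (follow-up), and assay ranges 0.05-20.0 ng/mg (ATV) and
#' 0.01-4.0 ng/mg (RTV). Body weight is not reported by the study and is
#' generated log-normally (median 50 kg, CV 20\%, bounds 25-90 kg) as a
#' plausible adolescent distribution.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @param occasion_days Named vector of sampling days,
#'   default `c(enrolment = 0, followup = 90)`.
#' @param analytes Analyte subset of `c("ATV", "RTV")`.
#' @param truth Named list of generating [hair_model()]s per analyte
#'   (defaults: the published final models).
#' @param sex_female Proportion female.
#' @param bmi_prop Named proportions for `normal`, `thin`, `overweight`
#'   (must sum to 1 after normalisation).
#' @param caregiver_prop Named proportions for `grandparent`, `parent`,
#'   `uncle_aunt`, `sibling`.
#' @param adherence List: `mean`, `sd`, `bounds` (truncation range) and
#'   `per_occasion` (draw a fresh score per occasion; default FALSE, a
#'   single score shared across occasions).
#' @param weight List: `median`, `cv`, `bounds` for the log-normal body
#'   weight distribution.
#' @param lloq,uloq Named lower/upper limits of quantification per analyte
#'   (ng/mg).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 50,
                        seed = 1L,
                        occasion_days = c(enrolment = 0, followup = 90),
                        analytes = c("ATV", "RTV"),
                        truth = list(ATV = atv_model(), RTV = rtv_model()),
                        sex_female = 0.54,
                        bmi_prop = c(normal = 54, thin = 30,
                                     overweight = 15) / 99,
                        caregiver_prop = c(grandparent = 0.40, parent = 0.20,
                                           uncle_aunt = 0.30, sibling = 0.10),
                        adherence = list(mean = 84.2, sd = 18.1,
                                         bounds = c(30, 100),
                                         per_occasion = FALSE),
                        weight = list(median = 50, cv = 0.20,
                                      bounds = c(25, 90)),
                        lloq = c(ATV = 0.05, RTV = 0.01),
                        uloq = c(ATV = 20.0, RTV = 4.0)) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(occasion_days) < 1 || anyDuplicated(occasion_days))
    stop("occasion days must be distinct", call. = FALSE)
  analytes <- match.arg(analytes, c("ATV", "RTV"), several.ok = TRUE)
  norm1 <- function(p, what) {
    if (any(p < 0)) stop(what, " proportions must be >= 0", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-6) p <- p / sum(p)
    p
  }
  bmi_prop <- norm1(bmi_prop[c("normal", "thin", "overweight")], "bmi")
  caregiver_prop <- norm1(caregiver_prop[c("grandparent", "parent",
                                           "uncle_aunt", "sibling")],
                          "caregiver")
  for (a in analytes) {
    if (is.null(truth[[a]])) stop("no truth model for ", a, call. = FALSE)
    if (!(lloq[[a]] > 0) || !(lloq[[a]] < uloq[[a]]))
      stop("need 0 < lloq < uloq for ", a, call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, seed = seed,
                 occasion_days = occasion_days, analytes = analytes,
                 truth = truth, sex_female = sex_female,
                 bmi_prop = bmi_prop, caregiver_prop = caregiver_prop,
                 adherence = adherence, weight = weight,
                 lloq = lloq, uloq = uloq),
            class = "cohort_spec")
}

#' Simulate a virtual cohort
#'
#' Draws subject covariates from the spec's distributions, realises
#' individual parameters (random effects are drawn per subject for every
#' eta the generating model carries), simulates hair concentrations under
#' the combined residual-error model, and flags below-quantification
#' records against the assay LLOQ. Deterministic under the seed.
#'
#' Simulated concentrations below the LLOQ are *flagged*, not masked:
#' the pre-censoring value stays in the `conc` column so that calibration
#' tests can reach it; [export_dataset()] masks it on export.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return An object of class `hairpk_cohort`: a list with `covariates`
#'   (one row per subject x occasion) and `observations` (one row per
#'   subject x occasion x analyte: `subject`, `occasion`, `time_h`,
#'   `analyte`, `conc`, `blq`, `lloq`).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 10, seed = 7))
#' head(cohort$observations)
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_preserved_seed(seed, {
    n <- spec$n_subjects
    ids <- sprintf("S%03d", seq_len(n))
    sex <- ifelse(stats::runif(n) < spec$sex_female, "female", "male")
    bmi <- sample(names(spec$bmi_prop), n, replace = TRUE,
                  prob = spec$bmi_prop)
    cg <- sample(names(spec$caregiver_prop), n, replace = TRUE,
                 prob = spec$caregiver_prop)
    wlog <- rtruncnorm(n, mean = log(spec$weight$median),
                       sd = sqrt(log(1 + spec$weight$cv^2)),
                       lower = log(spec$weight$bounds[1]),
                       upper = log(spec$weight$bounds[2]))
    weight <- exp(wlog)
    occ_names <- names(spec$occasion_days)
    n_occ <- length(occ_names)
    vas_draw <- function(k) rtruncnorm(k, spec$adherence$mean,
                                       spec$adherence$sd,
                                       spec$adherence$bounds[1],
                                       spec$adherence$bounds[2])
    if (isTRUE(spec$adherence$per_occasion)) {
      vas <- vas_draw(n * n_occ)
    } else {
      vas <- rep(vas_draw(n), each = n_occ)
    }
    covariates <- tibble::tibble(
      subject = rep(ids, each = n_occ),
      occasion = rep(occ_names, times = n),
      time_h = rep(unname(spec$occasion_days) * 24, times = n),
      sex = rep(sex, each = n_occ),
      weight = rep(weight, each = n_occ),
      bmi = rep(bmi, each = n_occ),
      caregiver = rep(cg, each = n_occ),
      adherence_vas = vas)

    obs <- list()
    for (a in spec$analytes) {
      m <- spec$truth[[a]]
      # one eta draw per subject for each component the model carries;
      # inert components are drawn too, so the stream is link-independent
      eta_tab <- matrix(stats::rnorm(n * 3), nrow = n) %*%
        diag(sqrt(pmax(m$params[c("omega2_k12", "omega2_CL",
                                  "omega2_Vc")], 0)))
      colnames(eta_tab) <- c("k12", "CL", "Vc")
      iov_tab <- if (m$params[["omega2_frac_iov"]] > 0)
        matrix(stats::rnorm(n * n_occ, 0,
                            sqrt(m$params[["omega2_frac_iov"]])),
               nrow = n)
      else matrix(0, nrow = n, ncol = n_occ)
      if (m$link == "population" && m$params[["omega2_frac_iov"]] == 0) {
        f <- predict_f(m, covariates)   # etas do not enter the prediction
      } else {
        f <- numeric(nrow(covariates))
        for (i in seq_len(n)) {
          rows <- which(covariates$subject == ids[i])
          eta <- stats::setNames(c(eta_tab[i, ], iov_tab[i, ]),
                                 c("k12", "CL", "Vc",
                                   paste0("iov_", occ_names)))
          f[rows] <- predict_f(m, covariates[rows, ], eta = eta)
        }
      }
      y <- f * (1 + stats::rnorm(length(f), 0, m$params[["sd_prop"]])) +
        stats::rnorm(length(f), 0, m$params[["sd_add"]])
      obs[[a]] <- tibble::tibble(
        subject = covariates$subject,
        occasion = covariates$occasion,
        time_h = covariates$time_h,
        analyte = a,
        conc = y,
        blq = FALSE,
        lloq = unname(spec$lloq[[a]]))
    }
    observations <- dplyr::bind_rows(obs)
    observations <- apply_blq(observations)
    n_above <- sum(observations$conc >
                     spec$uloq[observations$analyte], na.rm = TRUE)
    structure(list(covariates = covariates, observations = observations,
                   spec = spec, seed = seed, n_above_uloq = n_above),
              class = "hairpk_cohort")
  })
}

#' Flag below-quantification records
#'
#' Marks records with concentration strictly below the analyte's LLOQ as
#' BLQ (a value exactly at the limit is quantifiable: closed lower
#' bound). Concentrations are left in place - masking happens on export.
#'
#' @param observations Observation table with `analyte`, `conc` and
#'   either a `lloq` column or none.
#' @param lloq Optional named vector of LLOQs per analyte, overriding the
#'   table's `lloq` column.
#' @return The observation table with an updated `blq` column and an
#'   attribute `"blq_summary"`: a tibble of BLQ counts per analyte.
#' @export
apply_blq <- function(observations, lloq = NULL) {
  if (nrow(observations) == 0L) {
    out <- observations
    out$blq <- logical(0)
    attr(out, "blq_summary") <- tibble::tibble(analyte = character(0),
                                               n = integer(0),
                                               n_blq = integer(0))
    return(out)
  }
  lim <- if (!is.null(lloq)) {
    if (any(lloq <= 0)) stop("lloq must be > 0", call. = FALSE)
    unname(lloq[observations$analyte])
  } else observations$lloq
  if (is.null(lim) || any(!is.finite(lim)))
    stop("no LLOQ available for some records", call. = FALSE)
  observations$blq <- observations$conc < lim
  if (!is.null(lloq)) observations$lloq <- lim
  sm <- dplyr::summarise(dplyr::group_by(observations, .data$analyte),
                         n = dplyr::n(), n_blq = sum(.data$blq),
                         .groups = "drop")
  attr(observations, "blq_summary") <- sm
  observations
}

#' Analysis-ready dataset for one analyte
#'
#' Joins the cohort's per-occasion covariates onto the observation rows of
#' one analyte, producing the long-format table the fitting functions
#' consume.
#'
#' @param cohort A `hairpk_cohort` (or a list with `covariates` and
#'   `observations` in the same layout).
#' @param analyte `"ATV"` or `"RTV"`.
#' @return Tibble with one row per observation: `subject`, `occasion`,
#'   `time_h`, `conc`, `blq`, `lloq`, `weight`, `bmi`, `caregiver`,
#'   `adherence_vas`.
#' @export
analysis_dataset <- function(cohort, analyte) {
  obs <- cohort$observations[cohort$observations$analyte == analyte, ]
  if (nrow(obs) == 0L) stop("no observations for ", analyte, call. = FALSE)
  dplyr::inner_join(
    obs[, c("subject", "occasion", "time_h", "conc", "blq", "lloq")],
    cohort$covariates[, c("subject", "occasion", "weight", "bmi",
                          "caregiver", "adherence_vas")],
    by = c("subject", "occasion"))
}
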