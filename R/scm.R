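# Stepwise covariate model building on the hair fraction: forward
# inclusion by a likelihood-ratio criterion at alpha = 0.05, then backward
# elimination at alpha = 0.01, mirroring the PsN SCM procedure (single
# best candidate accepted per forward round).

.RELATION_DF <- c(occasion = 1L, adherence = 1L, bmi = 2L, caregiver = 3L)
.RELATION_BETAS <- list(
  occasion = "beta_occasion",
  adherence = "beta_adherence",
  bmi = c("beta_bmi_thin", "beta_bmi_overweight"),
  caregiver = c("beta_cg_parent", "beta_cg_uncle_aunt", "beta_cg_sibling"))

#' Candidate covariate-fraction relations
#'
#' The default candidate set for stepwise selection: occasion (1 df),
#' adherence score (1 df), BMI-for-age (2 df: thin, overweight vs
#' normal), caregiver (3 df: parent, uncle/aunt, sibling vs grandparent).
#'
#' @param names Subset of relation names to include.
#' @return Tibble with columns `relation` and `df`.
#' @export
candidate_relations <- function(names = c("occasion", "adherence", "bmi",
                                          "caregiver")) {
  if (length(names) == 0L)
    return(tibble::tibble(relation = character(0), df = integer(0)))
  names <- match.arg(names, names(.RELATION_DF), several.ok = TRUE)
  tibble::tibble(relation = names, df = unname(.RELATION_DF[names]))
}

#' Delta-OFV acceptance threshold
#'
#' Chi-square quantile at the phase's significance level (0.05 forward,
#' 0.01 backward) matched to the relation's degrees of freedom. The
#' `"fixed"` mode reproduces the conventional 1-df constants 3.83
#' (forward) and 6.64 (backward) regardless of df.
#'
#' @param df Degrees of freedom added/removed by the relation.
#' @param phase `"forward"` or `"backward"`.
#' @param mode `"chisq"` (default) or `"fixed"`.
#' @return The threshold (scalar).
#' @export
scm_threshold <- function(df, phase = c("forward", "backward"),
                          mode = c("chisq", "fixed")) {
  phase <- match.arg(phase)
  mode <- match.arg(mode)
  if (mode == "fixed") return(if (phase == "forward") 3.83 else 6.64)
  alpha <- if (phase == "forward") 0.05 else 0.01
  stats::qchisq(1 - alpha, df)
}

# add/remove a relation; new coefficients start at 0
.add_relation <- function(model, relation) {
  model$covariates <- union(model$covariates, relation)
  betas <- .RELATION_BETAS[[relation]]
  model <- set_params(model, stats::setNames(rep(0, length(betas)), betas))
  model$estimated <- union(model$estimated, betas)
  model
}

.drop_relation <- function(model, relation) {
  model$covariates <- setdiff(model$covariates, relation)
  betas <- .RELATION_BETAS[[relation]]
  model <- set_params(model, stats::setNames(rep(0, length(betas)), betas))
  model$estimated <- setdiff(model$estimated, betas)
  model
}

.fit_quietly <- function(data, model, control) {
  tryCatch(fit_hair_model(data, model, se = FALSE, control = control),
           error = function(e) NULL)
}

#' One forward-selection step
#'
#' Fits the current model extended by each candidate relation and accepts
#' the candidate with the largest OFV drop among those exceeding the
#' df-matched threshold. Ties are broken by fewer df, then by
#' lexicographic relation name. Candidates whose fit fails are skipped
#' with a message.
#'
#' @param model Current `hair_model` (also provides starting values).
#' @param candidates Tibble from [candidate_relations()]; relations
#'   already in the model are ignored.
#' @param data Analysis dataset (see [fit_hair_model()]).
#' @param threshold_mode Passed to [scm_threshold()].
#' @param control Optimiser control for the candidate fits.
#' @param base_fit Optional pre-computed fit of `model` on `data`.
#' @return List: `accepted` (relation name or `NULL`), `model` (updated
#'   if accepted), `fit` (the accepted fit or the base fit), and `steps`,
#'   a tibble with one row per candidate tried.
#' @export
forward_step <- function(model, candidates, data,
                         threshold_mode = "chisq", control = list(),
                         base_fit = NULL) {
  cand <- candidates[!(candidates$relation %in% model$covariates), ]
  if (nrow(cand) == 0L)
    return(list(accepted = NULL, model = model, fit = base_fit,
                steps = tibble::tibble()))
  if (is.null(base_fit)) base_fit <- fit_hair_model(data, model, se = FALSE,
                                                    control = control)
  rows <- list(); fits <- list()
  for (i in seq_len(nrow(cand))) {
    rel <- cand$relation[i]; df <- cand$df[i]
    thr <- scm_threshold(df, "forward", threshold_mode)
    fit_i <- .fit_quietly(data, .add_relation(base_fit$model, rel), control)
    if (is.null(fit_i) || !fit_i$convergence) {
      message("forward: candidate '", rel, "' skipped (fit failed)")
      rows[[i]] <- tibble::tibble(relation = rel, df = df,
                                  ofv = NA_real_, dofv = NA_real_,
                                  threshold = thr, decision = "skipped")
      next
    }
    fits[[rel]] <- fit_i
    dofv <- base_fit$ofv - fit_i$ofv
    rows[[i]] <- tibble::tibble(relation = rel, df = df, ofv = fit_i$ofv,
                                dofv = dofv, threshold = thr,
                                decision = ifelse(dofv > thr, "significant",
                                                  "not significant"))
  }
  steps <- dplyr::bind_rows(rows)
  ok <- steps[!is.na(steps$dofv) & steps$dofv > steps$threshold, ]
  if (nrow(ok) == 0L)
    return(list(accepted = NULL, model = model, fit = base_fit,
                steps = steps))
  ok <- ok[order(-ok$dofv, ok$df, ok$relation), ]
  best <- ok$relation[1]
  steps$decision[steps$relation == best] <- "accepted"
  list(accepted = best, model = fits[[best]]$model, fit = fits[[best]],
       steps = steps)
}

#' One backward-elimination step
#'
#' Refits the current model with each included relation removed. A
#' relation is retained only if its removal worsens the OFV by more than
#' the df-matched backward threshold; among relations below threshold,
#' the one whose removal costs least is eliminated.
#'
#' @inheritParams forward_step
#' @param relations Relations eligible for removal (default: all included
#'   covariates).
#' @return List: `removed` (relation name or `NULL`), `model`, `fit`, and
#'   `steps` as in [forward_step()].
#' @export
backward_step <- function(model, data, relations = model$covariates,
                          threshold_mode = "chisq", control = list(),
                          base_fit = NULL) {
  if (length(relations) == 0L)
    return(list(removed = NULL, model = model, fit = base_fit,
                steps = tibble::tibble()))
  if (is.null(base_fit)) base_fit <- fit_hair_model(data, model, se = FALSE,
                                                    control = control)
  rows <- list(); fits <- list()
  for (rel in relations) {
    df <- .RELATION_DF[[rel]]
    thr <- scm_threshold(df, "backward", threshold_mode)
    fit_i <- .fit_quietly(data, .drop_relation(base_fit$model, rel), control)
    if (is.null(fit_i) || !fit_i$convergence) {
      message("backward: removal of '", rel, "' skipped (fit failed)")
      rows[[rel]] <- tibble::tibble(relation = rel, df = df,
                                    ofv = NA_real_, dofv = NA_real_,
                                    threshold = thr, decision = "skipped")
      next
    }
    fits[[rel]] <- fit_i
    dofv <- fit_i$ofv - base_fit$ofv    # cost of removal
    rows[[rel]] <- tibble::tibble(relation = rel, df = df, ofv = fit_i$ofv,
                                  dofv = dofv, threshold = thr,
                                  decision = ifelse(dofv > thr, "retained",
                                                    "removable"))
  }
  steps <- dplyr::bind_rows(rows)
  cand <- steps[!is.na(steps$dofv) & steps$dofv <= steps$threshold, ]
  if (nrow(cand) == 0L)
    return(list(removed = NULL, model = model, fit = base_fit,
                steps = steps))
  cand <- cand[order(cand$dofv, cand$df, cand$relation), ]
  worst <- cand$relation[1]
  steps$decision[steps$relation == worst] <- "removed"
  list(removed = worst, model = fits[[worst]]$model, fit = fits[[worst]],
       steps = steps)
}

#' Run the full stepwise covariate procedure
#'
#' Forward inclusion until no candidate passes, then backward elimination
#' until every remaining relation survives the stricter criterion.
#' Returns the final model with a full audit trail.
#'
#' @inheritParams forward_step
#' @return An object of class `hairpk_scm`: `final_model`, `final_fit`,
#'   and `trace`, a tibble with one row per candidate evaluation
#'   (`phase`, `step`, `relation`, `df`, `ofv`, `dofv`, `threshold`,
#'   `decision`, `cumulative_df`).
#' @export
run_scm <- function(model, candidates, data, threshold_mode = "chisq",
                    control = list()) {
  stopifnot(inherits(model, "hair_model"))
  fit <- fit_hair_model(data, model, se = FALSE, control = control)
  if (!fit$convergence)
    warning("base model fit did not formally converge", call. = FALSE)
  trace <- list()
  step_no <- 0L
  cum_df <- 0L
  repeat {
    step_no <- step_no + 1L
    fw <- forward_step(fit$model, candidates, data,
                       threshold_mode = threshold_mode, control = control,
                       base_fit = fit)
    if (nrow(fw$steps %||% tibble::tibble()) > 0L)
      trace[[length(trace) + 1L]] <-
        dplyr::mutate(fw$steps, phase = "forward", step = step_no,
                      .before = 1)
    if (is.null(fw$accepted)) break
    cum_df <- cum_df + .RELATION_DF[[fw$accepted]]
    fit <- fw$fit
  }
  repeat {
    step_no <- step_no + 1L
    bw <- backward_step(fit$model, data, threshold_mode = threshold_mode,
                        control = control, base_fit = fit)
    if (nrow(bw$steps %||% tibble::tibble()) > 0L)
      trace[[length(trace) + 1L]] <-
        dplyr::mutate(bw$steps, phase = "backward", step = step_no,
                      .before = 1)
    if (is.null(bw$removed)) break
    cum_df <- cum_df - .RELATION_DF[[bw$removed]]
    fit <- bw$fit
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(phase = character(0), step = integer(0),
                   relation = character(0), df = integer(0),
                   ofv = numeric(0), dofv = numeric(0),
                   threshold = numeric(0), decision = character(0))
  # cumulative df of accepted relations after each row's step
  acc <- 0L
  cdf <- integer(nrow(trace))
  if (nrow(trace)) {
    for (i in seq_len(nrow(trace))) {
      if (trace$decision[i] == "accepted")
        acc <- acc + trace$df[i]
      if (trace$decision[i] == "removed")
        acc <- acc - trace$df[i]
      cdf[i] <- acc
    }
  }
  trace$cumulative_df <- cdf
  structure(list(final_model = fit$model, final_fit = fit, trace = trace),
            class = "hairpk_scm")
}

#' Write an SCM audit trail as a tab-separated file
#'
#' @param scm A `hairpk_scm` (or its `trace` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scm_trace <- function(scm, path) {
  trace <- if (inherits(scm, "hairpk_scm")) scm$trace else scm
  utils::write.table(trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.hairpk_scm <- function(x, ...) {
  cat("<hairpk_scm> final covariates:",
      if (length(x$final_model$covariates))
        paste(x$final_model$covariates, collapse = ", ") else "(none)",
      sprintf("| final OFV %.3f\n", x$final_fit$ofv))
  print(x$trace, n = 50)
  invisible(x)
}
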