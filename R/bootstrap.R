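# Nonparametric bootstrap of a fitted model: resample subjects with
# replacement, refit each resample starting from the original estimates,
# and summarise with medians and 90% percentile confidence intervals.

#' Resample subjects with replacement
#'
#' Draws `n` subjects (the original count) with replacement and
#' re-identifies them uniquely, so a subject drawn twice appears as two
#' distinct subjects; all rows (occasions) of a drawn subject travel
#' together. Optionally stratifies on each subject's number of occasions.
#'
#' @param data Long-format dataset with a `subject` column.
#' @param seed Optional integer seed for a reproducible draw.
#' @param stratify_by_occasions Resample within strata defined by each
#'   subject's occasion count (default FALSE, unstratified).
#' @return The resampled dataset, with new subject ids `B001...` and an
#'   attribute `"source_subject"` mapping new ids to originals.
#' @export
resample_subjects <- function(data, seed = NULL,
                              stratify_by_occasions = FALSE) {
  ids <- unique(data$subject)
  if (length(ids) < 2L) stop("need at least 2 subjects", call. = FALSE)
  draw <- function() {
    if (stratify_by_occasions) {
      n_occ <- vapply(split(data$occasion %||% rep(1, nrow(data)),
                            data$subject)[ids],
                      function(x) length(unique(x)), integer(1))
      unlist(lapply(split(ids, n_occ), function(g)
        sample(g, length(g), replace = TRUE)), use.names = FALSE)
    } else {
      sample(ids, length(ids), replace = TRUE)
    }
  }
  chosen <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
  pieces <- lapply(seq_along(chosen), function(k) {
    d <- data[data$subject == chosen[k], , drop = FALSE]
    d$subject <- sprintf("B%03d", k)
    d
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "source_subject") <- stats::setNames(chosen,
                                                 sprintf("B%03d",
                                                         seq_along(chosen)))
  out
}

#' Nonparametric bootstrap of a final model
#'
#' Refits the model to `n_resamples` subject-level resamples (each fit
#' warm-started from the supplied model's estimates, the PsN convention)
#' and summarises every estimated parameter by its median and the 5th and
#' 95th percentiles (type-7 quantiles), computed over converged resamples
#' only. A result with more than 50\% non-converged resamples is flagged
#' unreliable.
#'
#' @param data Analysis dataset (see [fit_hair_model()]).
#' @param model A `hair_model` already fitted to `data` (its parameter
#'   values are the refit starting points).
#' @param n_resamples Number of bootstrap resamples (paper-scale default
#'   1000).
#' @param seed Integer seed governing the whole resampling plan.
#' @param stratify_by_occasions Passed to [resample_subjects()].
#' @param control Optimiser control for the refits.
#' @return An object of class `hairpk_bootstrap`: `estimates` (one row
#'   per resample with a `converged` flag), `summary` (parameter, median,
#'   `q05`, `q95`), `n_converged`, `n_resamples`, `unreliable`.
#' @export
run_bootstrap <- function(data, model, n_resamples = 1000, seed = 1L,
                          stratify_by_occasions = FALSE, control = list()) {
  stopifnot(inherits(model, "hair_model"), n_resamples >= 1)
  est_names <- model$estimated
  rows <- vector("list", n_resamples)
  sub_seeds <- with_preserved_seed(seed,
                                   sample.int(.Machine$integer.max - 1L,
                                              n_resamples))
  for (b in seq_len(n_resamples)) {
    bdata <- resample_subjects(data, seed = sub_seeds[b],
                               stratify_by_occasions = stratify_by_occasions)
    fit_b <- tryCatch(fit_hair_model(bdata, model, se = FALSE,
                                     control = control),
                      error = function(e) NULL)
    est <- if (is.null(fit_b)) {
      stats::setNames(rep(NA_real_, length(est_names)), est_names)
    } else fit_b$model$params[est_names]
    rows[[b]] <- tibble::tibble(
      resample = b,
      converged = !is.null(fit_b) && fit_b$convergence,
      !!!stats::setNames(as.list(unname(est)), est_names))
  }
  estimates <- dplyr::bind_rows(rows)
  ok <- estimates[estimates$converged, , drop = FALSE]
  summary <- dplyr::bind_rows(lapply(est_names, function(p) {
    v <- ok[[p]]
    tibble::tibble(parameter = p,
                   median = stats::median(v),
                   q05 = stats::quantile(v, 0.05, names = FALSE, type = 7),
                   q95 = stats::quantile(v, 0.95, names = FALSE, type = 7))
  }))
  unreliable <- nrow(ok) < n_resamples / 2
  if (unreliable)
    warning("more than half of the bootstrap refits failed to converge; ",
            "result flagged unreliable", call. = FALSE)
  structure(list(estimates = estimates, summary = summary,
                 n_converged = nrow(ok), n_resamples = n_resamples,
                 seed = seed, unreliable = unreliable),
            class = "hairpk_bootstrap")
}

#' Write per-resample bootstrap estimates as CSV
#'
#' One row per resample, including the convergence flag.
#'
#' @param boot A `hairpk_bootstrap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_csv <- function(boot, path) {
  stopifnot(inherits(boot, "hairpk_bootstrap"))
  utils::write.csv(boot$estimates, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.hairpk_bootstrap <- function(x, ...) {
  cat(sprintf("<hairpk_bootstrap> %d resamples (%d converged%s)\n",
              x$n_resamples, x$n_converged,
              if (x$unreliable) ", UNRELIABLE" else ""))
  print(x$summary)
  invisible(x)
}
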