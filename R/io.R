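# Dataset export/import: a single long-format CSV dialect (comma, UTF-8,
# header row, "." for missing values).

.EXPORT_COLS <- c("ID", "TIME", "DRUG", "DV", "AMT", "EVID", "MDV", "OCC",
                  "WT", "BMI", "CG", "VAS", "BLQ", "LLOQ")
.BMI_LEVELS <- c("normal", "thin", "overweight")
.CG_LEVELS <- c("grandparent", "parent", "uncle_aunt", "sibling")
.OCC_CODES <- c(enrolment = 1L, followup = 2L)

#' Export a cohort as an analysis-ready CSV
#'
#' Writes a NONMEM-style long dataset. Encodings: one dose row per
#' subject x occasion x analyte (`EVID = 1`, `AMT` = dose in mg,
#' `MDV = 1`, `DV = "."`) followed by the observation row (`EVID = 0`,
#' `AMT = "."`); `OCC` 1 = enrolment, 2 = follow-up; `BLQ` rows keep
#' `MDV = 1` and a masked `DV = "."` (the pre-censoring value is never
#' exported); missing entries are `"."`.
#'
#' @param cohort A `hairpk_cohort` (see [simulate_cohort()]).
#' @param path Output file path.
#' @param dose Named vector of dose amounts per analyte
#'   (default `c(ATV = 300, RTV = 100)`).
#' @return `path`, invisibly.
#' @export
export_dataset <- function(cohort, path, dose = c(ATV = 300, RTV = 100)) {
  cov <- cohort$covariates
  obs <- cohort$observations
  orphans <- setdiff(unique(obs$subject), unique(cov$subject))
  if (length(orphans))
    stop("observations reference unknown subject(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  d <- dplyr::inner_join(
    obs, cov[, c("subject", "occasion", "weight", "bmi", "caregiver",
                 "adherence_vas")],
    by = c("subject", "occasion"))
  ids <- sort(unique(cov$subject))
  id_no <- stats::setNames(seq_along(ids), ids)
  fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 10,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  mk <- function(di, evid) {
    data.frame(
      ID = id_no[di$subject],
      TIME = fmt(di$time_h),
      DRUG = di$analyte,
      DV = if (evid == 1) "." else ifelse(di$blq, ".", fmt(di$conc)),
      AMT = if (evid == 1) fmt(unname(dose[di$analyte])) else ".",
      EVID = evid,
      MDV = if (evid == 1) 1L else as.integer(di$blq),
      OCC = .OCC_CODES[di$occasion],
      WT = fmt(di$weight),
      BMI = di$bmi,
      CG = di$caregiver,
      VAS = fmt(di$adherence_vas),
      BLQ = as.integer(di$blq),
      LLOQ = fmt(di$lloq),
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk(d, 1L), mk(d, 0L))
  out <- out[order(out$ID, out$DRUG, as.numeric(out$TIME), -out$EVID), ]
  utils::write.csv(out[, .EXPORT_COLS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an exported dataset back into cohort tables
#'
#' Parses the CSV dialect written by [export_dataset()], validating the
#' schema: exact column set, numeric `DV`/`WT`/`VAS`, and known category
#' levels. BLQ observations come back with `conc = NA` (the export masks
#' them).
#'
#' @param path CSV file path.
#' @return A `hairpk_cohort`-shaped list with `covariates` and
#'   `observations`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, colClasses = "character",
                                  check.names = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (nrow(raw) == 0L) stop("dataset is empty: ", path, call. = FALSE)
  miss <- setdiff(.EXPORT_COLS, names(raw))
  if (length(miss)) stop("missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), .EXPORT_COLS)
  if (length(extra)) stop("unexpected column(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  num <- function(x, col) {
    x[x == "."] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) stop("non-numeric ", col, " at row ", bad[1],
                          call. = FALSE)
    v
  }
  chk_levels <- function(x, levels, col) {
    bad <- setdiff(unique(x), levels)
    if (length(bad)) stop("unknown ", col, " level: ", bad[1],
                          call. = FALSE)
    x
  }
  occ_code <- num(raw$OCC, "OCC")
  if (any(!occ_code %in% .OCC_CODES))
    stop("unknown OCC code: ", setdiff(occ_code, .OCC_CODES)[1],
         call. = FALSE)
  tab <- tibble::tibble(
    subject = sprintf("S%03d", as.integer(num(raw$ID, "ID"))),
    time_h = num(raw$TIME, "TIME"),
    analyte = chk_levels(raw$DRUG, c("ATV", "RTV"), "DRUG"),
    conc = num(raw$DV, "DV"),
    evid = as.integer(num(raw$EVID, "EVID")),
    occasion = names(.OCC_CODES)[match(occ_code, .OCC_CODES)],
    weight = num(raw$WT, "WT"),
    bmi = chk_levels(raw$BMI, .BMI_LEVELS, "BMI"),
    caregiver = chk_levels(raw$CG, .CG_LEVELS, "CG"),
    adherence_vas = num(raw$VAS, "VAS"),
    blq = as.integer(num(raw$BLQ, "BLQ")) == 1L,
    lloq = num(raw$LLOQ, "LLOQ"))
  obs <- tab[tab$evid == 0L, ]
  covariates <- dplyr::distinct(
    tab[, c("subject", "occasion", "time_h", "weight", "bmi", "caregiver",
            "adherence_vas")])
  structure(list(
    covariates = covariates,
    observations = tibble::as_tibble(
      obs[, c("subject", "occasion", "time_h", "analyte", "conc", "blq",
              "lloq")])),
    class = "hairpk_cohort")
}
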