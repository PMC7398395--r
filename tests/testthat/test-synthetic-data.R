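# Virtual-cohort generator: covariate distributions, censoring, export.

test_that("cohort simulation is deterministic and leaves the caller's RNG untouched", {
  spec <- cohort_spec(n_subjects = 20, seed = 51)
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  c1 <- simulate_cohort(spec)
  after <- runif(1)
  expect_identical(before, after)   # RNG state preserved

  c2 <- simulate_cohort(spec)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(as.data.frame(c1$observations),
                   as.data.frame(c2$observations))

  # two occasions per subject and both analytes present
  expect_equal(nrow(c1$covariates), 40)
  expect_setequal(unique(c1$observations$analyte), c("ATV", "RTV"))
  expect_error(cohort_spec(n_subjects = 0), ">= 1")
})

test_that("covariate marginals follow the study's distributions", {
  co <- simulate_cohort(cohort_spec(n_subjects = 4000, seed = 52))
  subj <- co$covariates[co$covariates$occasion == "enrolment", ]

  cg <- table(subj$caregiver) / nrow(subj)
  expect_equal(as.numeric(cg[c("grandparent", "parent", "uncle_aunt",
                               "sibling")]),
               c(0.40, 0.20, 0.30, 0.10), tolerance = 0.02 / 0.10)
  bmi <- table(subj$bmi) / nrow(subj)
  expect_equal(as.numeric(bmi[c("normal", "thin", "overweight")]),
               c(54, 30, 15) / 99, tolerance = 0.02 / 0.15)

  # adherence respects its truncation bounds; the realised mean of the
  # doubly truncated normal (84.2, 18.1 on [30, 100]) is 78.2
  expect_true(all(subj$adherence_vas >= 30 & subj$adherence_vas <= 100))
  a <- (30 - 84.2) / 18.1; b <- (100 - 84.2) / 18.1
  mu_trunc <- 84.2 + 18.1 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mean(subj$adherence_vas), mu_trunc, tolerance = 0.01)

  # weight respects its bounds with the requested median
  expect_true(all(subj$weight >= 25 & subj$weight <= 90))
  expect_equal(median(subj$weight), 50, tolerance = 0.02)
})

test_that("BLQ flagging censors strictly below the limit with a closed lower bound", {
  obs <- tibble::tibble(
    subject = "S001", occasion = "enrolment", time_h = 0,
    analyte = c("ATV", "ATV", "ATV", "RTV"),
    conc = c(0.04, 0.05, 0.8, 0.005),
    blq = FALSE,
    lloq = c(0.05, 0.05, 0.05, 0.01))
  out <- apply_blq(obs)
  expect_identical(out$blq, c(TRUE, FALSE, FALSE, TRUE))
  sm <- attr(out, "blq_summary")
  expect_equal(sm$n_blq[sm$analyte == "ATV"], 1L)

  # override limits by analyte
  out2 <- apply_blq(obs, lloq = c(ATV = 0.5, RTV = 0.001))
  expect_identical(out2$blq, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(apply_blq(obs, lloq = c(ATV = -1, RTV = 0.01)), "> 0")

  # empty input: empty output, zero counts
  empty <- apply_blq(obs[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(attr(empty, "blq_summary")), 0L)
})

test_that("zero-noise simulation reproduces the deterministic structural prediction", {
  truth <- hair_model("ATV", dose_regimen(300, 24), plasma_defaults("ATV"),
                      frac_pop = 0.16,
                      betas = c(beta_occasion = -0.30),
                      covariates = "occasion",
                      sd_add = 0, sd_prop = 0)
  co <- simulate_cohort(atv_cohort_spec(15, seed = 53, truth = truth))
  d <- analysis_dataset(co, "ATV")
  expect_equal(d$conc, predict_f(truth, d), tolerance = 1e-12)
})

test_that("the exported dataset round-trips and honours its encodings", {
  co <- simulate_cohort(cohort_spec(n_subjects = 25, seed = 54))
  tf <- withr::local_tempfile(fileext = ".csv")
  export_dataset(co, tf)
  raw <- utils::read.csv(tf, colClasses = "character")

  # dose rows: EVID 1 with the analyte's dose, missing DV
  dose_atv <- raw[raw$EVID == "1" & raw$DRUG == "ATV", ]
  expect_true(all(dose_atv$AMT == "300"))
  expect_true(all(dose_atv$DV == "."))
  expect_true(all(raw$AMT[raw$EVID == "1" & raw$DRUG == "RTV"] == "100"))

  # BLQ observations: DV masked, MDV 1
  blq_rows <- raw[raw$EVID == "0" & raw$BLQ == "1", ]
  expect_gt(nrow(blq_rows), 0)
  expect_true(all(blq_rows$DV == "."))
  expect_true(all(blq_rows$MDV == "1"))

  back <- read_dataset(tf)
  bo <- back$observations[order(back$observations$subject,
                                back$observations$analyte,
                                back$observations$time_h), ]
  oo <- co$observations[order(co$observations$subject,
                              co$observations$analyte,
                              co$observations$time_h), ]
  expect_identical(bo$subject, oo$subject)
  expect_identical(bo$blq, oo$blq)
  # quantifiable concentrations survive the round trip; BLQ come back NA
  expect_equal(bo$conc[!bo$blq], oo$conc[!oo$blq], tolerance = 1e-7)
  expect_true(all(is.na(bo$conc[bo$blq])))
  bc <- back$covariates[back$covariates$occasion == "enrolment", ]
  oc <- co$covariates[co$covariates$occasion == "enrolment", ]
  expect_equal(bc$weight, oc$weight, tolerance = 1e-7)
  expect_identical(bc$caregiver, oc$caregiver)
})

test_that("schema violations are reported with context", {
  co <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 55))
  tf <- withr::local_tempfile(fileext = ".csv")
  export_dataset(co, tf)

  # unknown category level
  txt <- readLines(tf)
  bad <- sub("grandparent", "neighbour", txt)
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, tf2)
  expect_error(read_dataset(tf2), "neighbour")

  # missing column
  raw <- utils::read.csv(tf)
  raw$VAS <- NULL
  tf3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, tf3, row.names = FALSE)
  expect_error(read_dataset(tf3), "VAS")

  # empty file is an error, not empty tables
  tf4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("ID", "TIME", "DRUG", "DV", "AMT", "EVID", "MDV",
                     "OCC", "WT", "BMI", "CG", "VAS", "BLQ", "LLOQ"),
                   collapse = ","), tf4)
  expect_error(read_dataset(tf4), "empty")
  expect_error(read_dataset("no-such-file.csv"), "no such file")

  # referential inconsistency on export
  co_bad <- co
  co_bad$observations$subject[1] <- "S999"
  expect_error(export_dataset(co_bad, withr::local_tempfile()), "S999")
})

test_that("model configurations round-trip through YAML", {
  m <- atv_model()
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, tf)
  m2 <- read_model_yaml(tf)
  expect_equal(m2$params, m$params)
  expect_identical(m2$covariates, m$covariates)
  expect_identical(m2$estimated, m$estimated)
  expect_identical(m2$link, m$link)
  expect_equal(m2$plasma$k20, m$plasma$k20)
})
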