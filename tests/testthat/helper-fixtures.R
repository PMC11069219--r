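# Shared builders and independent oracles for the test suite.

# A minimal well-formed tumor record; override any field.
make_record <- function(patient_id = "P1", sex = "male",
                        birth_date = as.Date("1945-06-15"),
                        diagnosis_date = as.Date("2005-03-01"),
                        site = "C34.1", morphology = 8140L, behavior = 3L,
                        region = "north", dco = FALSE, laterality = "left",
                        vital_status = "alive",
                        vital_status_date = as.Date("2014-12-31")) {
  tibble::tibble(patient_id = patient_id, sex = sex, birth_date = birth_date,
                 diagnosis_date = diagnosis_date, site = site,
                 morphology = as.integer(morphology), behavior = behavior,
                 region = region, dco = dco, laterality = laterality,
                 vital_status = vital_status,
                 vital_status_date = vital_status_date)
}

make_records <- function(...) dplyr::bind_rows(...)

# Independent day-by-day person-time oracle: walks every at-risk day of every
# case, assigns it to its stratum, and accumulates 1/365.25 person-years.
oracle_person_time <- function(cohort, strata, by_histology = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    if (cohort$end[i] <= cohort$start[i]) next
    days <- seq(cohort$start[i], cohort$end[i] - 1, by = "day")
    lt <- as.POSIXlt(days)
    bl <- as.POSIXlt(cohort$birth_date[i])
    age <- (lt$year - bl$year) -
      ((lt$mon < bl$mon) | (lt$mon == bl$mon & lt$mday < bl$mday))
    band <- strata$age_labels[findInterval(age, strata$age_breaks)]
    period <- strata$period_labels[findInterval(lt$year + 1900L,
                                                strata$period_breaks)]
    rows[[i]] <- tibble::tibble(
      sex = cohort$sex[i], age_band = band, period = period,
      region = cohort$region[i],
      index_histology = if (by_histology) cohort$group[i] else "all")
  }
  dplyr::bind_rows(rows) |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "days") |>
    dplyr::mutate(person_years = days / 365.25) |>
    dplyr::select(-days)
}

# Random at-risk cases spanning band and period boundaries (deterministic
# under the caller's seed).
random_interval_cases <- function(n) {
  birth <- as.Date("1920-01-01") + sample.int(22000L, n, replace = TRUE)
  start <- as.Date("2002-01-01") + sample.int(4300L, n, replace = TRUE)
  end <- pmin(start + sample.int(3000L, n, replace = TRUE),
              as.Date("2014-12-31"))
  tibble::tibble(
    patient_id = sprintf("R%03d", seq_len(n)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    birth_date = birth, region = sample(c("a", "b"), n, replace = TRUE),
    start = start, end = end,
    group = sample(c("adenocarcinoma", "squamous"), n, replace = TRUE))
}

sir_total <- function(res, variant_name, which_sex = "all") {
  res[res$variant == variant_name & res$sex == which_sex &
        res$stratum_label == "total", , drop = FALSE]
}
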