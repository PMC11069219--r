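cfg <- cohort_config()
st <- strata_def()

test_that("at-risk intervals end at the earliest bound with the right label", {
  # dead 2 years after diagnosis: landmark start, death end
  dead <- make_record(diagnosis_date = as.Date("2010-01-01"),
                      vital_status = "dead",
                      vital_status_date = as.Date("2012-01-01"))
  iv <- at_risk_interval(dead, cfg = cfg)
  expect_equal(iv$start, as.Date("2010-07-01"))
  expect_equal(iv$end, as.Date("2012-01-01"))
  expect_equal(iv$end_reason, "death")
  expect_equal(as.numeric(iv$end - iv$start) / 365.25, 1.5, tolerance = 0.01)

  # alive, diagnosed late: censored at the study end
  alive <- make_record(diagnosis_date = as.Date("2013-06-30"))
  iv2 <- at_risk_interval(alive, cfg = cfg)
  expect_equal(iv2$end, as.Date("2014-12-31"))
  expect_equal(iv2$end_reason, "study_end")

  # hypothetical early diagnosis: capped at 13 years of follow-up
  early <- make_record(diagnosis_date = as.Date("2001-01-01"),
                       vital_status_date = as.Date("2020-01-01"))
  iv3 <- at_risk_interval(early, cfg = cfg)
  expect_equal(iv3$end, as.Date("2014-01-01"))
  expect_equal(iv3$end_reason, "max_followup")

  # a counted second primary censors first
  ev <- tibble::tibble(patient_id = "P1", diagnosis_date = as.Date("2011-03-15"))
  iv4 <- at_risk_interval(dead, events = ev, cfg = cfg)
  expect_equal(iv4$end, as.Date("2011-03-15"))
  expect_equal(iv4$end_reason, "splc")
  # an event before the at-risk start violates the counting contract
  bad <- tibble::tibble(patient_id = "P1", diagnosis_date = as.Date("2010-03-01"))
  expect_error(at_risk_interval(dead, events = bad, cfg = cfg), "before")
})

test_that("an interval inside one stratum is a single unsplit cell", {
  case <- tibble::tibble(patient_id = "P1", sex = "male",
                         birth_date = as.Date("1950-03-15"), region = "north",
                         start = as.Date("2006-01-10"), end = as.Date("2007-07-10"))
  pt <- tabulate_person_time(case, st)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$age_band, "55-59")
  expect_equal(pt$period, "2005-2009")
  expect_equal(pt$person_years, as.numeric(as.Date("2007-07-10") -
                                             as.Date("2006-01-10")) / 365.25)
})

test_that("a band-boundary birthday splits the interval exactly at the birthday", {
  case <- tibble::tibble(patient_id = "P1", sex = "female",
                         birth_date = as.Date("1942-06-20"), region = "north",
                         start = as.Date("2007-02-01"), end = as.Date("2008-02-01"))
  pt <- tabulate_person_time(case, st)  # 65th birthday 2007-06-20
  expect_equal(sort(pt$age_band), c("60-64", "65-69"))
  expect_equal(sum(pt$person_years), as.numeric(case$end - case$start) / 365.25)
  expect_equal(pt$person_years[pt$age_band == "60-64"],
               as.numeric(as.Date("2007-06-20") - as.Date("2007-02-01")) / 365.25)
})

test_that("tabulation conserves total follow-up and matches the day-by-day oracle", {
  set.seed(202)
  cases <- random_interval_cases(50)
  pt <- tabulate_person_time(cases, st, by_histology = TRUE)
  expect_equal(sum(pt$person_years),
               sum(as.numeric(cases$end - cases$start)) / 365.25,
               tolerance = 1e-12)
  oracle <- oracle_person_time(cases, st, by_histology = TRUE)
  merged <- dplyr::full_join(
    oracle, tibble::as_tibble(pt),
    by = c("sex", "age_band", "period", "region", "index_histology"),
    suffix = c("_oracle", "_split"))
  expect_false(any(is.na(merged$person_years_oracle)))
  expect_false(any(is.na(merged$person_years_split)))
  expect_lt(max(abs(merged$person_years_oracle - merged$person_years_split)),
            1e-9)
})

test_that("refining bands never changes the person-time total", {
  set.seed(203)
  cases <- random_interval_cases(30)
  coarse <- strata_def(age_breaks = seq(0, 80, 10),
                       period_breaks = c(2000, 2015))
  fine <- strata_def(age_breaks = seq(0, 85, 5),
                     period_breaks = seq(2000, 2015, 5))
  expect_equal(sum(tabulate_person_time(cases, coarse)$person_years),
               sum(tabulate_person_time(cases, fine)$person_years),
               tolerance = 1e-12)
})

test_that("follow-up windows partition person-time and label offsets from start", {
  set.seed(204)
  cases <- random_interval_cases(20)
  stf <- strata_def(followup_breaks = c(0, 1, 5, 13))
  ptf <- tabulate_person_time(cases, stf)
  expect_true(all(ptf$fu_band %in% stf$fu_labels))
  expect_gt(dplyr::n_distinct(ptf$fu_band), 1)
  expect_equal(sum(ptf$person_years),
               sum(as.numeric(cases$end - cases$start)) / 365.25,
               tolerance = 1e-12)
})

test_that("a date outside all period bands is an error naming the problem", {
  case <- tibble::tibble(patient_id = "P1", sex = "male",
                         birth_date = as.Date("1940-01-01"), region = "north",
                         start = as.Date("1998-01-01"), end = as.Date("1999-01-01"))
  expect_error(tabulate_person_time(case, st), "period")
})

test_that("person-time tables round-trip through delimited text", {
  set.seed(205)
  cases <- random_interval_cases(10)
  pt <- tabulate_person_time(cases, st)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_person_time_table(pt, path)
  back <- read_person_time_table(path)
  expect_equal(attr(back, "cohort_size"), attr(pt, "cohort_size"))
  attr(pt, "strata") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(pt))
})
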