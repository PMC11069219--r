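test_that("exact Poisson intervals behave at the boundaries and contain the estimate", {
  expect_equal(poisson_exact_ci(0, 2)$ci_low, 0)
  ci <- poisson_exact_ci(5, 2.5)
  expect_lt(ci$ci_low, 2)
  expect_gt(ci$ci_high, 2)
  # monotone in O at fixed E
  his <- poisson_exact_ci(0:20, 10)
  expect_true(all(diff(his$ci_low) > 0 | (0:19) == 0))
  expect_true(all(diff(his$ci_high) > 0))
  expect_error(poisson_exact_ci(3, 0), "positive")
  expect_error(poisson_exact_ci(-1, 1), "non-negative")
})

test_that("SIR cells divide O by E and totals pool before dividing", {
  cfg_s <- synth_config(background_rates = c(`0` = 0.02),
                        regions = c(north = 1),
                        histology_distribution = c(
                          squamous = 0.5, adenocarcinoma = 0.5, small_cell = 0,
                          large_cell = 0, other_carcinoma = 0, sarcoma = 0,
                          other_specified = 0, unspecified = 0))
  st1 <- strata_def(age_breaks = 0, period_breaks = c(2000, 2015))
  rates <- list(
    adenocarcinoma = rate_table_from_config(cfg_s, st1, "adenocarcinoma"),
    squamous = rate_table_from_config(cfg_s, st1, "squamous"))
  cohort <- tibble::tibble(patient_id = c("p1", "p2"), sex = "male",
                           group = c("adenocarcinoma", "squamous"))
  # excluded-group rates are 0.01; person-years chosen so E = 1 and 2
  pt <- tibble::tibble(sex = "male", age_band = "0+", period = "2000-2014",
                       region = "north",
                       index_histology = c("adenocarcinoma", "squamous"),
                       person_years = c(100, 200))
  events <- tibble::tibble(patient_id = c("p1", "p1", "p2"),
                           group = c("squamous", "squamous", "adenocarcinoma"))
  res <- estimate_sir(cohort, events, pt, rates, variant = "sir2_sub")
  cell <- res[res$stratum_label == "adenocarcinoma", ]
  expect_equal(cell$sir, 2 / 1)
  # pooled total is sum(O)/sum(E) = 3/3, not the mean of 2 and 0.5
  expect_equal(sir_total(res, "sir2_sub")$sir, 1)
  expect_equal(sir_total(res, "sir2_sub")$O, 3L)
})

test_that("same-group second primaries are dropped from O only in the sub variants", {
  cfg_s <- synth_config(background_rates = c(`0` = 0.02), regions = c(north = 1))
  st1 <- strata_def(age_breaks = 0, period_breaks = c(2000, 2015))
  rates <- rate_tables_from_config(cfg_s, st1)
  cohort <- tibble::tibble(patient_id = "p1", sex = "female",
                           group = "adenocarcinoma")
  pt_all <- tibble::tibble(sex = "female", age_band = "0+", period = "2000-2014",
                           region = "north", index_histology = "all",
                           person_years = 100)
  pt_hist <- dplyr::mutate(pt_all, index_histology = "adenocarcinoma")
  same_group_event <- tibble::tibble(patient_id = "p1", group = "adenocarcinoma",
                                     intprim = FALSE)
  raw <- estimate_sir(cohort, same_group_event, pt_all, rates$general,
                      variant = "sir1_raw")
  sub <- estimate_sir(cohort, same_group_event, pt_hist,
                      rates[names(rates) != "general"], variant = "sir2_sub")
  expect_equal(sir_total(raw, "sir1_raw")$O, 1L)
  expect_equal(sir_total(sub, "sir2_sub")$O, 0L)
})

test_that("zero expected with observed events is an error, empty cells are dropped", {
  cfg_s <- synth_config(background_rates = c(`0` = 0), regions = c(north = 1))
  st1 <- strata_def(age_breaks = 0, period_breaks = c(2000, 2015))
  rt <- rate_table_from_config(cfg_s, st1)
  cohort <- tibble::tibble(patient_id = "p1", sex = "male", group = "squamous")
  pt <- tibble::tibble(sex = "male", age_band = "0+", period = "2000-2014",
                       region = "north", person_years = 100)
  ev <- tibble::tibble(patient_id = "p1", group = "adenocarcinoma")
  expect_error(estimate_sir(cohort, ev, pt, rt, variant = "sir1_raw"),
               "zero expected")
  w <- testthat::capture_warnings(
    out <- estimate_sir(cohort, ev[0, ], pt, rt, variant = "sir1_raw"))
  expect_true(any(grepl("omitted", w)))
  expect_equal(nrow(out), 0L)
})

test_that("a null cohort without suppression recovers SIR close to 1", {
  cfg <- synth_config(n_persons = 30000, seed = 91, sir_real = 1,
                      apply_iarc_suppression = FALSE)
  rec <- generate_cohort(cfg)
  rt <- rate_table_from_config(cfg)
  res <- estimate_splc_sir(rec, cfg$cohort, rates = rt, variants = "sir1_raw")
  tot <- sir_total(res, "sir1_raw")
  expect_gt(tot$ci_high, 1)
  expect_lt(tot$ci_low, 1)
  expect_equal(tot$sir, 1, tolerance = 0.25)
})

test_that("follow-up stratification splits O and E consistently with the totals", {
  cfg <- synth_config(n_persons = 30000, seed = 92, sir_real = 2)
  rec <- generate_cohort(cfg)
  stf <- strata_def(followup_breaks = c(0, 1, 5, 13))
  rt <- rate_table_from_config(cfg, stf)
  res <- estimate_splc_sir(rec, cfg$cohort, strata = stf, rates = rt,
                           variants = "sir1_raw")
  cells <- res[res$sex != "all" & res$stratum_label != "total", ]
  tot <- sir_total(res, "sir1_raw")
  expect_equal(sum(cells$O), tot$O)
  expect_equal(sum(cells$E), tot$E, tolerance = 1e-9)
  expect_true(all(grepl("y$", cells$stratum_label)))
})
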