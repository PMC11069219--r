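st <- strata_def()

# A small reference population with known structure: cases in two strata.
pop_person_time <- tibble::tibble(
  sex = rep(c("male", "female"), each = 2),
  age_band = rep(c("60-64", "65-69"), 2),
  period = "2005-2009", region = "north",
  person_years = c(1000, 500, 800, 0))

pop_case <- function(id, sex = "male", birth = "1945-06-15",
                     dx = "2007-03-01", morph = 8140L, dco = FALSE) {
  make_record(patient_id = id, sex = sex, birth_date = as.Date(birth),
              diagnosis_date = as.Date(dx), morphology = morph, dco = dco)
}

test_that("rates are cases per person-year with DCO handling", {
  cases <- make_records(
    pop_case("a"), pop_case("b"),                      # two male cases, age 61
    pop_case("d", dco = TRUE))
  rt <- suppressWarnings(
    compute_reference_rates(cases, pop_person_time, st))
  expect_equal(rt$rate[rt$sex == "male" & rt$age_band == "60-64"],
               3 / 1000)
  rt_nodco <- suppressWarnings(
    compute_reference_rates(cases, pop_person_time, st, dco_included = FALSE))
  expect_equal(rt_nodco$cases[rt_nodco$sex == "male" & rt_nodco$age_band == "60-64"],
               2L)
  # DCO toggle changes exactly the DCO case's stratum numerator, by 1
  diff <- rt$cases - rt_nodco$cases
  expect_equal(sum(diff), 1L)
  expect_equal(diff[rt$sex == "male" & rt$age_band == "60-64"], 1L)
})

test_that("empty strata get rate zero with a warning", {
  cases <- pop_case("a")
  expect_warning(rt <- compute_reference_rates(cases, pop_person_time, st),
                 "zero denominator")
  expect_equal(rt$rate[rt$person_years == 0], 0)
})

test_that("excluding a histology group removes exactly its cases from numerators", {
  set.seed(99)
  cfg_s <- synth_config(n_persons = 200, seed = 12)
  pop <- generate_population_denominators(cfg_s, n_population = 5000, strata = st)
  general <- suppressWarnings(
    compute_reference_rates(pop$cases, pop$person_time, st))
  excl <- suppressWarnings(
    compute_histology_specific_rates(pop$cases, pop$person_time, st,
                                     excluded_group = "adenocarcinoma"))
  # brute-force recount on the same population
  sch <- histology_scheme("iarc8")
  is_adeno <- map_morphology(pop$cases$morphology, sch) == "adenocarcinoma"
  expect_equal(sum(excl$cases), nrow(pop$cases) - sum(is_adeno))
  expect_true(all(excl$rate <= general$rate + 1e-15))
  # a group with zero population share leaves the table unchanged
  none <- suppressWarnings(
    compute_histology_specific_rates(pop$cases, pop$person_time, st,
                                     excluded_group = "unspecified"))
  expect_equal(none$rate, general$rate)
  expect_error(
    compute_histology_specific_rates(pop$cases, pop$person_time, st,
                                     excluded_group = "nonesuch"),
    "Unknown")
})

test_that("expected counts multiply person-time by rates and add up", {
  cfg_s <- synth_config(background_rates = c(`0` = 0.02),
                        regions = c(north = 1))
  st1 <- strata_def(age_breaks = 0, period_breaks = c(2000, 2015))
  rt <- rate_table_from_config(cfg_s, st1)
  pt <- tibble::tibble(sex = "male", age_band = "0+", period = "2000-2014",
                       region = "north", person_years = 100)
  expect_equal(expected_count(pt, rt)$total, 2)
  pt2 <- dplyr::bind_rows(pt, dplyr::mutate(pt, sex = "female", person_years = 50))
  rt$rate[rt$sex == "female"] <- 0.01
  expect_equal(expected_count(pt2, rt)$total, 2.5)
  # additivity over a partition of the person-time
  expect_equal(expected_count(pt2[1, ], rt)$total +
                 expected_count(pt2[2, ], rt)$total,
               expected_count(pt2, rt)$total)
})

test_that("the histology-specific contract between person-time and rates is enforced", {
  cfg_s <- synth_config(background_rates = c(`0` = 0.02),
                        regions = c(north = 1))
  st1 <- strata_def(age_breaks = 0, period_breaks = c(2000, 2015))
  general <- rate_table_from_config(cfg_s, st1)
  excl_ac <- rate_table_from_config(cfg_s, st1, excluded_group = "adenocarcinoma")
  pt_ac <- tibble::tibble(sex = "male", age_band = "0+", period = "2000-2014",
                          region = "north", index_histology = "adenocarcinoma",
                          person_years = 100)
  expect_error(expected_count(pt_ac, general), "histology-specific")
  expect_silent(expected_count(pt_ac, excl_ac))
  # missing stratum in the rate table is reported
  pt_bad <- dplyr::mutate(pt_ac, region = "mars")
  expect_error(expected_count(pt_bad, excl_ac), "mars")
})

test_that("rate tables round-trip through text with bit-identical expected counts", {
  set.seed(100)
  cfg_s <- synth_config(n_persons = 200, seed = 13)
  pop <- generate_population_denominators(cfg_s, n_population = 3000, strata = st)
  rt <- suppressWarnings(compute_reference_rates(pop$cases, pop$person_time, st))
  pt <- pop$person_time
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rt, path)
  back <- read_rate_table(path)
  expect_identical(expected_count(pt, back)$total, expected_count(pt, rt)$total)
  expect_identical(attr(back, "excluded_group"), attr(rt, "excluded_group"))
})
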