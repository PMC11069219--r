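# Synthetic registry cohorts with known ground truth.
#
# The generator emulates a lung-cancer survivor cohort: stratum-specific
# first-cancer incidence, a categorical histology distribution p over the 8
# IARC groups, exponential post-diagnosis survival, a second-primary hazard
# equal to sir_real times the age-specific reference rate (piecewise
# exponential over age bands, starting at the landmark), second-primary
# histology drawn independently from the same p, and optional IARC/IACR-rule
# suppression of same-group (or unspecified-matched) second primaries. The
# seed fully determines the output, and toggling suppression alone never
# changes any non-suppressed record.

REPRESENTATIVE_CODES <- c(
  squamous = 8070L, adenocarcinoma = 8140L, small_cell = 8041L,
  large_cell = 8012L, other_carcinoma = 8240L, sarcoma = 8800L,
  other_specified = 9060L, unspecified = 8000L
)

#' Default synthetic histology distribution over the 8 IARC groups
#'
#' Fully specified histology (zero mass on the wildcard unspecified group)
#' with `sum(p^2) = 0.2986`, so conventional-SIR estimation on an
#' IARC/IACR-suppressed cohort under-estimates the true ratio by about 30%.
#' @return Named numeric vector over the `iarc8` groups, summing to 1.
#' @export
default_histology_distribution <- function() {
  c(squamous = 0.42, adenocarcinoma = 0.32, small_cell = 0.12,
    large_cell = 0.05, other_carcinoma = 0.05, sarcoma = 0.02,
    other_specified = 0.02, unspecified = 0)
}

#' Default age-specific background incidence (cases per person-year)
#' @return Named numeric vector: names are age-band lower bounds (years).
#' @export
default_background_rates <- function() {
  c(`0` = 2e-05, `40` = 2e-04, `50` = 8e-04, `60` = 2e-03,
    `70` = 3e-03, `80` = 3.5e-03)
}

#' Synthetic registry configuration
#'
#' @param n_persons Cohort size (index cases generated).
#' @param seed Integer seed; fully determines the output.
#' @param sex_split Proportion female (default 0.32).
#' @param age_mean,age_sd,age_range Truncated-normal age at diagnosis, years.
#' @param diagnosis_years `c(min, max)` diagnosis years.
#' @param histology_distribution Named probability vector over the `iarc8`
#'   groups (used for both sexes), or `list(female = ..., male = ...)`.
#' @param post_dx_survival_median Median post-diagnosis survival, years.
#' @param sir_real True second-primary hazard ratio vs the background rates.
#' @param background_rates Named step function of age: see
#'   [default_background_rates()]. Used both as the second-primary hazard
#'   baseline and as the general-population first-cancer incidence.
#' @param dco_fraction Share of eligible decedents flagged
#'   death-certificate-only.
#' @param regions Named region shares.
#' @param apply_iarc_suppression Delete second primaries an IARC/IACR
#'   registry could not record (same group as the index, or either tumor of
#'   unspecified histology)?
#' @param landmark_months,followup_end,max_followup_years Follow-up window;
#'   also stored as the matching [cohort_config()] in `$cohort`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_persons = 10000L, seed = 1L,
                         sex_split = 0.32,
                         age_mean = 68, age_sd = 10, age_range = c(30, 99),
                         diagnosis_years = c(2002L, 2013L),
                         histology_distribution = default_histology_distribution(),
                         post_dx_survival_median = 1.5,
                         sir_real = 1,
                         background_rates = default_background_rates(),
                         dco_fraction = 0.04,
                         regions = c(north = 0.5, south = 0.3, east = 0.2),
                         apply_iarc_suppression = FALSE,
                         landmark_months = 6L,
                         followup_end = as.Date("2014-12-31"),
                         max_followup_years = 13) {
  check_number(n_persons, "n_persons", lower = 1)
  check_number(seed, "seed", lower = -2^31 + 1, upper = 2^31 - 1)
  check_number(sex_split, "sex_split", lower = 0, upper = 1)
  check_number(age_mean, "age_mean", lower = 0)
  check_number(age_sd, "age_sd", lower = 1e-9)
  check_number(post_dx_survival_median, "post_dx_survival_median", lower = 1e-9)
  check_number(sir_real, "sir_real", lower = 0)
  check_number(dco_fraction, "dco_fraction", lower = 0, upper = 1)
  check_flag(apply_iarc_suppression, "apply_iarc_suppression")
  scheme <- histology_scheme("iarc8")
  dist <- histology_distribution
  if (!is.list(dist)) dist <- list(female = dist, male = dist)
  for (s in c("female", "male")) {
    p <- dist[[s]]
    if (is.null(p) || is.null(names(p)) ||
        !setequal(names(p), scheme$groups) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      abort("`histology_distribution` must be a named probability vector over the iarc8 groups.")
    }
    dist[[s]] <- p[scheme$groups]
  }
  if (is.null(names(background_rates)) || any(background_rates < 0) ||
      is.unsorted(as.numeric(names(background_rates)), strictly = TRUE)) {
    abort("`background_rates` must be a named, age-ordered non-negative vector.")
  }
  if (is.null(names(regions)) || any(regions < 0) ||
      abs(sum(regions) - 1) > 1e-9) {
    abort("`regions` must be named non-negative shares summing to 1.")
  }
  cohort <- cohort_config(diagnosis_period = diagnosis_years,
                          landmark_months = landmark_months,
                          followup_end = followup_end,
                          max_followup_years = max_followup_years)
  structure(
    list(n_persons = as.integer(n_persons), seed = as.integer(seed),
         sex_split = sex_split, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, diagnosis_years = as.integer(diagnosis_years),
         histology_distribution = if (identical(dist$female, dist$male))
           dist$female else dist,
         dist_by_sex = dist,
         post_dx_survival_median = post_dx_survival_median,
         sir_real = sir_real, background_rates = background_rates,
         dco_fraction = dco_fraction, regions = regions,
         apply_iarc_suppression = apply_iarc_suppression,
         landmark_months = as.integer(landmark_months),
         followup_end = as.Date(followup_end),
         max_followup_years = max_followup_years,
         cohort = cohort, scheme = scheme),
    class = "synth_config"
  )
}

# Step lookup of the background rate at (continuous) age.
background_rate_at <- function(age, cfg) {
  breaks <- as.numeric(names(cfg$background_rates))
  unname(cfg$background_rates[pmax(findInterval(age, breaks), 1L)])
}

# Piecewise-exponential waiting time (years) across age bands, starting at
# continuous age `age0`, with hazard `multiplier * background(age)`.
piecewise_exp_wait <- function(age0, cfg, multiplier) {
  n <- length(age0)
  if (n == 0 || multiplier <= 0) return(rep(Inf, n))
  breaks <- as.numeric(names(cfg$background_rates))
  rates <- multiplier * unname(cfg$background_rates)
  target <- rexp(n)
  wait <- rep(Inf, n)
  t <- numeric(n)
  age <- pmax(age0, breaks[1])
  band <- pmax(findInterval(age, breaks), 1L)
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    i <- band[idx]
    rate <- rates[i]
    upper <- c(breaks, Inf)[i + 1L]
    dt <- upper - age[idx]              # Inf in the open top band
    haz <- rate * dt
    haz[rate == 0] <- 0
    hit <- target[idx] <= haz
    hi <- idx[hit]
    wait[hi] <- t[hi] + target[hi] / rate[hit]
    active[hi] <- FALSE
    mi <- idx[!hit]
    top <- !is.finite(dt[!hit])         # rate-0 top band: event never occurs
    active[mi[top]] <- FALSE
    mi <- mi[!top]
    target[mi] <- target[mi] - haz[!hit][!top]
    t[mi] <- t[mi] + dt[!hit][!top]
    age[mi] <- upper[!hit][!top]
    band[mi] <- band[mi] + 1L
  }
  wait
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm((lower - mean) / sd)
  hi <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(lo + runif(n) * (hi - lo))
}

#' Generate a synthetic registry cohort
#'
#' One index lung tumor per person, plus second-primary tumor records where
#' one occurred before death/end of registry follow-up (and, with
#' `apply_iarc_suppression`, was registrable under IARC/IACR rules). The
#' number of generated-but-suppressed second primaries is recorded in
#' attribute `"ground_truth"`.
#'
#' @param cfg A [synth_config()].
#' @return A tumor-record tibble (one row per registered tumor) with
#'   attribute `"ground_truth"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_persons
  scheme <- cfg$scheme
  groups <- scheme$groups
  sex <- ifelse(runif(n) < cfg$sex_split, "female", "male")
  age_dx <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd,
                        cfg$age_range[1], cfg$age_range[2])
  d0 <- as.integer(as.Date(paste0(cfg$diagnosis_years[1], "-01-01")))
  d1 <- as.integer(as.Date(paste0(cfg$diagnosis_years[2], "-12-31")))
  dx_date <- as.Date(d0 + floor(runif(n) * (d1 - d0 + 1L)), origin = "1970-01-01")
  birth_date <- dx_date - round(age_dx * DAYS_PER_YEAR)
  region <- names(cfg$regions)[
    1L + findInterval(runif(n), cumsum(cfg$regions), left.open = TRUE)]
  draw_groups <- function(u_sex) {
    p <- cfg$dist_by_sex[[u_sex]]
    idx <- sex == u_sex
    out <- character(sum(idx))
    out <- groups[1L + findInterval(runif(sum(idx)), cumsum(p), left.open = TRUE)]
    out
  }
  index_group <- character(n)
  index_group[sex == "female"] <- draw_groups("female")
  index_group[sex == "male"] <- draw_groups("male")

  death_years <- rexp(n, rate = log(2) / cfg$post_dx_survival_median)
  death_date <- dx_date + round(death_years * DAYS_PER_YEAR)
  dead <- death_date <= cfg$followup_end
  vital_status <- ifelse(dead, "dead", "alive")
  vital_status_date <- pmin(death_date, cfg$followup_end)

  landmark_date <- dx_date %m+% months(cfg$landmark_months)
  age_landmark <- as.numeric(landmark_date - birth_date) / DAYS_PER_YEAR
  splc_wait <- piecewise_exp_wait(age_landmark, cfg, cfg$sir_real)
  splc_date <- landmark_date + round(pmin(splc_wait, 200) * DAYS_PER_YEAR)
  # SPLC histology drawn from the same distribution as the index tumors
  splc_group <- character(n)
  splc_group[sex == "female"] <- draw_groups("female")
  splc_group[sex == "male"] <- draw_groups("male")
  recorded <- is.finite(splc_wait) & splc_date < death_date &
    splc_date <= cfg$followup_end

  # DCO flags: drawn at random among all decedents, independently of the
  # second-primary process (a DCO patient is unknown to the registry until
  # death, so any second primary of theirs goes unregistered as well; the
  # output DCO and second-primary record sets are disjoint)
  dco <- rep(FALSE, n)
  dco[dead] <- runif(sum(dead)) < cfg$dco_fraction

  registrable <- recorded & !dco
  suppressed <- rep(FALSE, n)
  if (cfg$apply_iarc_suppression) {
    suppressed <- registrable &
      iarc_group_matches(splc_group, index_group, scheme$wildcard_groups)
  }
  keep_splc <- registrable & !suppressed

  laterality <- ifelse(runif(n) < 0.05, "unknown",
                       ifelse(runif(n) < 0.5, "left", "right"))
  splc_laterality <- ifelse(runif(n) < 0.05, "unknown",
                            ifelse(runif(n) < 0.5, "left", "right"))
  patient_id <- sprintf("P%07d", seq_len(n))

  index <- tibble(
    patient_id = patient_id, sex = sex, birth_date = birth_date,
    diagnosis_date = dx_date, site = "C34.9",
    morphology = unname(REPRESENTATIVE_CODES[index_group]), behavior = 3L,
    region = region, dco = dco, laterality = laterality,
    vital_status = vital_status, vital_status_date = vital_status_date
  )
  splc <- tibble(
    patient_id = patient_id[keep_splc], sex = sex[keep_splc],
    birth_date = birth_date[keep_splc],
    diagnosis_date = splc_date[keep_splc], site = "C34.9",
    morphology = unname(REPRESENTATIVE_CODES[splc_group[keep_splc]]),
    behavior = 3L, region = region[keep_splc], dco = FALSE,
    laterality = splc_laterality[keep_splc],
    vital_status = vital_status[keep_splc],
    vital_status_date = vital_status_date[keep_splc]
  )
  out <- dplyr::bind_rows(index, splc) |>
    dplyr::arrange(.data$patient_id, .data$diagnosis_date)
  attr(out, "ground_truth") <- list(
    sir_real = cfg$sir_real, n_persons = n,
    n_splc_occurred = sum(recorded), n_suppressed = sum(suppressed),
    seed = cfg$seed, apply_iarc_suppression = cfg$apply_iarc_suppression
  )
  out
}

#' Generate general-population denominators and incident-case roster
#'
#' Simulates a reference population followed from the start of the diagnosis
#' window to the end of follow-up, with first-cancer hazard equal to the
#' configured background rates (mortality is ignored; the denominators are
#' the population person-time a registry would use). Rates recomputed from
#' the output with [compute_reference_rates()] converge to the configured
#' background rates as `n_population` grows.
#'
#' @param cfg A [synth_config()].
#' @param n_population Number of simulated population members (default
#'   `cfg$n_persons`).
#' @param strata A [strata_def()].
#' @return A list: `person_time` (population person-years per stratum) and
#'   `cases` (incident first-primary tumor records).
#' @export
generate_population_denominators <- function(cfg, n_population = cfg$n_persons,
                                             strata = strata_def()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed((cfg$seed + 777703L) %% .Machine$integer.max)
  n <- as.integer(n_population)
  scheme <- cfg$scheme
  w0 <- as.Date(paste0(cfg$diagnosis_years[1], "-01-01"))
  we <- cfg$followup_end
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  age0 <- runif(n, 0, 95)
  birth_date <- w0 - round(age0 * DAYS_PER_YEAR)
  region <- names(cfg$regions)[
    1L + findInterval(runif(n), cumsum(cfg$regions), left.open = TRUE)]
  wait <- piecewise_exp_wait(age0, cfg, 1)
  lc_date <- w0 + round(pmin(wait, 500) * DAYS_PER_YEAR)
  is_case <- is.finite(wait) & lc_date <= we
  group <- character(n)
  for (s in c("female", "male")) {
    p <- cfg$dist_by_sex[[s]]
    idx <- sex == s
    group[idx] <- scheme$groups[
      1L + findInterval(runif(sum(idx)), cumsum(p), left.open = TRUE)]
  }
  dco <- runif(n) < cfg$dco_fraction

  roster <- tibble(sex = sex, birth_date = birth_date, region = region,
                   start = w0, end = pmin(lc_date, we))
  person_time <- tabulate_person_time(roster, strata, by_histology = FALSE)
  cases <- tibble(
    patient_id = sprintf("G%07d", which(is_case)),
    sex = sex[is_case], birth_date = birth_date[is_case],
    diagnosis_date = lc_date[is_case], site = "C34.9",
    morphology = unname(REPRESENTATIVE_CODES[group[is_case]]), behavior = 3L,
    region = region[is_case], dco = dco[is_case], laterality = "unknown",
    vital_status = "alive", vital_status_date = we, intprim = TRUE
  )
  list(person_time = person_time, cases = cases)
}

#' Exact reference-rate table implied by a synthetic configuration
#'
#' Builds the rate table the generator's infinite-population limit would
#' yield: for every stratum the configured background rate, multiplied by
#' `1 - p[excluded_group]` for histology-specific tables. This is the
#' external-rate-table path of the SIR machinery, free of Monte-Carlo noise.
#'
#' @param cfg A [synth_config()].
#' @param strata A [strata_def()].
#' @param excluded_group Optional `iarc8` group to exclude from the implied
#'   numerator.
#' @return A `rate_table`.
#' @export
rate_table_from_config <- function(cfg, strata = strata_def(),
                                   excluded_group = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(excluded_group) &&
      !excluded_group %in% cfg$scheme$groups) {
    abort(sprintf("Unknown histology group '%s'.", excluded_group))
  }
  band_rate <- background_rate_at(strata$age_breaks, cfg)
  grid <- tidyr::expand_grid(
    sex = c("female", "male"),
    age_band = strata$age_labels,
    period = strata$period_labels,
    region = names(cfg$regions)
  )
  grid$rate <- band_rate[match(grid$age_band, strata$age_labels)]
  if (!is.null(excluded_group)) {
    pf <- cfg$dist_by_sex$female[excluded_group]
    pm <- cfg$dist_by_sex$male[excluded_group]
    grid$rate <- grid$rate *
      ifelse(grid$sex == "female", 1 - pf, 1 - pm)
  }
  grid$cases <- NA_integer_
  grid$person_years <- NA_real_
  grid$excluded_group <- excluded_group %||% NA_character_
  new_rate_table(grid, excluded_group)
}

#' All rate tables needed by the four SIR variants, from a configuration
#'
#' @param cfg A [synth_config()].
#' @param strata A [strata_def()].
#' @return Named list: `general` plus one excluded-group table per `iarc8`
#'   group, suitable for [estimate_splc_sir()].
#' @export
rate_tables_from_config <- function(cfg, strata = strata_def()) {
  tabs <- c(list(general = rate_table_from_config(cfg, strata)),
            setNames(lapply(cfg$scheme$groups, function(g) {
              rate_table_from_config(cfg, strata, excluded_group = g)
            }), cfg$scheme$groups))
  tabs
}
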