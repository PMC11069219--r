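# Reference incidence-rate tables and expected counts.
#
# The conventional SIR compares a cohort's observed second primaries with the
# expected count E = sum over strata of PY_s * IR_s, where IR_s are general
# population incidence rates. The histology-specific SIR instead uses, for
# index-histology group j, rates IR_ij whose numerator excludes first
# primaries of group j -- the combinations an IARC/IACR registry can never
# record as second primaries.

STRATUM_COLUMNS <- c("sex", "age_band", "period", "region")

#' Compute stratified reference incidence rates
#'
#' Rates are incident first-primary cases per person-year in each sex x
#' age-band x period x region stratum. DCO (death-certificate-only) cases are
#' included in the numerator by default, as registry reference rates include
#' them.
#'
#' @param cases Incident-case tumor records for the reference population
#'   (needs `patient_id`, `sex`, `birth_date`, `diagnosis_date`, `region`,
#'   `morphology`, `dco`; `intprim` when `intprim_only = TRUE`).
#' @param person_time Population denominators: a tibble with the stratum
#'   columns plus `person_years` (e.g. from
#'   [generate_population_denominators()] or an external source).
#' @param strata A [strata_def()].
#' @param dco_included Count DCO cases in the numerator (default `TRUE`)?
#' @param first_primary_only Keep only each patient's earliest case (default
#'   `TRUE`, the general-population comparison); `FALSE` counts all supplied
#'   records.
#' @param intprim_only Restrict the numerator to records flagged `intprim`
#'   (IARC/IACR-countable primaries)?
#' @param excluded_group Optional `iarc8` group excluded from the numerator
#'   (histology-specific rates); see [compute_histology_specific_rates()].
#' @param scheme `iarc8` [histology_scheme()], used when `excluded_group` is
#'   set.
#' @return A `rate_table` tibble: stratum columns plus `cases`,
#'   `person_years`, `rate`, `excluded_group`. Strata with zero denominator
#'   get rate 0 with a warning; negative denominators are an error.
#' @export
compute_reference_rates <- function(cases, person_time, strata = strata_def(),
                                    dco_included = TRUE,
                                    first_primary_only = TRUE,
                                    intprim_only = FALSE,
                                    excluded_group = NULL,
                                    scheme = NULL) {
  check_flag(dco_included, "dco_included")
  check_flag(first_primary_only, "first_primary_only")
  check_columns(person_time, c(STRATUM_COLUMNS, "person_years"), "`person_time`")
  check_columns(cases, c("patient_id", "sex", "birth_date", "diagnosis_date",
                         "region", "morphology", "dco"), "`cases`")
  if (any(person_time$person_years < 0)) abort("Negative person-time denominator.")
  if (first_primary_only) {
    cases <- cases |>
      dplyr::arrange(.data$patient_id, .data$diagnosis_date, .data$morphology) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  }
  if (!dco_included) cases <- cases[!cases$dco, , drop = FALSE]
  if (intprim_only) {
    check_columns(cases, "intprim", "`cases` (with intprim_only = TRUE)")
    cases <- cases[cases$intprim, , drop = FALSE]
  }
  if (!is.null(excluded_group)) {
    scheme <- scheme %||% histology_scheme("iarc8")
    if (!excluded_group %in% scheme$groups) {
      abort(sprintf("Unknown histology group '%s'.", excluded_group))
    }
    grp <- map_morphology(cases$morphology, scheme)
    cases <- cases[grp != excluded_group, , drop = FALSE]
  }
  counts <- if (nrow(cases) == 0) {
    tibble(sex = character(), age_band = character(), period = character(),
           region = character(), cases = integer())
  } else {
    tibble(
      sex = cases$sex,
      age_band = age_band_label(age_completed(cases$birth_date,
                                              cases$diagnosis_date), strata),
      period = period_label(lubridate::year(cases$diagnosis_date), strata,
                            context = "Case diagnosis"),
      region = cases$region
    ) |> dplyr::count(.data$sex, .data$age_band, .data$period, .data$region,
                      name = "cases")
  }
  denom <- person_time |>
    dplyr::group_by(dplyr::across(dplyr::all_of(STRATUM_COLUMNS))) |>
    dplyr::summarise(person_years = sum(.data$person_years), .groups = "drop")
  out <- dplyr::left_join(denom, counts, by = STRATUM_COLUMNS)
  out$cases[is.na(out$cases)] <- 0L
  zero <- out$person_years == 0
  if (any(zero & out$cases > 0)) {
    abort("Stratum with cases but zero person-time denominator.")
  }
  if (any(zero)) {
    warn(sprintf("%d stratum/strata with zero denominator; rate set to 0.",
                 sum(zero)))
  }
  out$rate <- ifelse(zero, 0, out$cases / out$person_years)
  out$excluded_group <- excluded_group %||% NA_character_
  new_rate_table(out, excluded_group, dco_included)
}

new_rate_table <- function(df, excluded_group, dco_included = TRUE) {
  attr(df, "excluded_group") <- excluded_group %||% NA_character_
  attr(df, "dco_included") <- dco_included
  class(df) <- c("rate_table", setdiff(class(df), "rate_table"))
  df
}

#' Histology-specific reference rates excluding one group
#'
#' Identical to [compute_reference_rates()] except that first primaries whose
#' `iarc8` group equals `excluded_group` are removed from the numerator (the
#' denominator is unchanged), giving the rates IR_ij used by the
#' histology-specific SIR for index group j.
#'
#' @inheritParams compute_reference_rates
#' @param excluded_group The `iarc8` group to exclude (required).
#' @export
compute_histology_specific_rates <- function(cases, person_time,
                                             strata = strata_def(),
                                             excluded_group,
                                             scheme = histology_scheme("iarc8"),
                                             dco_included = TRUE,
                                             first_primary_only = TRUE,
                                             intprim_only = FALSE) {
  if (missing(excluded_group) || is.null(excluded_group)) {
    abort("`excluded_group` is required.")
  }
  compute_reference_rates(cases, person_time, strata,
                          dco_included = dco_included,
                          first_primary_only = first_primary_only,
                          intprim_only = intprim_only,
                          excluded_group = excluded_group, scheme = scheme)
}

#' Expected event count from person-time and reference rates
#'
#' `E = sum over strata of PY_s * IR_s`. Every person-time stratum must have
#' a matching rate stratum. When the person-time table carries a single
#' index-histology group j (the histology-specific wiring), the rate table
#' must have been built with `excluded_group = j`; a mismatch is an error.
#'
#' @param pt A `person_time_table` (see [tabulate_person_time()]).
#' @param rates A `rate_table`.
#' @return A list: `total` (the expected count E) and `by_stratum` (tibble of
#'   per-stratum contributions).
#' @export
expected_count <- function(pt, rates) {
  check_columns(pt, c(STRATUM_COLUMNS, "person_years"), "`pt`")
  check_columns(rates, c(STRATUM_COLUMNS, "rate"), "`rates`")
  excl <- attr(rates, "excluded_group") %||% NA_character_
  if ("index_histology" %in% names(pt)) {
    grp <- unique(pt$index_histology)
    if (length(grp) > 1L) {
      abort("`pt` mixes several index-histology groups; compute E per group.")
    }
    if (grp != "all" && (is.na(excl) || excl != grp)) {
      abort(sprintf(paste0("Person-time is for index group '%s' but the rate ",
                           "table excludes '%s'; the histology-specific SIR ",
                           "requires matching tables."), grp, excl))
    }
    if (grp == "all" && !is.na(excl)) {
      abort("General person-time paired with a histology-specific rate table.")
    }
  }
  rtab <- as_tibble(rates)[, c(STRATUM_COLUMNS, "rate")]
  joined <- dplyr::left_join(as_tibble(pt), rtab, by = STRATUM_COLUMNS)
  if (any(is.na(joined$rate))) {
    miss <- joined[is.na(joined$rate), STRATUM_COLUMNS]
    miss <- apply(utils::head(miss, 5L), 1L, paste, collapse = "/")
    abort(sprintf("No reference rate for person-time stratum/strata: %s%s",
                  paste(miss, collapse = "; "),
                  if (sum(is.na(joined$rate)) > 5) " ..." else ""))
  }
  joined$expected <- joined$person_years * joined$rate
  list(total = sum(joined$expected), by_stratum = joined)
}

#' Write / read a rate table as delimited text
#'
#' Numeric columns are written with full (shortest round-trip) precision so a
#' round trip reproduces expected counts bit-identically.
#'
#' @param rates A `rate_table`.
#' @param path File path.
#' @param delim Delimiter (default tab).
#' @export
write_rate_table <- function(rates, path, delim = "\t") {
  df <- as_tibble(rates)
  df$dco_included <- attr(rates, "dco_included") %||% TRUE
  # 17 significant digits guarantee a bit-identical double round trip
  for (col in c("rate", "person_years")) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  readr::write_delim(df, path, delim = delim, na = "NA")
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, na = "NA",
                          col_types = readr::cols(
                            cases = readr::col_integer(),
                            dco_included = readr::col_logical(),
                            .default = readr::col_character()))
  # base-R strtod is correctly rounded, preserving the %.17g round trip
  for (col in c("rate", "person_years")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  excl <- unique(df$excluded_group)
  dco <- if ("dco_included" %in% names(df)) df$dco_included[1] else TRUE
  df$dco_included <- NULL
  if (length(excl) != 1L) abort("Rate table mixes excluded_group values.")
  new_rate_table(df, if (is.na(excl)) NULL else excl, dco)
}
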