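# Standardized incidence ratios with exact Poisson confidence intervals.
#
# Four variants of the SIR for same-site second primaries:
#   sir1_raw     observed events / expected from general reference rates
#   sir2_sub     stratified by index-histology group; same-group events are
#                not counted as observed, and the reference rates for index
#                group j exclude group j from their numerator
#   sir3_iarc    sir1_raw restricted to IARC/IACR-countable (intprim) events
#                and rates
#   sir4_subiarc sir2_sub with the same intprim restriction
# Totals pool O and E across cells before dividing (never averages of
# ratios).

SIR_VARIANTS <- c("sir1_raw", "sir2_sub", "sir3_iarc", "sir4_subiarc")

#' Exact Poisson confidence interval for an SIR
#'
#' The Breslow–Day exact interval for O observed events given E expected:
#' `low = qchisq((1-level)/2, 2*O) / (2*E)` (0 when `O = 0`) and
#' `high = qchisq(1-(1-level)/2, 2*(O+1)) / (2*E)`.
#'
#' @param o Observed count(s), non-negative integers.
#' @param e Expected count(s), positive.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `ci_low`, `ci_high` (one row per element).
#' @examples
#' poisson_exact_ci(10, 10)  # approx (0.4795, 1.8390)
#' @export
poisson_exact_ci <- function(o, e, level = 0.95) {
  if (any(e <= 0)) abort("`e` must be positive.")
  if (any(o < 0) || any(o != round(o))) abort("`o` must be non-negative integers.")
  check_number(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  alpha <- 1 - level
  low <- ifelse(o == 0, 0, qchisq(alpha / 2, 2 * o) / (2 * e))
  high <- qchisq(1 - alpha / 2, 2 * (o + 1)) / (2 * e)
  tibble(ci_low = low, ci_high = high)
}

# Assemble SIR rows (point estimate + CI) from an O/E cell table.
sir_rows <- function(cells, variant, level) {
  bad <- cells$E == 0 & cells$O > 0
  if (any(bad)) {
    abort(sprintf("%d cell(s) with observed events but zero expected count; %s",
                  sum(bad), "the rate/person-time wiring is inconsistent."))
  }
  empty <- cells$E == 0
  if (any(empty)) {
    warn(sprintf("%d cell(s) with E = 0 and O = 0 omitted.", sum(empty)))
    cells <- cells[!empty, , drop = FALSE]
  }
  ci <- poisson_exact_ci(cells$O, cells$E, level)
  tibble(variant = variant, sex = cells$sex, stratum_label = cells$stratum_label,
         O = as.integer(cells$O), E = cells$E, sir = cells$O / cells$E,
         ci_low = ci$ci_low, ci_high = ci$ci_high, level = level)
}

#' Estimate SIR variants from counted events, person-time and rates
#'
#' The low-level estimator: takes an already-selected cohort, its counted
#' second-primary events, tabulated person-time and reference rates, and
#' returns per-cell and pooled SIRs. Most analyses should use
#' [estimate_splc_sir()], which wires these pieces per variant.
#'
#' @param cohort Index cases with `patient_id`, `sex` and `group` (index
#'   `iarc8` group).
#' @param events Counted second-primary events: `patient_id`, `group` (event
#'   `iarc8` group); `intprim` required for the `*_iarc` variants; `fu_band`
#'   (matching the person-time table) for follow-up stratification.
#' @param person_time A `person_time_table`; must carry `index_histology`
#'   groups for the `*_sub` variants and `"all"` otherwise.
#' @param rates A `rate_table` for `sir1_raw`/`sir3_iarc`, or a named list of
#'   rate tables keyed by index group (each built with that
#'   `excluded_group`) for `sir2_sub`/`sir4_subiarc`.
#' @param variant One of `"sir1_raw"`, `"sir2_sub"`, `"sir3_iarc"`,
#'   `"sir4_subiarc"`.
#' @param scheme `iarc8` [histology_scheme()] (identifies the wildcard
#'   unspecified group).
#' @param level Confidence level (default 0.95).
#' @param include_unspecified Keep the unspecified index-histology stratum in
#'   the `*_sub` variants (default `TRUE`)? With `FALSE`, wildcard index
#'   groups are dropped from both O and E.
#' @return A tibble of SIR results: `variant`, `sex`, `stratum_label`
#'   (index-group / follow-up cell, `"total"` for pooled rows; sex `"all"`
#'   pools both sexes), `O`, `E`, `sir`, `ci_low`, `ci_high`, `level`.
#' @export
estimate_sir <- function(cohort, events, person_time, rates,
                         variant = SIR_VARIANTS,
                         scheme = histology_scheme("iarc8"),
                         level = 0.95, include_unspecified = TRUE) {
  variant <- match.arg(variant)
  sub <- variant %in% c("sir2_sub", "sir4_subiarc")
  iarc <- variant %in% c("sir3_iarc", "sir4_subiarc")
  check_columns(cohort, c("patient_id", "sex", "group"), "`cohort`")
  check_columns(events, c("patient_id", "group"), "`events`")
  pt <- person_time

  if (iarc) {
    check_columns(events, "intprim", "`events` (iarc variant)")
    events <- events[events$intprim, , drop = FALSE]
  }
  events <- dplyr::left_join(
    events,
    dplyr::select(cohort, "patient_id", index_group = "group"),
    by = "patient_id")
  if (any(is.na(events$index_group))) {
    abort("Event(s) for patients absent from the cohort.")
  }
  if (sub) {
    if (!"index_histology" %in% names(pt) ||
        identical(unique(pt$index_histology), "all")) {
      abort("The *_sub variants need person-time tabulated by index histology.")
    }
    if (!is.list(rates) || inherits(rates, "rate_table")) {
      abort("The *_sub variants need a named list of per-group rate tables.")
    }
    # same-group second primaries are not counted as observed
    events <- events[events$group != events$index_group, , drop = FALSE]
    if (!include_unspecified) {
      keep <- !(pt$index_histology %in% scheme$wildcard_groups)
      pt <- pt[keep, , drop = FALSE]
      events <- events[!(events$index_group %in% scheme$wildcard_groups), ,
                       drop = FALSE]
    }
  } else if ("index_histology" %in% names(pt) &&
             !identical(unique(pt$index_histology), "all")) {
    abort("The raw variants need person-time without the histology dimension.")
  }

  by_fu <- "fu_band" %in% names(pt)
  if (by_fu) check_columns(events, "fu_band", "`events` (follow-up strata)")
  ev_sex <- dplyr::left_join(
    dplyr::select(events, -dplyr::any_of("sex")),
    dplyr::distinct(cohort, .data$patient_id, .data$sex), by = "patient_id")

  cell_cols <- c("sex", if (sub) "index_group", if (by_fu) "fu_band")
  o_tab <- dplyr::count(ev_sex, dplyr::across(dplyr::all_of(cell_cols)), name = "O")

  # expected counts per cell
  pt_cols <- c("sex", if (sub) "index_histology", if (by_fu) "fu_band")
  e_tab <- if (sub) {
    dplyr::bind_rows(lapply(unique(pt$index_histology), function(g) {
      if (is.null(rates[[g]])) {
        abort(sprintf("No rate table supplied for index group '%s'.", g))
      }
      ec <- expected_count(pt[pt$index_histology == g, , drop = FALSE],
                           rates[[g]])
      ec$by_stratum |>
        dplyr::group_by(dplyr::across(dplyr::all_of(pt_cols))) |>
        dplyr::summarise(E = sum(.data$expected), .groups = "drop")
    }))
  } else {
    expected_count(pt, rates)$by_stratum |>
      dplyr::group_by(dplyr::across(dplyr::all_of(pt_cols))) |>
      dplyr::summarise(E = sum(.data$expected), .groups = "drop")
  }
  if (sub) e_tab <- dplyr::rename(e_tab, index_group = "index_histology")

  cells <- dplyr::left_join(e_tab, o_tab, by = cell_cols)
  cells$O[is.na(cells$O)] <- 0L
  lab_cols <- setdiff(cell_cols, "sex")
  cells$stratum_label <- if (length(lab_cols) == 0) "total" else {
    do.call(paste, c(unname(as.list(cells[, lab_cols, drop = FALSE])), sep = " / "))
  }

  out <- sir_rows(cells, variant, level)
  # pooled rows: per-sex totals (when stratified), then both sexes combined
  if (length(lab_cols) > 0) {
    tot <- cells |>
      dplyr::group_by(.data$sex) |>
      dplyr::summarise(O = sum(.data$O), E = sum(.data$E), .groups = "drop") |>
      dplyr::mutate(stratum_label = "total")
    out <- dplyr::bind_rows(out, sir_rows(tot, variant, level))
  }
  all_tot <- cells |>
    dplyr::summarise(O = sum(.data$O), E = sum(.data$E)) |>
    dplyr::mutate(sex = "all", stratum_label = "total")
  dplyr::bind_rows(out, sir_rows(all_tot, variant, level))
}

#' One-call second-primary SIR analysis on registry records
#'
#' Runs the full pipeline: cohort selection, INTPRIM annotation, event
#' counting (a patient's first registered same-site second primary at or
#' after the landmark), at-risk intervals censored at the first counted
#' event, person-time tabulation, and [estimate_sir()] for each requested
#' variant.
#'
#' @param records Tumor-record tibble (all tumors).
#' @param cfg A [cohort_config()].
#' @param strata A [strata_def()]; give `followup_breaks` for
#'   follow-up-window stratification.
#' @param scheme `iarc8` [histology_scheme()].
#' @param rates Reference rates: a single general `rate_table` (raw/iarc
#'   variants only) or a named list with element `general` plus one
#'   `rate_table` per index group built with that `excluded_group`.
#' @param rates_iarc Rates for the `*_iarc` variants when they differ (e.g.
#'   numerators restricted to intprim records); defaults to `rates`.
#' @param variants Character vector of variants to compute.
#' @param level,include_unspecified Passed to [estimate_sir()].
#' @return A tibble of SIR results for all requested variants.
#' @export
estimate_splc_sir <- function(records, cfg = cohort_config(),
                              strata = strata_def(),
                              scheme = histology_scheme("iarc8"),
                              rates, rates_iarc = rates,
                              variants = "sir1_raw",
                              level = 0.95, include_unspecified = TRUE) {
  variants <- match.arg(variants, SIR_VARIANTS, several.ok = TRUE)
  if (inherits(rates, "rate_table")) rates <- list(general = rates)
  if (inherits(rates_iarc, "rate_table")) rates_iarc <- list(general = rates_iarc)
  if (is.null(rates$general)) abort("`rates` must contain a 'general' table.")

  need_iarc <- any(variants %in% c("sir3_iarc", "sir4_subiarc"))
  records <- annotate_international_primaries(records, scheme)
  fc <- filter_analysis_cohort(records, cfg)
  cohort <- fc$cohort
  cohort$group <- map_morphology(cohort$morphology, scheme)
  if (nrow(cohort) == 0) abort("Cohort selection retained no index cases.")

  # candidate events: same-site tumors at/after the landmark
  idx <- dplyr::select(cohort, "patient_id",
                       index_date = "diagnosis_date")
  subsequent <- records |>
    dplyr::filter(startsWith(.data$site, cfg$index_site_prefix)) |>
    dplyr::inner_join(idx, by = "patient_id") |>
    dplyr::filter(.data$diagnosis_date > .data$index_date) |>
    dplyr::mutate(group = map_morphology(.data$morphology, scheme))
  landmark <- idx$index_date %m+% months(cfg$landmark_months)
  subsequent <- subsequent[
    subsequent$diagnosis_date >=
      landmark[match(subsequent$patient_id, idx$patient_id)], , drop = FALSE]

  run_family <- function(ev_pool, variant_set, rate_set) {
    first_ev <- ev_pool |>
      dplyr::arrange(.data$patient_id, .data$diagnosis_date, .data$morphology) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
    with_iv <- at_risk_interval(
      cohort, dplyr::select(first_ev, "patient_id", "diagnosis_date"), cfg)
    counted <- first_ev[
      first_ev$patient_id %in% with_iv$patient_id[with_iv$end_reason == "splc"], ,
      drop = FALSE]
    if (!is.null(strata$followup_breaks)) {
      st <- with_iv$start[match(counted$patient_id, with_iv$patient_id)]
      off <- as.integer(counted$diagnosis_date) - as.integer(st)
      fi <- findInterval(off, round(strata$followup_breaks * DAYS_PER_YEAR))
      counted$fu_band <- strata$fu_labels[pmin(pmax(fi, 1L),
                                               length(strata$fu_labels))]
    }
    dplyr::bind_rows(lapply(variant_set, function(v) {
      sub <- v %in% c("sir2_sub", "sir4_subiarc")
      pt <- tabulate_person_time(with_iv, strata, by_histology = sub)
      r <- if (sub) rate_set[names(rate_set) != "general"] else rate_set$general
      estimate_sir(cohort, counted, pt, r, variant = v, scheme = scheme,
                   level = level, include_unspecified = include_unspecified)
    }))
  }

  out <- list()
  plain <- intersect(variants, c("sir1_raw", "sir2_sub"))
  if (length(plain) > 0) out <- c(out, list(run_family(subsequent, plain, rates)))
  iarcv <- intersect(variants, c("sir3_iarc", "sir4_subiarc"))
  if (length(iarcv) > 0) {
    out <- c(out, list(run_family(subsequent[subsequent$intprim, , drop = FALSE],
                                  iarcv, rates_iarc)))
  }
  dplyr::bind_rows(out)
}
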