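# Person-time at risk: per-case at-risk intervals, and tabulation of
# person-years into sex x age-band x period x region (x index-histology)
# strata by splitting each interval at every band-boundary birthday and
# calendar-period boundary. Durations are whole days / 365.25; age bands are
# left-closed and a band transition occurs on the birthday itself.

#' Stratum definitions for person-time and rate tables
#'
#' @param age_breaks Increasing lower bounds of age bands in years; the last
#'   band is open-ended (default 5-year bands `0-4` ... `85+`).
#' @param period_breaks Increasing calendar-year cut points; bands are
#'   `[b_i, b_{i+1})` and any date outside `[min, max)` is an error where
#'   period assignment is required (default `2000, 2005, 2010, 2015`).
#' @param followup_breaks Optional increasing cut points (years since start
#'   of at-risk time, starting at 0) adding a follow-up-window dimension.
#' @return A `strata_def` list with the breaks and their band labels.
#' @export
strata_def <- function(age_breaks = seq(0, 85, by = 5),
                       period_breaks = c(2000L, 2005L, 2010L, 2015L),
                       followup_breaks = NULL) {
  stopifnot(length(age_breaks) >= 1, !is.unsorted(age_breaks, strictly = TRUE),
            all(age_breaks == round(age_breaks)),
            length(period_breaks) >= 2, !is.unsorted(period_breaks, strictly = TRUE))
  if (!is.null(followup_breaks)) {
    stopifnot(length(followup_breaks) >= 2,
              !is.unsorted(followup_breaks, strictly = TRUE),
              followup_breaks[1] >= 0)
  }
  age_labels <- c(if (length(age_breaks) > 1) {
    paste0(sprintf("%02d", utils::head(age_breaks, -1)), "-",
           sprintf("%02d", age_breaks[-1] - 1))
  }, paste0(utils::tail(age_breaks, 1), "+"))
  period_labels <- paste0(utils::head(period_breaks, -1), "-",
                          period_breaks[-1] - 1)
  fu_labels <- if (is.null(followup_breaks)) NULL else {
    paste0(utils::head(followup_breaks, -1), "-", followup_breaks[-1], "y")
  }
  structure(list(age_breaks = age_breaks, age_labels = age_labels,
                 period_breaks = as.integer(period_breaks),
                 period_labels = period_labels,
                 followup_breaks = followup_breaks, fu_labels = fu_labels),
            class = "strata_def")
}

age_band_label <- function(age, strata) {
  strata$age_labels[findInterval(age, strata$age_breaks)]
}

period_label <- function(year, strata, context = "date") {
  i <- findInterval(year, strata$period_breaks)
  out_of_range <- i < 1L | i >= length(strata$period_breaks)
  if (any(out_of_range)) {
    abort(sprintf("%s outside all period bands (years: %s).", context,
                  paste(unique(year[out_of_range]), collapse = ", ")))
  }
  strata$period_labels[i]
}

#' Compute per-case at-risk intervals
#'
#' At-risk time starts `landmark_months` after diagnosis and ends at the
#' earliest of: the first counted second-primary event, the vital-status date
#' for deceased patients, the end of study follow-up, and
#' `max_followup_years` after diagnosis. Ties are labelled with that priority
#' (`"splc"`, `"death"`, `"study_end"`, `"max_followup"`).
#'
#' @param cohort Index cases (output of [filter_analysis_cohort()]).
#' @param events Optional tibble of counted second-primary events
#'   (`patient_id`, `diagnosis_date`); only each patient's earliest event is
#'   used. An event before a patient's at-risk start is an error.
#' @param cfg The [cohort_config()] used to select the cohort.
#' @return `cohort` with added `start`, `end` (`Date`) and `end_reason`
#'   columns.
#' @export
at_risk_interval <- function(cohort, events = NULL, cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  check_columns(cohort, c("patient_id", "diagnosis_date", "vital_status",
                          "vital_status_date"), "`cohort`")
  start <- cohort$diagnosis_date %m+% months(cfg$landmark_months)
  max_fu_date <- if (abs(cfg$max_followup_years - round(cfg$max_followup_years)) < 1e-9) {
    cohort$diagnosis_date %m+% months(12L * as.integer(round(cfg$max_followup_years)))
  } else {
    cohort$diagnosis_date + round(cfg$max_followup_years * DAYS_PER_YEAR)
  }
  death_date <- cohort$vital_status_date
  death_date[cohort$vital_status != "dead"] <- NA
  event_date <- rep(as.Date(NA), nrow(cohort))
  if (!is.null(events) && nrow(events) > 0) {
    check_columns(events, c("patient_id", "diagnosis_date"), "`events`")
    first_ev <- events |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(event_date = min(.data$diagnosis_date), .groups = "drop")
    event_date <- first_ev$event_date[match(cohort$patient_id, first_ev$patient_id)]
    if (any(!is.na(event_date) & event_date < start)) {
      abort("Counted event before at-risk start for at least one patient.")
    }
  }
  # earliest bound wins; on ties the reason priority is splc > death >
  # study_end > max_followup
  bounds <- cbind(as.numeric(event_date), as.numeric(death_date),
                  as.numeric(cfg$followup_end), as.numeric(max_fu_date))
  reasons <- c("splc", "death", "study_end", "max_followup")
  bounds[is.na(bounds)] <- Inf
  pick <- max.col(-bounds, ties.method = "first")
  end <- as.Date(bounds[cbind(seq_len(nrow(bounds)), pick)],
                 origin = "1970-01-01")
  cohort$start <- start
  cohort$end <- end
  cohort$end_reason <- reasons[pick]
  cohort
}

#' Tabulate person-years at risk into strata
#'
#' Each at-risk interval is split at every age-band birthday, calendar-period
#' boundary and (optionally) follow-up-window boundary; fragments accrue to
#' the stratum of their start date. The table total equals the summed
#' interval lengths exactly (conservation), and refining bands never changes
#' the total.
#'
#' @param cohort Index cases with `start`/`end` columns (see
#'   [at_risk_interval()]) plus `sex`, `birth_date`, `region`, and `group`
#'   (the index iarc8 histology group) when `by_histology = TRUE`.
#' @param strata A [strata_def()].
#' @param by_histology Keep the index-histology dimension (needed by the
#'   histology-specific SIR)?
#' @return A `person_time_table` tibble: stratum columns (`sex`, `age_band`,
#'   `period`, `region`, `index_histology`, optionally `fu_band`) plus
#'   `person_years`; attribute `cohort_size` records the number of cases.
#' @export
tabulate_person_time <- function(cohort, strata = strata_def(),
                                 by_histology = FALSE) {
  stopifnot(inherits(strata, "strata_def"))
  need <- c("sex", "birth_date", "region", "start", "end")
  if (by_histology) need <- c(need, "group")
  check_columns(cohort, need, "`cohort`")
  cohort <- cohort[cohort$end > cohort$start, , drop = FALSE]
  n <- nrow(cohort)
  if (n == 0) {
    out <- tibble(sex = character(), age_band = character(),
                  period = character(), region = character(),
                  index_histology = character(), person_years = numeric())
    attr(out, "cohort_size") <- 0L
    class(out) <- c("person_time_table", class(out))
    return(out)
  }
  start_i <- as.integer(cohort$start)
  end_i <- as.integer(cohort$end)
  birth_parts <- civil_from_days(as.integer(cohort$birth_date))

  # candidate split dates: band-boundary birthdays ...
  ages <- strata$age_breaks[strata$age_breaks > 0]
  case_id <- rep(seq_len(n), times = length(ages))
  ann <- days_from_civil(rep(birth_parts$year, times = length(ages)) +
                           rep(as.integer(ages), each = n),
                         rep(birth_parts$month, times = length(ages)),
                         rep(birth_parts$day, times = length(ages)))
  # ... calendar-period boundaries ...
  yrs <- strata$period_breaks
  case_id <- c(case_id, rep(seq_len(n), times = length(yrs)))
  jan1 <- rep(days_from_civil(yrs, 1L, 1L), each = n)
  splits <- c(ann, jan1)
  # ... and follow-up-window boundaries (day offsets from start).
  if (!is.null(strata$followup_breaks)) {
    fb <- strata$followup_breaks
    fb_days <- round(fb * DAYS_PER_YEAR)
    case_id <- c(case_id, rep(seq_len(n), times = length(fb_days)))
    splits <- c(splits, rep(start_i, times = length(fb_days)) +
                  rep(fb_days, each = n))
  }
  inside <- splits > start_i[case_id] & splits < end_i[case_id]
  case_id <- c(case_id[inside], seq_len(n))
  splits <- c(splits[inside], start_i)

  ord <- order(case_id, splits)
  case_id <- case_id[ord]
  frag_start <- splits[ord]
  dup <- c(FALSE, diff(case_id) == 0 & diff(frag_start) == 0)
  case_id <- case_id[!dup]
  frag_start <- frag_start[!dup]
  last <- c(diff(case_id) != 0, TRUE)
  frag_end <- ifelse(last, end_i[case_id], c(frag_start[-1], 0L))

  fs_parts <- civil_from_days(frag_start)
  bm <- birth_parts$month[case_id]
  bd <- birth_parts$day[case_id]
  age <- fs_parts$year - birth_parts$year[case_id] -
    ((fs_parts$month < bm) | (fs_parts$month == bm & fs_parts$day < bd))
  key <- tibble(
    sex = cohort$sex[case_id],
    age_band = age_band_label(age, strata),
    period = period_label(fs_parts$year, strata, context = "At-risk time"),
    region = cohort$region[case_id],
    index_histology = if (by_histology) cohort$group[case_id] else "all",
    person_years = days_to_years(frag_end - frag_start)
  )
  if (!is.null(strata$followup_breaks)) {
    off <- frag_start - start_i[case_id]
    fi <- findInterval(off, round(strata$followup_breaks * DAYS_PER_YEAR))
    if (any(fi < 1L | fi >= length(strata$followup_breaks))) {
      abort("At-risk time outside all follow-up windows.")
    }
    key$fu_band <- strata$fu_labels[fi]
  }
  out <- key |>
    dplyr::group_by(dplyr::across(-dplyr::all_of("person_years"))) |>
    dplyr::summarise(person_years = sum(.data$person_years), .groups = "drop")
  attr(out, "cohort_size") <- n
  attr(out, "strata") <- strata
  class(out) <- c("person_time_table", class(out))
  out
}

#' Write / read a person-time table as delimited text
#' @param pt A `person_time_table`.
#' @param path File path.
#' @param delim Delimiter (default tab).
#' @return `read_person_time_table()` returns the table; cohort size is
#'   stored in a `# cohort_size:` header comment.
#' @export
write_person_time_table <- function(pt, path, delim = "\t") {
  writeLines(sprintf("# cohort_size: %d", attr(pt, "cohort_size") %||% NA_integer_),
             path)
  df <- as_tibble(pt)
  df$person_years <- sprintf("%.17g", df$person_years)
  readr::write_delim(df, path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' @rdname write_person_time_table
#' @export
read_person_time_table <- function(path, delim = "\t") {
  first <- readLines(path, n = 1L)
  out <- readr::read_delim(path, delim = delim, comment = "#",
                           col_types = readr::cols(
                             .default = readr::col_character()))
  out$person_years <- as.numeric(out$person_years)
  attr(out, "cohort_size") <- as.integer(sub(".*cohort_size: *", "", first))
  class(out) <- c("person_time_table", class(out))
  out
}
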