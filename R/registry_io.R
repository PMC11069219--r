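# Tumor-record data model, flat-file I/O, and cohort selection.
#
# A tumor record is one registered tumor: patient id, sex, birth and diagnosis
# dates, ICD-10 site, ICD-O-3 morphology (4 digits) + behavior digit, region,
# DCO flag, laterality, vital status and vital-status date. The flat-file
# dialect is delimited text (comma by default, tab accepted), UTF-8, header
# row, ISO-8601 dates, missing-value token "".

TUMOR_COLUMNS <- c("patient_id", "sex", "birth_date", "diagnosis_date", "site",
                   "morphology", "region", "dco", "laterality",
                   "vital_status", "vital_status_date")

#' Cohort-selection configuration
#'
#' Defaults reproduce a lung-cancer (ICD-10 C34) survivor cohort: diagnoses
#' 2002-2013, a 6-month survival landmark, follow-up ending 2014-12-31 with at
#' most 13 years per case, and exclusion of morphology codes that are likely
#' miscoded metastases (8263, 8290, 8720, 8815, 8933, 9050, 9133).
#'
#' @param index_site_prefix ICD-10 prefix selecting index tumors.
#' @param diagnosis_period Two diagnosis years `c(min, max)`, inclusive.
#' @param landmark_months Post-diagnosis survival (months) required for
#'   inclusion; also the start offset of the at-risk interval.
#' @param followup_end Last date of follow-up (`Date` or ISO string).
#' @param max_followup_years Maximum years of follow-up per case.
#' @param excluded_morphologies Integer morphology codes excluded as index
#'   cases.
#' @param age_range Optional `c(min, max)` completed age at diagnosis; `NULL`
#'   (default) applies no age exclusion.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(index_site_prefix = "C34",
                          diagnosis_period = c(2002L, 2013L),
                          landmark_months = 6L,
                          followup_end = as.Date("2014-12-31"),
                          max_followup_years = 13,
                          excluded_morphologies = c(8263L, 8290L, 8720L, 8815L,
                                                    8933L, 9050L, 9133L),
                          age_range = NULL) {
  stopifnot(is.character(index_site_prefix), length(index_site_prefix) == 1L)
  if (length(diagnosis_period) != 2L || diagnosis_period[1] > diagnosis_period[2]) {
    abort("`diagnosis_period` must be c(year_min, year_max) with min <= max.")
  }
  check_number(landmark_months, "landmark_months", lower = 0)
  check_number(max_followup_years, "max_followup_years", lower = 1e-9)
  followup_end <- as.Date(followup_end)
  if (!is.null(age_range)) {
    if (length(age_range) != 2L || age_range[1] > age_range[2]) {
      abort("`age_range` must be c(min, max) with min <= max, or NULL.")
    }
  }
  structure(
    list(index_site_prefix = index_site_prefix,
         diagnosis_period = as.integer(diagnosis_period),
         landmark_months = as.integer(landmark_months),
         followup_end = followup_end,
         max_followup_years = max_followup_years,
         excluded_morphologies = as.integer(excluded_morphologies),
         age_range = age_range),
    class = "cohort_config"
  )
}

#' Read tumor records from a delimited text file
#'
#' Rows with an unparseable date, an invalid sex code, or an out-of-range
#' morphology are rejected (not read into the result) and logged with their
#' line number in the parse report; a missing mandatory column is a hard
#' error. Extra columns (e.g. `intprim`) are passed through.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) tries comma, then tab.
#' @return A tibble of tumor records in file order, with a parse report
#'   attached as attribute `"parse_report"` (see [parse_report()]).
#' @export
read_tumor_records <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()))
  check_columns(raw, TUMOR_COLUMNS, sprintf("'%s'", path))

  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  note <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }
  sex <- raw$sex
  note(!(sex %in% c("female", "male")), "invalid_sex")
  parse_date <- function(x, col) {
    d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
    note(is.na(d), paste0("invalid_", col))
    d
  }
  birth_date <- parse_date(raw$birth_date, "birth_date")
  diagnosis_date <- parse_date(raw$diagnosis_date, "diagnosis_date")
  vital_status_date <- parse_date(raw$vital_status_date, "vital_status_date")
  morphology <- suppressWarnings(as.integer(raw$morphology))
  note(is.na(morphology) | morphology < 8000L | morphology > 9993L,
       "invalid_morphology")
  behavior <- if ("behavior" %in% names(raw)) {
    suppressWarnings(as.integer(raw$behavior))
  } else rep(3L, n)
  dco <- toupper(trimws(raw$dco)) %in% c("TRUE", "T", "1", "YES")
  vital_status <- raw$vital_status
  note(!(vital_status %in% c("alive", "dead")), "invalid_vital_status")
  laterality <- raw$laterality
  laterality[is.na(laterality) | laterality == ""] <- "unknown"
  note(!(laterality %in% c("left", "right", "bilateral", "unknown")),
       "invalid_laterality")

  keep <- is.na(reason)
  records <- tibble(
    patient_id = raw$patient_id[keep],
    sex = sex[keep],
    birth_date = birth_date[keep],
    diagnosis_date = diagnosis_date[keep],
    site = raw$site[keep],
    morphology = morphology[keep],
    behavior = behavior[keep],
    region = raw$region[keep],
    dco = dco[keep],
    laterality = laterality[keep],
    vital_status = vital_status[keep],
    vital_status_date = vital_status_date[keep]
  )
  extra <- setdiff(names(raw), c(TUMOR_COLUMNS, "behavior"))
  for (col in extra) {
    records[[col]] <- utils::type.convert(raw[[col]][keep], as.is = TRUE)
  }
  rejects <- tibble(line = which(!keep) + 1L, reason = reason[!keep])
  attr(records, "parse_report") <- list(
    rows_read = n, rows_kept = sum(keep), rows_rejected = sum(!keep),
    rejects = rejects
  )
  records
}

#' Parse report of [read_tumor_records()]
#' @param records Result of [read_tumor_records()].
#' @return A list: `rows_read`, `rows_kept`, `rows_rejected`, and a `rejects`
#'   tibble (`line`, `reason`).
#' @export
parse_report <- function(records) attr(records, "parse_report")

#' Write tumor records to a delimited text file
#'
#' Inverse of [read_tumor_records()]: dates are written ISO-8601 and a
#' write-then-read round trip reproduces the record collection.
#'
#' @param records Tumor-record tibble.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @export
write_tumor_records <- function(records, path, delim = ",") {
  check_columns(records, TUMOR_COLUMNS, "`records`")
  readr::write_delim(records, path, delim = delim, na = "")
  invisible(path)
}

# Exclusion reasons, in the fixed precedence order used for the audit log.
EXCLUSION_REASONS <- c("site", "period", "unusual_morphology", "dco",
                       "landmark", "age")

#' Select the analysis cohort of index cases
#'
#' For each patient the earliest tumor matching `index_site_prefix` (earliest
#' overall when none matches) is the candidate index case. A candidate is
#' retained when its site matches, the diagnosis year lies in
#' `diagnosis_period`, its morphology is not in `excluded_morphologies`, it
#' is not a death-certificate-only (DCO) diagnosis, the patient survived at
#' least `landmark_months` after diagnosis, and (if configured) age at
#' diagnosis lies in `age_range`. Each excluded candidate carries exactly one
#' reason: the first failing rule in the fixed order site, period,
#' unusual_morphology, dco, landmark, age.
#'
#' @param records Tumor-record tibble (all tumors, all patients).
#' @param cfg A [cohort_config()].
#' @return A list: `cohort` (retained index cases) and `exclusions` (tibble
#'   `patient_id`, `reason`). Together they partition the candidate set.
#' @export
filter_analysis_cohort <- function(records, cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  check_columns(records, TUMOR_COLUMNS, "`records`")
  if (nrow(records) == 0) {
    warn("Empty record collection; empty cohort returned.")
    return(list(cohort = records,
                exclusions = tibble(patient_id = character(), reason = character())))
  }
  is_index_site <- startsWith(records$site, cfg$index_site_prefix)
  cand <- records |>
    dplyr::mutate(.row = dplyr::row_number(), .site_ok = is_index_site) |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$.site_ok),
                   .data$diagnosis_date, .data$morphology, .data$.row) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)

  dx_year <- lubridate::year(cand$diagnosis_date)
  landmark_date <- cand$diagnosis_date %m+% months(cfg$landmark_months)
  age_dx <- age_completed(cand$birth_date, cand$diagnosis_date)

  reason <- rep(NA_character_, nrow(cand))
  fail <- function(bad, why) reason[bad & is.na(reason)] <<- why
  fail(!cand$.site_ok, "site")
  fail(dx_year < cfg$diagnosis_period[1] | dx_year > cfg$diagnosis_period[2], "period")
  fail(cand$morphology %in% cfg$excluded_morphologies, "unusual_morphology")
  fail(cand$dco, "dco")
  fail(cand$vital_status_date < landmark_date, "landmark")
  if (!is.null(cfg$age_range)) {
    fail(age_dx < cfg$age_range[1] | age_dx > cfg$age_range[2], "age")
  }

  keep <- is.na(reason)
  cohort <- cand[keep, , drop = FALSE] |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row", -".site_ok")
  exclusions <- tibble(patient_id = cand$patient_id[!keep],
                       reason = reason[!keep])
  list(cohort = cohort, exclusions = exclusions)
}
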