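# Multiple-primary (MP) rule engines.
#
# Registries disagree on when a later tumor in the same organ is a new
# primary. The IARC/IACR dialect allows one primary per site group per
# lifetime unless the histology *group* differs (the unspecified group
# matches any group, in both directions, so it can never found a new
# same-site primary nor follow one). The SEER-style dialect counts a later
# same-site tumor when the disease-free gap reaches a threshold (3 years), or
# the ICD-O-3 histology differs at the third digit, or laterality differs
# with both sides known. Only these narrated clauses are implemented, not the
# full SEER MP/H rulebook.

#' Multiple-primary ruleset
#'
#' @param dialect `"iarc"` or `"seer"`.
#' @param disease_free_years Gap (years) after which any same-site tumor
#'   counts as new under the SEER dialect; ignored (none) under IARC.
#' @param use_laterality Should differing known laterality count a same-site
#'   tumor as new (SEER default `TRUE`)?
#' @param site_nchar Number of leading ICD-10 characters defining "same site"
#'   (default 3: all of C34.x is one site).
#' @return An `mp_ruleset` list.
#' @export
mp_ruleset <- function(dialect = c("iarc", "seer"),
                       disease_free_years = 3,
                       use_laterality = TRUE,
                       site_nchar = 3L) {
  dialect <- match.arg(dialect)
  if (dialect == "iarc") {
    ruleset <- list(dialect = "iarc", histology_resolution = "group",
                    disease_free_years = NA_real_, use_laterality = FALSE,
                    site_nchar = as.integer(site_nchar))
  } else {
    check_number(disease_free_years, "disease_free_years", lower = 0)
    check_flag(use_laterality, "use_laterality")
    ruleset <- list(dialect = "seer", histology_resolution = "third_digit",
                    disease_free_years = disease_free_years,
                    use_laterality = use_laterality,
                    site_nchar = as.integer(site_nchar))
  }
  structure(ruleset, class = "mp_ruleset")
}

# Does iarc8 group `a` match `b` for MP purposes? Wildcard (unspecified)
# groups match everything, in both directions.
iarc_group_matches <- function(a, b, wildcard_groups) {
  a == b | a %in% wildcard_groups | b %in% wildcard_groups
}

#' Decide which tumors of one patient count as new primaries
#'
#' @param tumors One patient's tumor records, sorted by `diagnosis_date`
#'   (same-day ties must already be broken deterministically, e.g. by
#'   ascending morphology then input order as [annotate_international_primaries()]
#'   does). Unsorted input is an error.
#' @param rules An [mp_ruleset()].
#' @param scheme An `iarc8` [histology_scheme()] (used by the IARC dialect).
#' @return Logical vector: does each tumor count as a new primary? The first
#'   tumor always counts; tumors at a different site (leading `site_nchar`
#'   ICD-10 characters) always count.
#' @examples
#' sch <- histology_scheme("iarc8")
#' pair <- tibble::tibble(
#'   site = "C34.1", morphology = c(8140L, 8140L),
#'   diagnosis_date = as.Date(c("2005-01-01", "2015-01-01")),
#'   laterality = "unknown"
#' )
#' count_primaries(pair, mp_ruleset("iarc"), sch)  # TRUE FALSE
#' count_primaries(pair, mp_ruleset("seer"), sch)  # TRUE TRUE
#' @export
count_primaries <- function(tumors, rules, scheme = histology_scheme("iarc8")) {
  stopifnot(inherits(rules, "mp_ruleset"))
  check_columns(tumors, c("site", "morphology", "diagnosis_date", "laterality"),
                "`tumors`")
  n <- nrow(tumors)
  if (n == 0) return(logical(0))
  if (is.unsorted(tumors$diagnosis_date)) {
    abort("`tumors` must be sorted by diagnosis_date.")
  }
  site_grp <- substr(tumors$site, 1L, rules$site_nchar)
  group <- map_morphology(tumors$morphology, scheme)
  third <- substr(sprintf("%04d", tumors$morphology), 1L, 3L)
  counts <- logical(n)
  counted <- integer(0)  # indices of counted tumors
  for (i in seq_len(n)) {
    prev <- counted[site_grp[counted] == site_grp[i]]
    new <- if (length(prev) == 0) {
      TRUE
    } else if (rules$dialect == "iarc") {
      !any(iarc_group_matches(group[i], group[prev], scheme$wildcard_groups))
    } else {
      ok <- vapply(prev, function(j) {
        gap <- days_to_years(tumors$diagnosis_date[i] - tumors$diagnosis_date[j])
        if (gap >= rules$disease_free_years) return(TRUE)
        if (third[i] != third[j]) return(TRUE)
        if (rules$use_laterality) {
          lat_i <- tumors$laterality[i]; lat_j <- tumors$laterality[j]
          known <- !(lat_i %in% c("unknown", "bilateral")) &&
            !(lat_j %in% c("unknown", "bilateral"))
          if (known && lat_i != lat_j) return(TRUE)
        }
        FALSE
      }, logical(1))
      all(ok)
    }
    counts[i] <- new
    if (new) counted <- c(counted, i)
  }
  counts
}

#' Annotate records with the INTPRIM flag
#'
#' Marks, per patient, which tumors would count as primaries under the
#' IARC/IACR rules — the per-record annotation SEER supplies as the
#' `INTPRIM` variable. Records are otherwise unchanged and returned in their
#' input order; same-day ties are broken by ascending morphology, then input
#' order, so the flag is deterministic.
#'
#' @param records Multi-patient tumor-record tibble.
#' @param scheme An `iarc8` [histology_scheme()].
#' @return `records` with an added (or replaced) logical `intprim` column.
#' @export
annotate_international_primaries <- function(records,
                                             scheme = histology_scheme("iarc8")) {
  check_columns(records, c("patient_id", "site", "morphology", "diagnosis_date",
                           "laterality"), "`records`")
  rules <- mp_ruleset("iarc")
  ord <- order(records$patient_id, records$diagnosis_date,
               records$morphology, seq_len(nrow(records)))
  sorted <- records[ord, , drop = FALSE]
  # single-tumor patients always count; run the rule engine only where a
  # patient has several tumors
  multi_ids <- unique(sorted$patient_id[duplicated(sorted$patient_id)])
  flags <- rep(TRUE, nrow(sorted))
  if (length(multi_ids) > 0) {
    rows <- which(sorted$patient_id %in% multi_ids)
    chunk <- sorted[rows, c("patient_id", "site", "morphology",
                            "diagnosis_date", "laterality")]
    flags[rows] <- unlist(
      lapply(split(seq_along(rows), chunk$patient_id),
             function(ix) count_primaries(chunk[ix, , drop = FALSE],
                                          rules, scheme)),
      use.names = FALSE)
  }
  sorted$intprim <- flags
  sorted[order(ord), , drop = FALSE]
}
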