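#' Histology grouping schemes for lung cancer morphology codes
#'
#' Lung tumors are grouped by ICD-O-3 morphology in two resolutions:
#'
#' * `"iarc8"` — the eight "histologically different" groups used by the
#'   IARC/IACR multiple-primary rules for lung: squamous, adenocarcinoma,
#'   small-cell, large-cell, other carcinoma, sarcoma (incl. mesothelioma),
#'   other specified cancer, and a catch-all unspecified group. Tumors within
#'   one group cannot give rise to a registered same-site second primary under
#'   IARC/IACR rules, and the unspecified group matches *any* group in both
#'   directions.
#' * `"who5"` — the WHO reporting aggregation: SCC, AC, SCLC, LCC, O&U.
#'
#' The code-range table ships as an editable tab-separated file
#' (`system.file("extdata", "icdo3_lung_histology_groups.tsv", package =
#' "sirhist")`) with columns `code_low`, `code_high`, `iarc8_group`,
#' `who5_group`, `wildcard`, so registry-specific dialects can be swapped in
#' without code changes. `who5` is a strict coarsening of `iarc8` (see
#' [iarc8_to_who5()]).
#'
#' @param name `"iarc8"` or `"who5"`.
#' @param file Optional path to an alternative range table with the same
#'   columns; defaults to the packaged table.
#' @return A `histology_scheme` object: a list with elements `name`, `groups`
#'   (ordered group labels), `wildcard_groups`, and `table` (the range table).
#' @examples
#' sch <- histology_scheme("iarc8")
#' map_morphology(c(8070, 8140, 8041), sch)
#' @export
histology_scheme <- function(name = c("iarc8", "who5"), file = NULL) {
  name <- match.arg(name)
  if (is.null(file)) {
    file <- system.file("extdata", "icdo3_lung_histology_groups.tsv",
                        package = "sirhist", mustWork = TRUE)
  }
  tab <- readr::read_tsv(file, col_types = readr::cols(
    code_low = readr::col_integer(),
    code_high = readr::col_integer(),
    iarc8_group = readr::col_character(),
    who5_group = readr::col_character(),
    wildcard = readr::col_logical()
  ))
  tab <- dplyr::arrange(tab, .data$code_low)
  if (any(tab$code_low[-1] <= tab$code_high[-nrow(tab)])) {
    abort("Histology scheme ranges overlap.")
  }
  group_col <- if (name == "iarc8") "iarc8_group" else "who5_group"
  groups <- if (name == "iarc8") {
    c("squamous", "adenocarcinoma", "small_cell", "large_cell",
      "other_carcinoma", "sarcoma", "other_specified", "unspecified")
  } else {
    c("SCC", "AC", "SCLC", "LCC", "O&U")
  }
  stray <- setdiff(unique(tab[[group_col]]), groups)
  if (length(stray) > 0) {
    abort(sprintf("Scheme file contains unknown %s label(s): %s",
                  name, paste(stray, collapse = ", ")))
  }
  catch_all <- if (name == "iarc8") "unspecified" else "O&U"
  wildcard_groups <- unique(tab[[group_col]][tab$wildcard])
  structure(
    list(name = name, groups = groups, catch_all = catch_all,
         wildcard_groups = wildcard_groups, table = tab, group_col = group_col),
    class = "histology_scheme"
  )
}

#' @export
print.histology_scheme <- function(x, ...) {
  cat(sprintf("<histology_scheme: %s; %d groups; %d code ranges>\n",
              x$name, length(x$groups), nrow(x$table)))
  invisible(x)
}

#' Map ICD-O-3 morphology codes to histology groups
#'
#' Unlisted codes inside the valid morphology range \[8000, 9993\] fall to the
#' scheme's catch-all unspecified group with a warning; codes outside the
#' range are an error. The behavior digit plays no role in grouping.
#'
#' @param code Integer vector of 4-digit ICD-O-3 morphology codes.
#' @param scheme A [histology_scheme()].
#' @return Character vector of group labels, same length as `code`.
#' @export
map_morphology <- function(code, scheme) {
  stopifnot(inherits(scheme, "histology_scheme"))
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 8000L | code > 9993L)) {
    bad <- code[is.na(code) | code < 8000L | code > 9993L]
    abort(sprintf("Morphology code(s) outside [8000, 9993]: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  tab <- scheme$table
  idx <- findInterval(code, tab$code_low)
  hit <- idx >= 1L & code <= tab$code_high[pmax(idx, 1L)]
  out <- rep(scheme$catch_all, length(code))
  out[hit] <- tab[[scheme$group_col]][idx[hit]]
  if (any(!hit)) {
    warn(sprintf("%d morphology code(s) not listed in the %s scheme; assigned to '%s': %s",
                 sum(!hit), scheme$name, scheme$catch_all,
                 paste(unique(code[!hit]), collapse = ", ")))
  }
  out
}

#' Collapse IARC 8-group labels to the WHO 5-group reporting scheme
#'
#' @param group Character vector of `iarc8` group labels.
#' @return Character vector of `who5` labels (`SCC`, `AC`, `SCLC`, `LCC`,
#'   `O&U`).
#' @export
iarc8_to_who5 <- function(group) {
  map <- c(squamous = "SCC", adenocarcinoma = "AC", small_cell = "SCLC",
           large_cell = "LCC", other_carcinoma = "O&U", sarcoma = "O&U",
           other_specified = "O&U", unspecified = "O&U")
  bad <- setdiff(unique(group), names(map))
  if (length(bad) > 0) {
    abort(sprintf("Unknown iarc8 group label(s): %s", paste(bad, collapse = ", ")))
  }
  unname(map[group])
}

#' Per-sex histology group distribution of a cohort
#'
#' Computes, for each sex, the proportion `p` of index cases in every group of
#' the scheme together with the IARC/IACR correction factor `x = 1 - p` (the
#' fraction of second primaries in that index group that would remain
#' registrable under IARC/IACR rules if second-tumor histology follows the
#' same distribution).
#'
#' @param records A tumor-record tibble (needs `sex` and `morphology`).
#' @param scheme A [histology_scheme()]; distributions are usually computed on
#'   the `iarc8` scheme.
#' @return A tibble with columns `sex`, `group`, `n`, `p`, `x`, `wildcard`;
#'   all scheme groups appear for every sex present (zero counts included).
#'   Sexes with zero cases are dropped with a warning.
#' @export
histology_distribution <- function(records, scheme = histology_scheme("iarc8")) {
  check_columns(records, c("sex", "morphology"), "`records`")
  sexes <- intersect(c("female", "male"), unique(records$sex))
  absent <- setdiff(c("female", "male"), sexes)
  if (length(absent) > 0) {
    warn(sprintf("No cases for sex: %s; omitted from the distribution.",
                 paste(absent, collapse = ", ")))
  }
  if (length(sexes) == 0) abort("No cases with a valid sex.")
  records <- dplyr::mutate(records, group = map_morphology(.data$morphology, scheme))
  grid <- tidyr::expand_grid(sex = sexes, group = scheme$groups)
  counts <- dplyr::count(records, .data$sex, .data$group, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("sex", "group"))
  out$n[is.na(out$n)] <- 0L
  out <- out |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(x = 1 - .data$p,
                  wildcard = .data$group %in% scheme$wildcard_groups)
  class(out) <- c("histology_distribution", class(out))
  out
}
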