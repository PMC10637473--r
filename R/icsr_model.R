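#' Normalise free-text sex codes to the package's three-level vocabulary
#'
#' Spontaneous-report exports code sex inconsistently. This maps the common
#' encodings (`"M"`, `"F"`, `"male"`, `"female"`, `"1"`, `"2"`, blank, `NA`)
#' case-insensitively onto `"male"`, `"female"` or `"unknown"`. Any other
#' value becomes `"unknown"` with a warning.
#'
#' @param x Character (or coercible) vector of raw sex codes.
#' @return Character vector with values in `c("male", "female", "unknown")`.
#' @export
#' @examples
#' normalize_sex(c("M", "f", "1", "2", "", NA))
normalize_sex <- function(x) {
  raw <- trimws(tolower(as.character(x)))
  out <- dplyr::case_when(
    is.na(raw) | raw == "" | raw %in% c("na", "unknown", "u") ~ "unknown",
    raw %in% c("m", "male", "1") ~ "male",
    raw %in% c("f", "female", "2") ~ "female",
    TRUE ~ NA_character_
  )
  bad <- is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "%d sex value(s) outside the recognised vocabulary mapped to 'unknown' (e.g. %s)",
      sum(bad), paste(utils::head(unique(raw[bad]), 3L), collapse = ", ")
    ))
    out[bad] <- "unknown"
  }
  out
}

# Collapse per-mention rows into one report per case_id: drugs/reactions are
# unioned; a case with conflicting known sexes resolves to "unknown" (a known
# sex beats "unknown" from blank rows).
merge_mentions <- function(mentions, quiet = FALSE) {
  resolved <- mentions |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      sex_known = list(setdiff(unique(.data$sex), "unknown")),
      drugs = list(sort(unique(.data$drug))),
      reactions = list(sort(unique(.data$reaction_pt))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      conflict = lengths(.data$sex_known) > 1L,
      sex = purrr::map_chr(.data$sex_known,
                           ~ if (length(.x) == 1L) .x else "unknown")
    )
  if (any(resolved$conflict) && !quiet) {
    warn(sprintf(
      "%d case(s) had conflicting sex codes; resolved to 'unknown': %s",
      sum(resolved$conflict),
      paste(utils::head(resolved$case_id[resolved$conflict], 5L), collapse = ", ")
    ))
  }
  resolved |>
    dplyr::arrange(.data$case_id) |>
    dplyr::select("case_id", "sex", "drugs", "reactions")
}

#' Read individual case safety reports
#'
#' Reads ICSRs from either a long CSV (one row per case-drug-reaction
#' mention, header `case_id,drug,reaction_pt,sex`) or a JSON array of report
#' objects with fields `case_id`, `sex`, `drugs`, `reactions`. Rows sharing a
#' `case_id` are merged into one report whose drug and reaction sets are the
#' unions of the mentions; conflicting known sexes within a case resolve to
#' `"unknown"` with a warning.
#'
#' @param path Path to the input file.
#' @param format `"long_csv"` or `"json"`.
#' @param term_map Optional PT-to-SOC map (see [read_term_map()]); when given,
#'   the number of reaction codes that do not resolve is reported.
#' @param quiet Suppress the informational report-count message.
#' @return A tibble of reports with columns `case_id` (character), `sex`
#'   (character: male/female/unknown), and list-columns `drugs`, `reactions`.
#' @export
read_icsr <- function(path, format = c("long_csv", "json"), term_map = NULL,
                      quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("input file does not exist: %s", path))

  if (format == "long_csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    required <- c("case_id", "drug", "reaction_pt", "sex")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    if (nrow(raw) == 0) abort("empty dataset: file contains a header but no reports")
    for (col in c("case_id", "drug", "reaction_pt")) {
      vals <- raw[[col]]
      if (any(is.na(vals) | trimws(vals) == "")) {
        abort(sprintf("column '%s' contains missing or blank values", col))
      }
    }
    mentions <- raw |>
      dplyr::transmute(
        case_id = .data$case_id,
        drug = .data$drug,
        reaction_pt = .data$reaction_pt,
        sex = normalize_sex(.data$sex)
      )
    reports <- merge_mentions(mentions)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(recs) == 0) abort("empty dataset: JSON array contains no reports")
    reports <- purrr::map_dfr(recs, function(r) {
      for (f in c("case_id", "drugs", "reactions")) {
        if (is.null(r[[f]])) abort(sprintf("missing required field(s): %s", f))
      }
      drugs <- unique(as.character(unlist(r$drugs)))
      reactions <- unique(as.character(unlist(r$reactions)))
      if (length(drugs) == 0 || length(reactions) == 0) {
        abort(sprintf("report '%s' has an empty drug or reaction set", r$case_id))
      }
      tibble(
        case_id = as.character(r$case_id),
        sex = normalize_sex(r$sex %||% NA_character_),
        drugs = list(sort(drugs)),
        reactions = list(sort(reactions))
      )
    })
    reports <- deduplicate(reports, quiet = TRUE)
  }

  if (!quiet) {
    inform(sprintf("read %d report(s) from %s", nrow(reports), path))
    if (!is.null(term_map)) {
      pts <- unique(unlist(reports$reactions))
      n_unmapped <- sum(!pts %in% term_map$pt_code)
      inform(sprintf("%d of %d distinct reaction PT(s) unmapped in term map",
                     n_unmapped, length(pts)))
    }
  }
  reports
}

#' Write reports to disk
#'
#' The long CSV format emits one row per case-drug-reaction mention (the
#' cross product of each report's drug and reaction sets), so
#' `read_icsr(write_icsr(x))` recovers the same reports. JSON mirrors the
#' report structure directly.
#'
#' @param reports Report tibble as returned by [read_icsr()] or
#'   [simulate_icsr()].
#' @param path Output path.
#' @param format `"long_csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_icsr <- function(reports, path, format = c("long_csv", "json")) {
  format <- match.arg(format)
  if (format == "long_csv") {
    long <- reports |>
      dplyr::select("case_id", "sex", "drugs", "reactions") |>
      tidyr::unnest_longer("drugs", values_to = "drug") |>
      tidyr::unnest_longer("reactions", values_to = "reaction_pt") |>
      dplyr::select("case_id", "drug", "reaction_pt", "sex")
    readr::write_csv(long, path, progress = FALSE)
  } else {
    recs <- purrr::pmap(reports, function(case_id, sex, drugs, reactions, ...) {
      list(case_id = case_id, sex = sex,
           drugs = as.list(drugs), reactions = as.list(reactions))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Collapse duplicate case identifiers
#'
#' Returns at most one report per `case_id`: drug and reaction sets are
#' unioned across duplicates and conflicting known sexes resolve to
#' `"unknown"`. Output is sorted by `case_id`, so the operation is
#' deterministic and idempotent.
#'
#' @param reports Report tibble.
#' @param quiet Suppress the sex-conflict warning.
#' @return Deduplicated report tibble.
#' @export
deduplicate <- function(reports, quiet = FALSE) {
  mentions <- reports |>
    tidyr::unnest_longer("drugs", values_to = "drug") |>
    tidyr::unnest_longer("reactions", values_to = "reaction_pt") |>
    dplyr::select("case_id", "drug", "reaction_pt", "sex")
  merge_mentions(mentions, quiet = quiet)
}

#' Read a PT-to-SOC reaction term map
#'
#' The map is a CSV with columns `pt_code,pt_name,soc_code,soc_name`, one row
#' per preferred term (PT), each PT belonging to exactly one system organ
#' class (SOC). With no argument the bundled synthetic mock map is used: a
#' two-level stand-in for the licensed MedDRA hierarchy covering the reaction
#' terms used throughout the package's examples.
#'
#' @param path Path to a map CSV, or `NULL` for the bundled synthetic map.
#' @return Tibble with columns `pt_code`, `pt_name`, `soc_code`, `soc_name`.
#' @export
read_term_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_pt_soc_map.csv",
                        package = "sexsignal", mustWork = TRUE)
  }
  map <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("pt_code", "pt_name", "soc_code", "soc_name")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0) {
    abort(sprintf("term map missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dup <- map$pt_code[duplicated(map$pt_code)]
  if (length(dup) > 0) {
    abort(sprintf("term map violates the mono-hierarchy: duplicated pt_code %s",
                  paste(unique(dup), collapse = ", ")))
  }
  map
}

#' Resolve preferred terms to their system organ class
#'
#' Unmapped codes return a sentinel term with `soc_code = "UNMAPPED"` rather
#' than erroring, so no reaction is ever silently dropped downstream.
#'
#' @param term_map Term map tibble from [read_term_map()].
#' @param pt_code Character vector of PT codes.
#' @return Tibble with one row per element of `pt_code`, columns as in the
#'   term map.
#' @export
#' @examples
#' map_to_soc(read_term_map(), c("conjunctivitis", "ZZZ"))
map_to_soc <- function(term_map, pt_code) {
  tibble(pt_code = as.character(pt_code)) |>
    dplyr::left_join(term_map, by = "pt_code") |>
    dplyr::mutate(
      pt_name = dplyr::coalesce(.data$pt_name, .data$pt_code),
      soc_code = dplyr::coalesce(.data$soc_code, "UNMAPPED"),
      soc_name = dplyr::coalesce(.data$soc_name, "Unmapped")
    )
}
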