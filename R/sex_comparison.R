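#' Classify the sex-difference pattern of an ADR (vectorised)
#'
#' Given per-sex IC credibility bounds, assigns each ADR one of six labels.
#' A stratum is a signal when its lower bound is positive; a stratum is NA
#' (the ADR never reported in that sex) when its bounds are `NA`:
#' * `male_only` — male signal, female stratum NA (symmetric: `female_only`);
#' * `male_stronger` — male signal and either the female stratum is present
#'   but not a signal, or both are signals with non-overlapping intervals
#'   (`male ic025 > female ic975`); symmetric: `female_stronger`;
#' * `both_equal` — both signals with overlapping intervals;
#' * `neither` — everything else.
#'
#' The rule is antisymmetric: swapping the sexes swaps `male_*`/`female_*`
#' labels and fixes `both_equal` and `neither`.
#'
#' @param male_ic025,male_ic975 Male-stratum credibility bounds (`NA` = ADR
#'   absent in males).
#' @param female_ic025,female_ic975 Female-stratum bounds.
#' @return Character vector of pattern labels.
#' @export
#' @examples
#' classify_sex_pattern(0.45, 3.69, NA, NA)     # male_only
#' classify_sex_pattern(5.59, 6.11, 4.78, 5.33) # male_stronger
classify_sex_pattern <- function(male_ic025, male_ic975,
                                 female_ic025, female_ic975) {
  m_na <- is.na(male_ic025)
  f_na <- is.na(female_ic025)
  m_sig <- !m_na & male_ic025 > 0
  f_sig <- !f_na & female_ic025 > 0
  dplyr::case_when(
    m_sig & f_na ~ "male_only",
    f_sig & m_na ~ "female_only",
    m_sig & !f_na & (!f_sig | male_ic025 > female_ic975) ~ "male_stronger",
    f_sig & !m_na & (!m_sig | female_ic025 > male_ic975) ~ "female_stronger",
    m_sig & f_sig ~ "both_equal",
    TRUE ~ "neither"
  )
}

#' Classify the sex pattern from two disproportionality results
#'
#' @param male,female One-row result tibbles (e.g. from [evaluate_pair()])
#'   with `ic025`/`ic975` columns, `NA` when the ADR is absent in the
#'   stratum.
#' @return A single pattern label; see [classify_sex_pattern()].
#' @export
classify_pattern <- function(male, female) {
  classify_sex_pattern(male$ic025, male$ic975, female$ic025, female$ic975)
}

#' Sex-stratified disproportionality comparison for one drug
#'
#' Runs the full male/female stratified analysis for a drug: one row per
#' reaction PT observed together with the drug in either sex stratum, with
#' the per-sex counts, IC estimates and credibility bounds, ROR/PRR, signal
#' flags, and the sex-difference pattern label. Rows are sorted by SOC then
#' PT; a stratum in which the ADR was never co-reported carries NA IC values.
#'
#' @param reports Deduplicated report tibble.
#' @param drug Drug of interest.
#' @param term_map PT-to-SOC map (default: the bundled synthetic map).
#' @param level Credibility level.
#' @param method Interval method (`"gamma"` or `"normal"`).
#' @return A `sexsig_comparison` tibble: `reaction_pt`, `soc_code`,
#'   `soc_name`, `male_*` and `female_*` statistic columns, `pattern`.
#' @export
run_comparison <- function(reports, drug, term_map = read_term_map(),
                           level = 0.95, method = c("gamma", "normal")) {
  method <- match.arg(method)
  drugs_seen <- unique(unlist(reports$drugs))
  empty <- tibble(reaction_pt = character(), soc_code = character(),
                  soc_name = character(), pattern = character())
  if (!drug %in% drugs_seen) {
    warn(sprintf("drug '%s' not present in the dataset; returning empty comparison", drug))
    return(structure(empty, class = c("sexsig_comparison", class(empty))))
  }
  sexed <- reports[reports$sex %in% c("male", "female"), ]
  with_drug <- sexed[vapply(sexed$drugs, function(d) drug %in% d, logical(1)), ]
  pts <- sort(unique(unlist(with_drug$reactions)))
  if (length(pts) == 0) {
    warn(sprintf("drug '%s' has no co-reported reactions in the sexed strata", drug))
    return(structure(empty, class = c("sexsig_comparison", class(empty))))
  }
  pairs <- tibble(drug = drug, reaction_pt = pts)

  one_stratum <- function(stratum) {
    if (nrow(filter_stratum(reports, stratum)) == 0) {
      # empty stratum: every ADR is unobserved there -> whole-column NA rows
      res <- tibble(
        reaction_pt = pts, n_observed = 0L, n_drug = 0L, n_reaction = 0L,
        n_total = 0L, n_expected = NA_real_, ic = NA_real_, ic025 = NA_real_,
        ic975 = NA_real_, ror = NA_real_, ror_low = NA_real_,
        ror_high = NA_real_, ror_corrected = NA, prr = NA_real_,
        prr_low = NA_real_, prr_high = NA_real_, prr_corrected = NA,
        is_na = TRUE, is_signal = FALSE
      )
    } else {
      res <- disproportionality_table(reports, stratum = stratum, level = level,
                                      pairs = pairs, method = method) |>
        dplyr::select(-"drug", -"stratum")
    }
    dplyr::rename_with(res, ~ paste0(stratum, "_", .x), -"reaction_pt")
  }
  out <- one_stratum("male") |>
    dplyr::inner_join(one_stratum("female"), by = "reaction_pt") |>
    dplyr::mutate(
      pattern = classify_sex_pattern(.data$male_ic025, .data$male_ic975,
                                     .data$female_ic025, .data$female_ic975)
    )
  soc <- map_to_soc(term_map, out$reaction_pt)
  out <- dplyr::bind_cols(
    soc |> dplyr::select(pt_code = "pt_code", soc_code = "soc_code",
                         soc_name = "soc_name"),
    out |> dplyr::select(-"reaction_pt")
  ) |>
    dplyr::rename(reaction_pt = "pt_code") |>
    dplyr::arrange(.data$soc_code, .data$reaction_pt)
  attr(out, "drug") <- drug
  attr(out, "level") <- level
  structure(out, class = c("sexsig_comparison", class(out)))
}

#' Reporting summary statistics for a drug
#'
#' Counts the deduplicated reports mentioning the drug: total, with known
#' sex, female and male, together with the derived percentages and the
#' female-to-male reporting ratio. Percentages and the ratio are kept at
#' full precision; rounding happens only at display/export time.
#'
#' @param reports Deduplicated report tibble.
#' @param drug Drug of interest.
#' @return A one-row `sexsig_summary` tibble; see [summary_from_counts()].
#' @export
summary_statistics <- function(reports, drug) {
  sub <- reports[vapply(reports$drugs, function(d) drug %in% d, logical(1)), ]
  summary_from_counts(
    n_reports_total = nrow(sub),
    n_with_sex = sum(sub$sex != "unknown"),
    n_female = sum(sub$sex == "female"),
    n_male = sum(sub$sex == "male"),
    drug = drug
  )
}

#' Summary statistics from pre-tabulated counts
#'
#' Computes the percentage of reports with sex information, the per-sex
#' percentages of the sexed reports, and the female-to-male reporting ratio
#' from externally supplied counts (e.g. counts quoted from a published
#' analysis). When the female and male counts do not partition the sexed
#' count — which happens when the counts come from overlapping tabulations —
#' a warning is raised and the percentages are still computed against the
#' supplied `n_with_sex` denominator.
#'
#' @param n_reports_total Total distinct reports mentioning the drug.
#' @param n_with_sex Reports with known sex.
#' @param n_female,n_male Reports per sex.
#' @param drug Optional drug label carried through.
#' @return One-row tibble: the four counts, `pct_with_sex`,
#'   `pct_female_of_sexed`, `pct_male_of_sexed` (percent scale, full
#'   precision), and `f_to_m_ratio` (`NA` when `n_male = 0`).
#' @export
#' @examples
#' summary_from_counts(2910, 2581, 2001, 1768)
summary_from_counts <- function(n_reports_total, n_with_sex, n_female, n_male,
                                drug = NA_character_) {
  stopifnot(n_reports_total >= 0, n_with_sex >= 0, n_female >= 0, n_male >= 0)
  if (n_female + n_male != n_with_sex) {
    warn(sprintf(
      "n_female + n_male (%d) differs from n_with_sex (%d); percentages use n_with_sex as denominator",
      n_female + n_male, n_with_sex))
  }
  out <- tibble(
    drug = drug,
    n_reports_total = as.integer(n_reports_total),
    n_with_sex = as.integer(n_with_sex),
    n_female = as.integer(n_female),
    n_male = as.integer(n_male),
    pct_with_sex = if (n_reports_total > 0) 100 * n_with_sex / n_reports_total else NA_real_,
    pct_female_of_sexed = if (n_with_sex > 0) 100 * n_female / n_with_sex else NA_real_,
    pct_male_of_sexed = if (n_with_sex > 0) 100 * n_male / n_with_sex else NA_real_,
    f_to_m_ratio = if (n_male > 0) n_female / n_male else NA_real_
  )
  structure(out, class = c("sexsig_summary", class(out)))
}

#' @export
print.sexsig_summary <- function(x, ...) {
  cat("Reporting summary", if (!is.na(x$drug)) sprintf("for %s", x$drug), "\n")
  cat(sprintf("  reports: %d; with sex information: %d (%.1f%%)\n",
              x$n_reports_total, x$n_with_sex, x$pct_with_sex))
  cat(sprintf("  female: %d (%.1f%%); male: %d (%.1f%%); F:M ratio %s\n",
              x$n_female, x$pct_female_of_sexed,
              x$n_male, x$pct_male_of_sexed,
              ifelse(is.na(x$f_to_m_ratio), "NA",
                     sprintf("%.2f:1", x$f_to_m_ratio))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of a sex comparison
#'
#' One row per (reaction, sex) with the counts, IC and bounds — the shape
#' used for forest plots and heatmaps.
#'
#' @param x A `sexsig_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return A tibble with columns `reaction_pt`, `soc_code`, `sex`,
#'   `n_observed`, `n_expected`, `ic`, `ic025`, `ic975`, `is_signal`,
#'   `pattern`.
#' @exportS3Method generics::tidy
tidy.sexsig_comparison <- function(x, ...) {
  long <- function(sex) {
    pick <- function(col) x[[paste0(sex, "_", col)]]
    tibble(
      reaction_pt = x$reaction_pt,
      soc_code = x$soc_code,
      sex = sex,
      n_observed = pick("n_observed"),
      n_expected = pick("n_expected"),
      ic = pick("ic"),
      ic025 = pick("ic025"),
      ic975 = pick("ic975"),
      is_signal = pick("is_signal"),
      pattern = x$pattern
    )
  }
  dplyr::bind_rows(long("male"), long("female")) |>
    dplyr::arrange(.data$soc_code, .data$reaction_pt, .data$sex)
}

#' One-row overview of a sex comparison
#'
#' @param x A `sexsig_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return A one-row tibble: number of reactions analysed, per-sex signal
#'   counts, and the count of each sex-difference pattern.
#' @exportS3Method generics::glance
glance.sexsig_comparison <- function(x, ...) {
  pat <- table(factor(x$pattern, levels = PATTERN_LEVELS))
  dplyr::bind_cols(
    tibble(
      drug = attr(x, "drug") %||% NA_character_,
      n_reactions = nrow(x),
      n_male_signals = sum(x$male_is_signal, na.rm = TRUE),
      n_female_signals = sum(x$female_is_signal, na.rm = TRUE)
    ),
    as_tibble(as.list(pat))
  )
}
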