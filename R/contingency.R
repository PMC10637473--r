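# Restrict reports to a sex stratum. "all" keeps every report, including
# sex-unknown ones; "male"/"female" keep only that sex.
filter_stratum <- function(reports, stratum) {
  stratum <- match.arg(stratum, STRATUM_LEVELS)
  if (stratum == "all") reports else reports[reports$sex == stratum, ]
}

# Report-level mention tables: one row per distinct (case_id, drug) and
# (case_id, reaction_pt). A report mentioning a term twice counts once.
drug_mentions <- function(reports) {
  reports |>
    dplyr::select("case_id", "drugs") |>
    tidyr::unnest_longer("drugs", values_to = "drug") |>
    dplyr::distinct()
}

reaction_mentions <- function(reports) {
  reports |>
    dplyr::select("case_id", "reactions") |>
    tidyr::unnest_longer("reactions", values_to = "reaction_pt") |>
    dplyr::distinct()
}

#' Per-stratum 2x2 sufficient statistics for a drug-reaction pair
#'
#' Counts distinct case reports in the chosen sex stratum: reports with both
#' the drug and the reaction (`n_observed`), with the drug (`n_drug`), with
#' the reaction (`n_reaction`), and in total (`n_total`). All four counts are
#' restricted to the stratum, so the male and female analyses are fully
#' independent subgroup analyses; `stratum = "all"` includes sex-unknown
#' reports.
#'
#' @param reports Deduplicated report tibble.
#' @param drug Drug name.
#' @param reaction_pt Reaction PT code.
#' @param stratum `"male"`, `"female"` or `"all"`.
#' @return One-row tibble: `stratum`, `n_observed`, `n_drug`, `n_reaction`,
#'   `n_total`.
#' @export
count_stratum <- function(reports, drug, reaction_pt, stratum = "all") {
  stratum <- match.arg(stratum, STRATUM_LEVELS)
  sub <- filter_stratum(reports, stratum)
  has_drug <- vapply(sub$drugs, function(d) drug %in% d, logical(1))
  has_rxn <- vapply(sub$reactions, function(r) reaction_pt %in% r, logical(1))
  tibble(
    stratum = stratum,
    n_observed = sum(has_drug & has_rxn),
    n_drug = sum(has_drug),
    n_reaction = sum(has_rxn),
    n_total = nrow(sub)
  )
}

# Counts for many pairs at once (the vectorised engine behind
# disproportionality_table / run_comparison).
count_pairs <- function(reports, pairs, stratum) {
  sub <- filter_stratum(reports, stratum)
  dm <- drug_mentions(sub)
  rm_ <- reaction_mentions(sub)
  n_total <- nrow(sub)
  n_drug_tbl <- dplyr::count(dm, .data$drug, name = "n_drug")
  n_rxn_tbl <- dplyr::count(rm_, .data$reaction_pt, name = "n_reaction")
  n_obs_tbl <- dm |>
    dplyr::inner_join(rm_, by = "case_id", relationship = "many-to-many") |>
    dplyr::count(.data$drug, .data$reaction_pt, name = "n_observed")
  pairs |>
    dplyr::left_join(n_obs_tbl, by = c("drug", "reaction_pt")) |>
    dplyr::left_join(n_drug_tbl, by = "drug") |>
    dplyr::left_join(n_rxn_tbl, by = "reaction_pt") |>
    dplyr::mutate(
      stratum = stratum,
      dplyr::across(c("n_observed", "n_drug", "n_reaction"),
                    ~ dplyr::coalesce(.x, 0L)),
      n_total = n_total
    ) |>
    dplyr::select("drug", "reaction_pt", "stratum", "n_observed", "n_drug",
                  "n_reaction", "n_total")
}

#' Expected count under drug-reaction independence
#'
#' `N_expected = N_drug * N_reaction / N_total`: the number of co-reports
#' expected if the drug and the reaction occurred independently across the
#' stratum's reports.
#'
#' @param counts Counts tibble (rows from [count_stratum()] or any data frame
#'   with `n_drug`, `n_reaction`, `n_total` columns).
#' @return Numeric vector of expected counts (full precision, not rounded).
#' @export
#' @examples
#' expected_count(data.frame(n_drug = 100, n_reaction = 80, n_total = 1000))
expected_count <- function(counts) {
  if (any(counts$n_total == 0)) {
    abort("undefined stratum: n_total = 0 (empty stratum has no expected count)")
  }
  counts$n_drug * counts$n_reaction / counts$n_total
}

# The four 2x2 cells: a = both, b = drug only, c = reaction only, d = neither.
contingency_cells <- function(counts) {
  a <- counts$n_observed
  b <- counts$n_drug - a
  c <- counts$n_reaction - a
  d <- counts$n_total - counts$n_drug - counts$n_reaction + a
  if (any(d < 0) || any(b < 0) || any(c < 0)) {
    abort("invalid counts: 2x2 cells must be non-negative")
  }
  tibble(a = a, b = b, c = c, d = d)
}
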