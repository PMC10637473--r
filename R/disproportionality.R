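#' Information component point estimate
#'
#' The IC is the log2 of the shrunken observed-to-expected reporting ratio,
#' `log2((N_obs + 0.5) / (N_exp + 0.5))`, as in the Bayesian confidence
#' propagation neural network (BCPNN) approach to disproportionality
#' analysis. The matched +0.5 shrinkage constants pull small-count pairs
#' toward 0 and make the IC exactly 0 whenever observed equals expected.
#'
#' @param n_observed Observed report count(s).
#' @param n_expected Expected count(s) under independence.
#' @return Numeric vector of IC values (log2 scale).
#' @export
#' @examples
#' ic_point(40, 8)      # strong over-reporting
#' ic_point(0, 7.5)     # = -4: strong under-reporting
ic_point <- function(n_observed, n_expected) {
  log2((n_observed + 0.5) / (n_expected + 0.5))
}

#' Credibility interval of the information component
#'
#' Under the shrinkage model the relative reporting rate has a
#' `Gamma(shape = N_obs + 0.5, rate = N_exp + 0.5)` posterior; the default
#' `"gamma"` method returns the log2-transformed exact quantiles of that
#' posterior. The `"normal"` method is a log-gamma normal approximation
#' (`IC +/- z * sqrt(trigamma(shape)) / ln 2`) offered for comparison.
#'
#' @param n_observed,n_expected As in [ic_point()]; vectorised.
#' @param level Credibility level in (0, 1), default 0.95.
#' @param method `"gamma"` (exact posterior quantiles) or `"normal"`.
#' @return Tibble with columns `ic025` and `ic975` (named for the default
#'   95% level; they hold the `(1-level)/2` and `(1+level)/2` bounds).
#' @export
ic_interval <- function(n_observed, n_expected, level = 0.95,
                        method = c("gamma", "normal")) {
  method <- match.arg(method)
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    abort("level must be a single probability strictly inside (0, 1)")
  }
  shape <- n_observed + 0.5
  rate <- n_expected + 0.5
  alpha <- (1 - level) / 2
  if (method == "gamma") {
    lo <- log2(qgamma(alpha, shape = shape, rate = rate))
    hi <- log2(qgamma(1 - alpha, shape = shape, rate = rate))
  } else {
    ic <- ic_point(n_observed, n_expected)
    half <- qnorm(1 - alpha) * sqrt(trigamma(shape)) / log(2)
    lo <- ic - half
    hi <- ic + half
  }
  tibble(ic025 = lo, ic975 = hi)
}

#' Information component from stratum counts
#'
#' @param counts Counts tibble (from [count_stratum()]).
#' @return Numeric vector of IC values.
#' @export
information_component <- function(counts) {
  ic_point(counts$n_observed, expected_count(counts))
}

#' Credibility interval from stratum counts
#'
#' @inheritParams ic_interval
#' @param counts Counts tibble (from [count_stratum()]).
#' @return Tibble with `ic025`, `ic975`.
#' @export
ic_credible_interval <- function(counts, level = 0.95,
                                 method = c("gamma", "normal")) {
  ic_interval(counts$n_observed, expected_count(counts),
              level = level, method = match.arg(method))
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a*d)/(b*c)` on the 2x2 cells, with a 95% log-normal Wald interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane-Anscombe +0.5 correction on all four cells, flagged in the
#' `ror_corrected` column.
#'
#' @param counts Counts tibble; vectorised over rows.
#' @param level Confidence level, default 0.95.
#' @return Tibble with `ror`, `ror_low`, `ror_high`, `ror_corrected`.
#' @export
reporting_odds_ratio <- function(counts, level = 0.95) {
  cells <- contingency_cells(counts)
  corrected <- cells$a == 0 | cells$b == 0 | cells$c == 0 | cells$d == 0
  adj <- ifelse(corrected, 0.5, 0)
  a <- cells$a + adj; b <- cells$b + adj; c <- cells$c + adj; d <- cells$d + adj
  ror <- (a * d) / (b * c)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(
    ror = ror,
    ror_low = exp(log(ror) - z * se),
    ror_high = exp(log(ror) + z * se),
    ror_corrected = corrected
  )
}

#' Proportional reporting ratio with Wald confidence interval
#'
#' `PRR = (a / N_drug) / (c / (N_total - N_drug))`: the reaction's frequency
#' among the drug's reports relative to its frequency among all other
#' reports, with interval
#' `exp(ln PRR +/- z * sqrt(1/a - 1/N_drug + 1/c - 1/(N_total - N_drug)))`.
#' A zero `a` or `c` triggers the +0.5 correction on all four cells, flagged.
#'
#' @inheritParams reporting_odds_ratio
#' @return Tibble with `prr`, `prr_low`, `prr_high`, `prr_corrected`.
#' @export
proportional_reporting_ratio <- function(counts, level = 0.95) {
  if (any(counts$n_total == counts$n_drug)) {
    abort("undefined PRR: n_total = n_drug leaves no comparator population")
  }
  cells <- contingency_cells(counts)
  corrected <- cells$a == 0 | cells$c == 0
  adj <- ifelse(corrected, 0.5, 0)
  a <- cells$a + adj; b <- cells$b + adj; c <- cells$c + adj; d <- cells$d + adj
  n_drug <- a + b
  n_other <- c + d
  prr <- (a / n_drug) / (c / n_other)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a - 1 / n_drug + 1 / c - 1 / n_other)
  tibble(
    prr = prr,
    prr_low = exp(log(prr) - z * se),
    prr_high = exp(log(prr) + z * se),
    prr_corrected = corrected
  )
}

# Full statistics block for a counts tibble. Rows with n_observed = 0 follow
# the NA convention: IC point and bounds render NA and is_signal is FALSE.
# Rows with no comparator population (n_total = n_drug) get NA PRR.
dispro_stats <- function(counts, level = 0.95, method = "gamma") {
  n_exp <- expected_count(counts)
  ci <- ic_interval(counts$n_observed, n_exp, level = level, method = method)
  prr <- tibble(prr = NA_real_, prr_low = NA_real_, prr_high = NA_real_,
                prr_corrected = NA)[rep(1, nrow(counts)), ]
  prr_ok <- counts$n_total > counts$n_drug
  if (any(prr_ok)) {
    prr[prr_ok, ] <- proportional_reporting_ratio(counts[prr_ok, ], level = level)
  }
  out <- dplyr::bind_cols(
    counts,
    tibble(
      n_expected = n_exp,
      ic = ic_point(counts$n_observed, n_exp),
      ic025 = ci$ic025,
      ic975 = ci$ic975
    ),
    reporting_odds_ratio(counts, level = level),
    prr
  )
  out |>
    dplyr::mutate(
      is_na = .data$n_observed == 0,
      is_signal = !.data$is_na & .data$ic025 > 0,
      dplyr::across(c("ic", "ic025", "ic975"),
                    ~ ifelse(.data$is_na, NA_real_, .x))
    )
}

#' Evaluate one drug-reaction pair in one stratum
#'
#' Composes the stratified counting, the expected count, the IC with its
#' credibility interval, and the ROR/PRR comparators into a single tidy row.
#' Pairs with zero observed co-reports carry `is_na = TRUE` and NA in the IC
#' columns (the convention used for strata in which an ADR was never
#' reported); the signal flag is `ic025 > 0`.
#'
#' @param reports Deduplicated report tibble.
#' @param drug Drug name.
#' @param reaction_pt Reaction PT code.
#' @param stratum `"male"`, `"female"` or `"all"`.
#' @param level Credibility/confidence level.
#' @param method Interval method, `"gamma"` or `"normal"`.
#' @return One-row tibble with counts, `n_expected`, `ic`, `ic025`, `ic975`,
#'   `ror` (+CI), `prr` (+CI), `is_signal`, `is_na`.
#' @export
evaluate_pair <- function(reports, drug, reaction_pt, stratum = "all",
                          level = 0.95, method = c("gamma", "normal")) {
  method <- match.arg(method)
  counts <- count_stratum(reports, drug, reaction_pt, stratum)
  if (counts$n_total == 0) {
    abort(sprintf("undefined stratum: no reports in stratum '%s'", stratum))
  }
  dplyr::bind_cols(tibble(drug = drug, reaction_pt = reaction_pt),
                   dispro_stats(counts, level = level, method = method))
}

#' Disproportionality table for many pairs at once
#'
#' Computes the full statistics block for every requested drug-reaction pair
#' in one stratum. By default the pairs are the cross product of all drugs
#' and all reaction PTs appearing anywhere in the dataset, which is the
#' screening mode used for database-wide signal scans.
#'
#' @inheritParams evaluate_pair
#' @param pairs Optional tibble with columns `drug`, `reaction_pt` selecting
#'   the pairs to evaluate.
#' @return Tibble with one row per pair, columns as in [evaluate_pair()].
#' @export
disproportionality_table <- function(reports, stratum = "all", level = 0.95,
                                     pairs = NULL,
                                     method = c("gamma", "normal")) {
  method <- match.arg(method)
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(
      drug = sort(unique(unlist(reports$drugs))),
      reaction_pt = sort(unique(unlist(reports$reactions)))
    )
  }
  counts <- count_pairs(reports, pairs, stratum)
  if (nrow(counts) > 0 && counts$n_total[1] == 0) {
    abort(sprintf("undefined stratum: no reports in stratum '%s'", stratum))
  }
  dispro_stats(counts, level = level, method = method)
}
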