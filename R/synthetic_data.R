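# Truncated geometric pmf on 1..kmax with decay parameter q in (0,1):
# P(k) proportional to (1 - q)^(k - 1). q -> 1 concentrates at k = 1;
# q -> 0 approaches the uniform distribution on 1..kmax.
trunc_geom_pmf <- function(q, kmax) {
  w <- (1 - q)^(0:(kmax - 1))
  w / sum(w)
}

trunc_geom_mean <- function(q, kmax) sum(seq_len(kmax) * trunc_geom_pmf(q, kmax))

# Solve the decay parameter that gives the requested mean.
trunc_geom_solve <- function(mean, kmax) {
  if (mean <= 1 || mean >= (1 + kmax) / 2) {
    abort(sprintf("reaction_mean must lie in (1, %.2f) for kmax = %d",
                  (1 + kmax) / 2, kmax))
  }
  uniroot(function(q) trunc_geom_mean(q, kmax) - mean,
          lower = 1e-9, upper = 1 - 1e-9, tol = 1e-12)$root
}

#' Specify a planted drug-reaction signal
#'
#' A planted signal multiplies the probability that reports mentioning `drug`
#' also include `reaction_pt`, by a sex-specific relative reporting rate
#' `rho`. `rho = 1` is the null (no disproportionality) in that stratum;
#' `rho = 0` makes the pair never co-occur; `log2(rho)` is the value the
#' information component estimates for that stratum.
#'
#' @param drug Drug name (must be in the simulation's drug catalog).
#' @param reaction_pt Reaction PT code (must be in the reaction catalog).
#' @param rho_male,rho_female Non-negative relative reporting rates.
#' @return One-row tibble describing the signal.
#' @export
planted_signal <- function(drug, reaction_pt, rho_male = 1, rho_female = 1) {
  stopifnot(rho_male >= 0, rho_female >= 0)
  tibble(drug = drug, reaction_pt = reaction_pt,
         rho_male = rho_male, rho_female = rho_female)
}

#' Configure the synthetic ICSR generator
#'
#' Defines a generative model for spontaneous-report data: each report draws
#' a sex, one primary suspect drug from the drug catalog's marginal
#' probabilities, and `k` reactions (truncated-geometric `k`) from the
#' reaction catalog, then planted signals rescale the inclusion probability
#' of their reaction among reports carrying their drug by the sex-specific
#' relative rate `rho`.
#'
#' Reactions are drawn by systematic probability-proportional-to-size
#' sampling without replacement, which makes the marginal inclusion
#' probability of reaction `r` in a report with `k` reactions exactly
#' `k * p_r`; this requires `kmax * max(p_r) <= 1` and is what allows planted
#' signals to hit their target rate exactly.
#'
#' @param n_reports Number of reports to generate.
#' @param drug_catalog Named numeric vector of drug marginal probabilities
#'   (normalised to sum to 1).
#' @param reaction_catalog Named numeric vector of reaction PT marginal
#'   probabilities (normalised to sum to 1).
#' @param reaction_mean Mean number of reactions per report (truncated
#'   geometric on `1..reaction_kmax`).
#' @param reaction_kmax Maximum reactions per report.
#' @param sex_probs Probabilities for (male, female, unknown); must sum to 1.
#' @param signals Tibble of planted signals (rows from [planted_signal()]),
#'   or `NULL` for a null database.
#' @param seed Integer seed; fully determines the generated dataset.
#' @param n_duplicates Number of duplicated case entries to append (a simple
#'   duplication knob for exercising [deduplicate()]).
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(n_reports,
                       drug_catalog = default_drug_catalog(),
                       reaction_catalog = default_reaction_catalog(),
                       reaction_mean = 2.5,
                       reaction_kmax = 6,
                       sex_probs = c(male = 0.45, female = 0.51, unknown = 0.04),
                       signals = NULL,
                       seed = 20211,
                       n_duplicates = 0) {
  stopifnot(length(n_reports) == 1, n_reports >= 0, n_reports == floor(n_reports))
  if (is.null(names(drug_catalog)) || is.null(names(reaction_catalog))) {
    abort("drug_catalog and reaction_catalog must be named probability vectors")
  }
  if (any(drug_catalog < 0) || any(reaction_catalog < 0)) {
    abort("catalog probabilities must be non-negative")
  }
  if (any(duplicated(names(drug_catalog))) || any(duplicated(names(reaction_catalog)))) {
    abort("catalog names must be unique")
  }
  drug_catalog <- drug_catalog / sum(drug_catalog)
  reaction_catalog <- reaction_catalog / sum(reaction_catalog)
  sex_probs <- sex_probs[SEX_LEVELS]
  if (anyNA(sex_probs)) abort("sex_probs must be named with male, female, unknown")
  if (any(sex_probs < 0) || any(sex_probs > 1) || abs(sum(sex_probs) - 1) > 1e-12) {
    abort("sex_probs must be probabilities summing to 1 (within 1e-12)")
  }
  if (reaction_kmax * max(reaction_catalog) > 1 + 1e-12) {
    abort(sprintf(
      "reaction_kmax * max(reaction probability) = %.3f exceeds 1; exact inclusion probabilities require kmax * max(p) <= 1",
      reaction_kmax * max(reaction_catalog)))
  }
  if (is.null(signals)) {
    signals <- planted_signal(character(), character(), numeric(), numeric())
  }
  signals <- as_tibble(signals)
  stopifnot(all(c("drug", "reaction_pt", "rho_male", "rho_female") %in% names(signals)))
  bad_drug <- setdiff(signals$drug, names(drug_catalog))
  bad_pt <- setdiff(signals$reaction_pt, names(reaction_catalog))
  if (length(bad_drug) || length(bad_pt)) {
    abort(sprintf("planted signal refers to unknown drug/reaction: %s",
                  paste(c(bad_drug, bad_pt), collapse = ", ")))
  }
  if (any(signals$rho_male < 0) || any(signals$rho_female < 0)) {
    abort("relative reporting rates rho must be >= 0")
  }
  q <- trunc_geom_solve(reaction_mean, reaction_kmax)
  structure(
    list(
      n_reports = as.integer(n_reports),
      drug_catalog = drug_catalog,
      reaction_catalog = reaction_catalog,
      reaction_mean = reaction_mean,
      reaction_kmax = as.integer(reaction_kmax),
      reaction_pmf = trunc_geom_pmf(q, reaction_kmax),
      mean_k = trunc_geom_mean(q, reaction_kmax),
      sex_probs = sex_probs,
      signals = signals,
      seed = as.integer(seed),
      n_duplicates = as.integer(n_duplicates)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  reports: %d  drugs: %d  reactions: %d  mean reactions/report: %.2f\n",
              x$n_reports, length(x$drug_catalog), length(x$reaction_catalog), x$mean_k))
  cat(sprintf("  sex mix (M/F/unknown): %.2f / %.2f / %.2f   seed: %d\n",
              x$sex_probs[["male"]], x$sex_probs[["female"]],
              x$sex_probs[["unknown"]], x$seed))
  cat(sprintf("  planted signals: %d\n", nrow(x$signals)))
  invisible(x)
}

#' Default drug catalog
#'
#' Twenty drugs: the suspect drug of interest (`dupilumab`) at a 2% marginal
#' share, plus nineteen background drugs with Zipf-decaying shares — a
#' caricature of how reporting volume concentrates on a few widely used
#' drugs in a spontaneous-reporting database.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_drug_catalog <- function() {
  others <- 1 / seq_len(19)
  others <- 0.98 * others / sum(others)
  c(dupilumab = 0.02, setNames(others, sprintf("drug_%02d", 2:20)))
}

#' Default reaction catalog
#'
#' The 40+ preferred terms of the bundled synthetic PT-to-SOC map with
#' inverse-square-root decaying marginal probabilities, so common reactions
#' (e.g. headache-like terms) dominate while the tail stays populated.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_reaction_catalog <- function() {
  pts <- read_term_map()$pt_code
  w <- 1 / sqrt(seq_along(pts))
  setNames(w / sum(w), pts)
}

# Systematic probability-proportional-to-size sampling: for each report with
# k reactions, lay the weights k*p_r end to end (total length k) and take the
# units hit by u, u+1, ..., u+k-1 for a single uniform start u. Because
# k * p_r <= 1 for every r, no unit is hit twice and the inclusion
# probability of unit r is exactly k * p_r.
draw_reactions <- function(k, probs) {
  n <- length(k)
  pts <- names(probs)
  out <- vector("list", n)
  for (kk in sort(unique(k))) {
    idx <- which(k == kk)
    cumw <- cumsum(kk * probs)
    u <- runif(length(idx))
    pos <- rep(u, each = kk) + rep(seq_len(kk) - 1, times = length(idx))
    unit <- findInterval(pos, cumw) + 1L
    sel <- split(pts[unit], rep(idx, each = kk))
    out[idx] <- lapply(sel, sort)
  }
  out
}

#' Generate a synthetic ICSR dataset
#'
#' Draws `n_reports` reports from the generative model in `config`:
#' sex, one primary drug, a background reaction set, then planted-signal
#' adjustment. For a signal with relative rate `rho`, reports carrying the
#' signal drug include the signal reaction with probability
#' `min(1, rho * q)` where `q = mean_k * p_r` is the background inclusion
#' probability — implemented by adding the reaction with the complementary
#' probability when `rho > 1` and thinning it with probability `rho` when
#' `rho < 1`, so the target rate is hit exactly. Sex-unknown reports take
#' `rho = 1`. The output is fully determined by `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return Report tibble (`case_id`, `sex`, `drugs`, `reactions`), with an
#'   attribute `clamped` counting reports whose target probability
#'   `rho * q` exceeded 1 and was clamped.
#' @export
simulate_icsr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  if (n == 0) {
    return(tibble(case_id = character(), sex = character(),
                  drugs = list(), reactions = list()))
  }
  sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = config$sex_probs)
  drug <- sample(names(config$drug_catalog), n, replace = TRUE,
                 prob = config$drug_catalog)
  k <- sample.int(config$reaction_kmax, n, replace = TRUE,
                  prob = config$reaction_pmf)
  reactions <- draw_reactions(k, config$reaction_catalog)

  n_clamped <- 0L
  if (nrow(config$signals) > 0) {
    for (s in seq_len(nrow(config$signals))) {
      sig <- config$signals[s, ]
      hit <- which(drug == sig$drug & sex != "unknown")
      if (length(hit) == 0) next
      q <- config$mean_k * config$reaction_catalog[[sig$reaction_pt]]
      rho <- ifelse(sex[hit] == "male", sig$rho_male, sig$rho_female)
      target <- rho * q
      clamped <- target > 1
      n_clamped <- n_clamped + sum(clamped)
      target <- pmin(target, 1)
      has <- vapply(reactions[hit], function(r) sig$reaction_pt %in% r, logical(1))
      u <- runif(length(hit))
      # rho >= 1: add with prob (target - q)/(1 - q) when absent;
      # rho <  1: keep with prob target/q (= rho) when present.
      add <- !has & rho >= 1 & u < (target - q) / (1 - q)
      keep <- has & (rho >= 1 | u < target / q)
      include <- add | keep
      for (i in seq_along(hit)) {
        if (include[i] && !has[i]) {
          reactions[[hit[i]]] <- sort(c(reactions[[hit[i]]], sig$reaction_pt))
        } else if (!include[i] && has[i]) {
          reactions[[hit[i]]] <- setdiff(reactions[[hit[i]]], sig$reaction_pt)
        }
      }
      # a report whose only reaction was thinned away still needs one:
      # redraw a single background reaction excluding the signal PT
      empty <- hit[lengths(reactions[hit]) == 0]
      if (length(empty) > 0) {
        p2 <- config$reaction_catalog[names(config$reaction_catalog) != sig$reaction_pt]
        redraw <- sample(names(p2), length(empty), replace = TRUE, prob = p2)
        reactions[empty] <- as.list(redraw)
      }
    }
  }
  if (n_clamped > 0) {
    inform(sprintf("%d report-level target probabilities exceeded 1 and were clamped",
                   n_clamped))
  }

  reports <- tibble(
    case_id = sprintf("case_%08d", seq_len(n)),
    sex = sex,
    drugs = as.list(drug),
    reactions = reactions
  )
  if (config$n_duplicates > 0) {
    dup_idx <- sample.int(n, min(config$n_duplicates, n), replace = FALSE)
    reports <- dplyr::bind_rows(reports, reports[dup_idx, ]) |>
      dplyr::arrange(.data$case_id)
  }
  attr(reports, "clamped") <- n_clamped
  reports
}

#' Ground-truth information component of the generator
#'
#' Returns `log2(rho)` for the requested drug-reaction pair and sex stratum —
#' the asymptotic target of the IC estimator under the generative model
#' (exactly, up to a `log2(1 + f_drug * (rho - 1))` term that vanishes as the
#' drug's marginal share shrinks). Unplanted pairs return 0.
#'
#' @param config A [sim_config()] object.
#' @param drug,reaction_pt Pair to query; must exist in the catalogs.
#' @param sex `"male"` or `"female"` (`"unknown"` strata carry no planted
#'   signal and return 0).
#' @return The true log2 relative reporting rate.
#' @export
true_ic <- function(config, drug, reaction_pt, sex) {
  stopifnot(inherits(config, "sim_config"))
  sex <- match.arg(sex, SEX_LEVELS)
  if (!drug %in% names(config$drug_catalog) ||
      !reaction_pt %in% names(config$reaction_catalog)) {
    abort(sprintf("unknown drug-reaction pair: %s / %s", drug, reaction_pt))
  }
  row <- config$signals |>
    dplyr::filter(.data$drug == !!drug, .data$reaction_pt == !!reaction_pt)
  if (nrow(row) == 0 || sex == "unknown") return(0)
  rho <- if (sex == "male") row$rho_male[[1]] else row$rho_female[[1]]
  log2(rho)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the arguments of [sim_config()]: scalar fields
#' `n_reports`, `reaction_mean`, `reaction_kmax`, `seed`, `n_duplicates`;
#' mappings `drug_catalog`, `reaction_catalog`, `sex_probs` (name ->
#' probability); and a `signals` list of mappings with keys `drug`,
#' `reaction_pt`, `rho_male`, `rho_female`. Omitted fields take the
#' [sim_config()] defaults.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file does not exist: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$n_reports)) abort("config is missing required field: n_reports")
  args <- list(n_reports = raw$n_reports)
  for (f in c("reaction_mean", "reaction_kmax", "seed", "n_duplicates")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  for (f in c("drug_catalog", "reaction_catalog", "sex_probs")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$signals)) {
    args$signals <- purrr::map_dfr(raw$signals, function(s) {
      for (f in c("drug", "reaction_pt")) {
        if (is.null(s[[f]])) abort(sprintf("signal entry missing field: %s", f))
      }
      planted_signal(s$drug, s$reaction_pt,
                     rho_male = s$rho_male %||% 1,
                     rho_female = s$rho_female %||% 1)
    })
  }
  do.call(sim_config, args)
}
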