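---
title: "Sex-stratified disproportionality analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified disproportionality analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexsignal)
library(dplyr)
```

## The problem

Spontaneous-reporting pharmacovigilance databases collect individual case
safety reports (ICSRs): one report per patient, each naming one or more
suspect drugs and one or more coded adverse reactions, usually with the
patient's sex. Because there is no denominator of exposed patients,
drug–event associations are screened by *disproportionality*: is the pair
reported more often than expected if drug and reaction were independent
across the database? Sex modulates both innate and adaptive immunity, so a
drug's adverse-event profile can differ between males and females; running
the same disproportionality screen inside each sex stratum, and then
comparing the per-sex estimates, is a simple and transparent way to look
for that dimorphism.

`sexsignal` implements this pipeline end to end: a data model for ICSRs
with a two-level reaction hierarchy (preferred term → system organ class),
stratified 2×2 counting, the Bayesian information component with exact
credibility intervals plus the classical ROR/PRR comparators, a
sex-difference classifier, and a fully specified synthetic ICSR generator
that provides ground truth for every stage.

## The statistic

For a drug–reaction pair in a stratum, let `N_obs` be the number of
distinct reports carrying both, `N_drug` and `N_reaction` the marginal
report counts, and `N_total` the stratum size. Under independence the
expected co-report count is

```
N_exp = N_drug * N_reaction / N_total .
```

The information component (IC), from the Bayesian confidence propagation
neural network (BCPNN) tradition, is the shrunken log ratio

```
IC = log2( (N_obs + 0.5) / (N_exp + 0.5) ) .
```

The matched +0.5 constants shrink small-count pairs toward 0 (IC is exactly
0 when observed equals expected) and keep the estimate finite at
`N_obs = 0`. For the credibility interval we use the standard conjugate
formulation: the relative reporting rate has a
`Gamma(shape = N_obs + 0.5, rate = N_exp + 0.5)` posterior, and `IC025` /
`IC975` are the log2-transformed exact 2.5% and 97.5% posterior quantiles
(`stats::qgamma`). The point IC is the log2 posterior mean, so it always
lies strictly inside the interval. `IC025 > 0` is the conventional signal
criterion. A normal approximation on the log-gamma scale
(`IC ± z·sqrt(trigamma(N_obs + 0.5))/ln 2`) is available behind
`method = "normal"` for comparison; the gamma quantiles are the default and
are validated in the test suite against Monte-Carlo draws from the stated
posterior (agreement within 0.01 IC units across a grid of small and large
counts).

The comparators follow standard practice: `ROR = ad/bc` on the 2×2 cells
with a log-normal Wald interval, and
`PRR = (a/N_drug) / (c/(N_total − N_drug))` likewise; any zero cell
triggers the Haldane–Anscombe +0.5 correction on all four cells and is
flagged. On large, well-populated tables with a rare drug, ROR, PRR and
`2^IC` agree within a few percent — a consistency property the tests
exercise.

## Counting rules

All counts are *distinct reports*: a report mentioning a reaction twice
counts once, and duplicate case identifiers are merged (drug and reaction
sets unioned; conflicting known sexes resolve to `unknown` with a warning)
before analysis. Stratified analyses use fully within-stratum totals — all
four counts restricted to the stratum — which is the standard subgroup
disproportionality design and keeps the male and female ICs independent
comparisons. Reports with unknown sex are excluded from the male and female
strata but included in `stratum = "all"`. A stratum in which the pair was
never co-reported (`N_obs = 0`) renders `NA` for IC and its bounds, rather
than the finite but meaningless shrunken value.

## Sex-difference classification

The per-reaction comparison assigns one of six labels from the per-sex
intervals: `male_only` / `female_only` when the reaction is a signal in one
sex and absent (never co-reported) in the other; `male_stronger` /
`female_stronger` when one sex is a signal and the other stratum is present
but either not a signal or has a credibility interval entirely below it
(interval separation, e.g. male IC025 above female IC975); `both_equal`
when both are signals with overlapping intervals; `neither` otherwise.
"Stronger association" has no canonical operational definition in the
disproportionality literature; interval separation was chosen because it is
conservative, testable, and antisymmetric under swapping the sexes (a
property the test suite checks over randomised inputs).

## The synthetic generator

Real pharmacovigilance databases are access-restricted, so the package
ships a generative model that emulates their structure with known ground
truth. Per report: a sex drawn from `(male, female, unknown)` probabilities
(default `0.45 / 0.51 / 0.04`, a female reporting excess typical of
spontaneous-report data); exactly one primary suspect drug from a 20-drug
catalog (default: the drug of interest at a 2% share plus 19 background
drugs with Zipf-decaying shares); and `k` reactions (truncated-geometric
`k`, default mean 2.5, maximum 6) from a 40+-term catalog with
inverse-square-root decaying marginals.

Two numerical choices matter:

* **Exact inclusion probabilities.** The `k` background reactions are drawn
  by systematic probability-proportional-to-size (Madow) sampling, so the
  marginal probability that reaction `r` appears in a report with `k`
  reactions is *exactly* `k·p_r` (this requires `kmax · max(p_r) ≤ 1`,
  validated at configuration time). Joint inclusions are weakly correlated,
  which is irrelevant to pairwise drug–reaction independence.
* **Multiplicative signal injection.** A planted signal with relative rate
  `ρ` rescales the signal reaction's inclusion probability among reports
  carrying the signal drug to `min(1, ρ·q)`, where `q = E[k]·p_r` is the
  background inclusion probability — implemented exactly, by adding the
  reaction with the complementary probability when `ρ > 1` and thinning it
  with probability `ρ` when `ρ < 1`. Clamped probabilities are counted and
  reported. Consequently the observed/expected ratio converges to
  `ρ / (1 + f_drug·(ρ − 1))`, i.e. to `ρ` up to a term that vanishes for
  rare drugs; `true_ic()` returns `log2(ρ)`, the asymptotic target. Tests
  that quantify estimator error therefore plant signals on drugs with small
  (1–2%) market share, where the residual bias is a small fraction of the
  tolerance. Sex-unknown reports take `ρ = 1`.

The generator does *not* emulate reporting-delay dynamics, country or age
structure, drug-name noise, masking/competition between signals, or
polypharmacy (each report carries one primary suspect drug, which keeps
`N_drug` well-defined). Passing tests on synthetic data therefore validate
the estimators and the pipeline plumbing under a clean reporting model;
they do not certify behaviour under the biases of real spontaneous-report
data.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:
hand-enumerated counts on a six-report toy set; closed-form IC values
(`IC(8, 8) = 0`, `IC(0, 7.5) = −4` exactly); Monte-Carlo gamma-posterior
quantiles (10^6 draws per grid point, 0.01 IC-unit agreement); type-I error
on a null database (10 replicates of 100,000 reports over a 20-drug ×
40-reaction catalog: the per-pair flag rate must stay at or below 5%, and
sits below the nominal one-sided 2.5% because small-count pairs are
conservative); and parameter recovery (20 replicates of 200,000 reports
with planted `ρ ∈ {2, 8}` and expected pair counts above 50: the IC is
within 0.3 of `log2 ρ`, and a male-only planted signal classifies as
`male_only`/`male_stronger`, in at least 90% of replicates). These sizes
give each check three or more Monte-Carlo standard errors of headroom while
keeping the default run lightweight.

Published summary arithmetic is reproduced from the printed counts of a
published sex-stratified analysis of dupilumab reports
(2,910 reports; 2,581 with sex information; 2,001 female; 1,768 male →
88.7% with sex information, 77.5% / 68.5% per sex, F:M ratio 1.13:1).
Those per-sex counts do not partition the sexed total — they come from
overlapping tabulations — so `summary_from_counts()` warns and uses the
sexed total as the denominator, which is exactly how the printed
percentages recompute. Dataset-derived summaries from
`summary_statistics()` always satisfy the partition identity.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_reports = 200000,
  signals = planted_signal("dupilumab", "dry_eye", rho_male = 8, rho_female = 2),
  seed = 20211
)
reports <- simulate_icsr(cfg)

evaluate_pair(reports, "dupilumab", "dry_eye", stratum = "male")

comparison <- run_comparison(reports, "dupilumab")
glance(comparison)
plot_ic_forest(comparison)

summary_statistics(reports, "dupilumab")
```

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `level` | intervals, comparisons | 0.95 | credibility/confidence level; `IC025 > 0` at 0.95 is the signal rule |
| `method` | intervals | `"gamma"` | exact posterior quantiles vs log-gamma normal approximation |
| `sex_probs` | generator | 0.45/0.51/0.04 | male/female/unknown mix |
| `reaction_mean`, `reaction_kmax` | generator | 2.5, 6 | truncated-geometric reactions per report |
| `rho_male`, `rho_female` | planted signals | 1 | per-sex relative reporting rate; `log2 ρ` is the IC target |
| `digits` | exports | 2 (comparison), 4 (results) | display rounding; internals stay full precision |

## Known limitations

* The PT→SOC map shipped with the package is a small synthetic stand-in for
  the licensed MedDRA dictionary (a mono-hierarchy: each PT belongs to one
  SOC); real MedDRA has five levels and multi-axiality.
* No multiple-comparison adjustment is applied across reactions — standard
  for IC-based screening, but flags are hypotheses, not confirmed risks.
* Drug names are matched exactly; there is no normalisation of synonyms or
  combination products.
* The interval-separation rule for `male_stronger`/`female_stronger` is
  conservative; it is not a formal interaction test between sexes.
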