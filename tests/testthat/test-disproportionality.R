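test_that("the IC point estimate evaluates the shrunken log2 ratio exactly", {
  expect_equal(ic_point(40, 8), log2(40.5 / 8.5))
  expect_equal(ic_point(40, 8), 2.252387, tolerance = 1e-6)
  expect_identical(ic_point(8, 8), 0)        # symmetric shrinkage constants
  expect_identical(ic_point(0, 7.5), -4)     # 0.5/8 is an exact power of two
  counts <- data.frame(n_observed = 40, n_drug = 100, n_reaction = 80,
                       n_total = 1000)
  expect_equal(information_component(counts), log2(40.5 / 8.5))
})

test_that("the IC is monotone in observed and expected counts", {
  grid <- tidyr::expand_grid(n_obs = c(0, 1, 5, 40, 500),
                             n_exp = c(0.5, 2, 8, 100))
  for (e in unique(grid$n_exp)) {
    ics <- ic_point(sort(unique(grid$n_obs)), e)
    expect_true(all(diff(ics) > 0))
  }
  for (o in unique(grid$n_obs)) {
    ics <- ic_point(o, sort(unique(grid$n_exp)))
    expect_true(all(diff(ics) < 0))
  }
})

test_that("shrinkage vanishes as counts scale up", {
  raw_ratio <- log2(12 / 5)
  ks <- c(1, 10, 100, 1e4, 1e6)
  errs <- abs(ic_point(12 * ks, 5 * ks) - raw_ratio)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 1e-6)
})

test_that("credibility bounds bracket the point IC and tighten with information", {
  ci <- ic_interval(40, 8)
  expect_lt(ci$ic025, ic_point(40, 8))
  expect_gt(ci$ic975, ic_point(40, 8))
  ci10 <- ic_interval(400, 80)
  expect_lt(ci10$ic975 - ci10$ic025, ci$ic975 - ci$ic025)

  big <- ic_interval(1e6, 1e6)
  expect_lt(big$ic025, 0)
  expect_gt(big$ic975, 0)
  expect_lt(big$ic975 - big$ic025, 0.01)

  expect_error(ic_interval(5, 5, level = 1.2), "level")
  expect_error(ic_interval(5, 5, level = 1), "level")
})

test_that("gamma bounds match a Monte-Carlo posterior oracle", {
  set.seed(401)
  for (case in list(c(40, 8), c(1, 0.5), c(5, 100))) {
    draws <- log2(stats::rgamma(1e6, shape = case[1] + 0.5, rate = case[2] + 0.5))
    mc <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    ci <- ic_interval(case[1], case[2])
    expect_equal(ci$ic025, mc[1], tolerance = 0.01)
    expect_equal(ci$ic975, mc[2], tolerance = 0.01)
  }
})

test_that("the normal approximation tracks the exact bounds for large counts", {
  g <- ic_interval(500, 400, method = "gamma")
  n <- ic_interval(500, 400, method = "normal")
  expect_lt(abs(n$ic025 - g$ic025), 0.02)
  expect_lt(abs(n$ic975 - g$ic975), 0.02)
})

test_that("ROR matches direct arithmetic and handles degenerate tables", {
  counts <- data.frame(n_observed = 40, n_drug = 100, n_reaction = 80,
                       n_total = 1000)
  r <- reporting_odds_ratio(counts)   # cells 40, 60, 40, 860
  expect_equal(r$ror, (40 * 860) / (60 * 40))
  expect_false(r$ror_corrected)
  expect_lt(r$ror_low, r$ror)
  expect_gt(r$ror_high, r$ror)

  prop <- data.frame(n_observed = 10, n_drug = 30, n_reaction = 40,
                     n_total = 120)  # cells 10,20,30,60: proportional rows
  expect_equal(reporting_odds_ratio(prop)$ror, 1)

  zero <- data.frame(n_observed = 0, n_drug = 60, n_reaction = 40,
                     n_total = 961)  # a=0 -> Haldane-Anscombe on all cells
  rz <- reporting_odds_ratio(zero)
  expect_true(rz$ror_corrected)
  expect_equal(rz$ror, (0.5 * 861.5) / (60.5 * 40.5))
})

test_that("PRR matches direct arithmetic and requires a comparator population", {
  counts <- data.frame(n_observed = 40, n_drug = 100, n_reaction = 80,
                       n_total = 1000)
  p <- proportional_reporting_ratio(counts)
  expect_equal(p$prr, (40 / 100) / (40 / 900))
  expect_equal(p$prr, 9)
  expect_false(p$prr_corrected)

  equal_rates <- data.frame(n_observed = 10, n_drug = 100, n_reaction = 100,
                            n_total = 1000)  # 10/100 == 90/900
  expect_equal(proportional_reporting_ratio(equal_rates)$prr, 1)

  zero_c <- data.frame(n_observed = 12, n_drug = 50, n_reaction = 12,
                       n_total = 500)  # c = 0 -> corrected
  pz <- proportional_reporting_ratio(zero_c)
  expect_true(pz$prr_corrected)
  expect_equal(pz$prr, (12.5 / 51) / (0.5 / 451))

  no_comp <- data.frame(n_observed = 5, n_drug = 50, n_reaction = 10,
                        n_total = 50)
  expect_error(proportional_reporting_ratio(no_comp), "comparator")
})

test_that("ROR, PRR and 2^IC agree on large well-populated tables", {
  grid <- tidyr::expand_grid(n_drug = c(1500, 2000, 2500),
                             n_reaction = c(4000, 5000, 6000),
                             rho = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    n_total <- 200000
    n_drug <- grid$n_drug[i]
    n_reaction <- grid$n_reaction[i]
    n_exp <- n_drug * n_reaction / n_total
    n_obs <- round(grid$rho[i] * n_exp)
    counts <- data.frame(n_observed = n_obs, n_drug = n_drug,
                         n_reaction = n_reaction, n_total = n_total)
    est <- c(2^information_component(counts),
             reporting_odds_ratio(counts)$ror,
             proportional_reporting_ratio(counts)$prr)
    expect_lt(max(est) / min(est), 1.1)
  }
})

test_that("evaluate_pair composes counts and statistics on the toy set", {
  res <- evaluate_pair(toy6_reports(), "D", "X", "male")
  expect_equal(res$n_observed, 1L)
  expect_equal(res$n_expected, 1)
  expect_equal(res$ic, log2(1.5 / 1.5))
  expect_false(res$is_na)
  expect_true(res$ic025 < res$ic & res$ic < res$ic975)
  expect_identical(res$is_signal, res$ic025 > 0)

  # unobserved pair: NA convention
  na_res <- evaluate_pair(toy6_reports(), "D", "Z", "male")
  expect_true(na_res$is_na)
  expect_true(is.na(na_res$ic) && is.na(na_res$ic025) && is.na(na_res$ic975))
  expect_false(na_res$is_signal)

  expect_error(evaluate_pair(toy6_reports()[0, ], "D", "X", "all"),
               "undefined stratum")
})

test_that("the screening table matches pairwise evaluation", {
  cfg <- sim_config(3000, seed = 55)
  reports <- simulate_icsr(cfg)
  tab <- disproportionality_table(
    reports, "female",
    pairs = tibble::tibble(drug = "dupilumab",
                           reaction_pt = c("dry_eye", "headache", "seminoma")))
  for (i in seq_len(nrow(tab))) {
    single <- evaluate_pair(reports, "dupilumab", tab$reaction_pt[i], "female")
    expect_equal(as.data.frame(tab[i, ]),
                 as.data.frame(single[names(tab)]))
  }
})
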