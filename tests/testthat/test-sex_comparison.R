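test_that("published-style IC triples classify into the expected sex patterns", {
  # male signal, reaction never reported in females
  expect_equal(classify_sex_pattern(0.45, 3.69, NA, NA), "male_only")
  # both signals, male interval entirely above the female interval
  expect_equal(classify_sex_pattern(5.59, 6.11, 4.78, 5.33), "male_stronger")
  # female signal, reaction never reported in males
  expect_equal(classify_sex_pattern(NA, NA, 1.21, 3.73), "female_only")
  # both signals with overlapping intervals
  expect_equal(classify_sex_pattern(5.62, 5.81, 4.85, 6.0), "both_equal")
  # no signal anywhere
  expect_equal(classify_sex_pattern(-0.5, 1.0, -0.3, 0.8), "neither")
  # male signal, female present but not a signal
  expect_equal(classify_sex_pattern(0.92, 1.67, -0.49, 0.26), "male_stronger")
})

test_that("classify_pattern accepts evaluate_pair-style rows", {
  male <- tibble::tibble(ic = 2.5, ic025 = 0.45, ic975 = 3.69)
  female <- tibble::tibble(ic = NA_real_, ic025 = NA_real_, ic975 = NA_real_)
  expect_equal(classify_pattern(male, female), "male_only")
  expect_equal(classify_pattern(female, male), "female_only")
})

test_that("pattern classification is antisymmetric under sex swap", {
  set.seed(501)
  swap_map <- c(male_only = "female_only", female_only = "male_only",
                male_stronger = "female_stronger",
                female_stronger = "male_stronger",
                both_equal = "both_equal", neither = "neither")
  for (i in 1:200) {
    m025 <- if (runif(1) < 0.15) NA_real_ else runif(1, -3, 3)
    f025 <- if (runif(1) < 0.15) NA_real_ else runif(1, -3, 3)
    m975 <- m025 + runif(1, 0.1, 3)
    f975 <- f025 + runif(1, 0.1, 3)
    fwd <- classify_sex_pattern(m025, m975, f025, f975)
    rev <- classify_sex_pattern(f025, f975, m025, m975)
    expect_identical(rev, unname(swap_map[fwd]))
  }
})

test_that("summary percentages and ratio recompute exactly from counts", {
  s <- suppressWarnings(summary_from_counts(2910, 2581, 2001, 1768))
  expect_equal(round(s$pct_with_sex, 1), 88.7)
  expect_equal(round(s$pct_female_of_sexed, 1), 77.5)
  expect_equal(round(s$pct_male_of_sexed, 1), 68.5)
  expect_equal(round(s$f_to_m_ratio, 2), 1.13)
  # non-partition counts warn but still compute against n_with_sex
  expect_warning(summary_from_counts(2910, 2581, 2001, 1768), "denominator")

  even <- summary_from_counts(120, 100, 50, 50)
  expect_equal(even$f_to_m_ratio, 1)
  expect_equal(even$pct_female_of_sexed, 50)

  all_female <- summary_from_counts(60, 50, 50, 0)
  expect_true(is.na(all_female$f_to_m_ratio))
})

test_that("dataset-derived summaries satisfy the partition identity", {
  reports <- make_reports(
    case_id = sprintf("c%d", 1:8),
    sex = c("male", "male", "female", "female", "female", "unknown", "male", "female"),
    drugs = c("D", "D", "D", "D", "E", "D", "E", "D"),
    reactions = rep("X", 8)
  )
  s <- summary_statistics(reports, "D")
  expect_equal(s$n_reports_total, 6L)
  expect_equal(s$n_with_sex, 5L)
  expect_equal(s$n_female + s$n_male, s$n_with_sex)
  expect_equal(s$pct_with_sex, 100 * 5 / 6)
  expect_equal(s$f_to_m_ratio, 3 / 2)
})

test_that("a planted male-only signal is recovered as male_only", {
  cfg <- recovery_config(150000, seed = 61, rho_male = 8, rho_female = 0)
  reports <- simulate_icsr(cfg)
  comp <- run_comparison(reports, "drug_20")
  row <- comp[comp$reaction_pt == "seminoma", ]
  expect_equal(row$pattern, "male_only")
  expect_true(row$male_is_signal)
  expect_true(row$female_is_na)
  expect_true(is.na(row$female_ic))
})

test_that("a symmetric planted signal is recovered as both_equal", {
  cfg <- sim_config(
    150000,
    signals = planted_signal("drug_20", "seminoma", rho_male = 8, rho_female = 8),
    seed = 62
  )
  reports <- simulate_icsr(cfg)
  comp <- run_comparison(reports, "drug_20")
  expect_equal(comp$pattern[comp$reaction_pt == "seminoma"], "both_equal")
})

test_that("comparison rows are sorted, labelled with SOC, and total over patterns", {
  cfg <- sim_config(20000, seed = 63)
  reports <- simulate_icsr(cfg)
  comp <- run_comparison(reports, "dupilumab")
  expect_s3_class(comp, "sexsig_comparison")
  expect_false(is.unsorted(comp$soc_code))
  expect_true(all(comp$pattern %in% c("male_only", "female_only", "male_stronger",
                                      "female_stronger", "both_equal", "neither")))
  expect_true(all(comp$soc_code != "UNMAPPED"))
  # every reaction co-reported with the drug in a sexed stratum appears once
  expect_false(any(duplicated(comp$reaction_pt)))

  expect_warning(empty <- run_comparison(reports, "nosuchdrug"), "not present")
  expect_equal(nrow(empty), 0L)
})

test_that("tidy and glance views are consistent with the wide table", {
  cfg <- sim_config(20000, seed = 64,
                    signals = planted_signal("dupilumab", "seminoma", 8, 8))
  reports <- simulate_icsr(cfg)
  comp <- run_comparison(reports, "dupilumab")
  long <- generics::tidy(comp)
  expect_equal(nrow(long), 2L * nrow(comp))
  expect_setequal(unique(long$sex), c("male", "female"))
  m <- long[long$sex == "male", ]
  expect_equal(m$ic[match(comp$reaction_pt, m$reaction_pt)], comp$male_ic)

  g <- generics::glance(comp)
  expect_equal(g$n_reactions, nrow(comp))
  expect_equal(g$n_male_signals, sum(comp$male_is_signal))
  pattern_cols <- c("male_only", "female_only", "male_stronger",
                    "female_stronger", "both_equal", "neither")
  expect_equal(sum(unlist(g[pattern_cols])), nrow(comp))

  expect_s3_class(plot_ic_forest(comp), "gg")
  expect_s3_class(plot_ic_heatmap(comp), "gg")
  expect_s3_class(ggplot2::autoplot(comp), "gg")
})
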