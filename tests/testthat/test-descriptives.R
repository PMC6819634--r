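test_that("class summary reproduces the published one-decimal percentages", {
  counts <- reference_class_counts()
  cls <- rep(names(counts), counts)
  s <- summarize_classes(cls)
  expect_equal(s$total, 10966)
  expect_equal(unname(s$percents),
               c(7.5, 3.2, 76.9, 2.4, 5.4, 4.7))
  expect_equal(s$consistent_pct, 87.6)
  expect_equal(s$inconsistent_pct, 12.4)
  expect_equal(s$ever_reported_pct, 23.1)
  expect_equal(s$consistent_ipv_any_pct, 10.7)
  expect_equal(unname(s$within_inconsistent_pct), c(19, 43, 38))
})

test_that("summary percentages sum to ~100 and handle degenerate cohorts", {
  set.seed(21)
  for (rep in 1:20) {
    counts <- stats::setNames(sample(0:500, 6, replace = TRUE),
                              ipv_classes())
    if (sum(counts) == 0) counts[1] <- 1
    s <- summarize_classes(rep(names(counts), counts))
    # six cells each rounded to one decimal: worst-case drift 6 * 0.05
    expect_lt(abs(sum(s$percents) - 100), 0.31)
  }
  one <- summarize_classes(rep("MAINLY_IPV", 10))
  expect_equal(unname(one$percents["MAINLY_IPV"]), 100)
  expect_equal(sum(one$percents), 100)

  expect_error(summarize_classes(character(0)), "empty")
  expect_error(summarize_classes(c("MAINLY_IPV", "INELIGIBLE")),
               "INELIGIBLE")
})

test_that("rounding of table cells is half-up", {
  expect_equal(round_half_up(100 * 587 / 10966, 1), 5.4)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.5), 3)
})

test_that("class by answered-count table has the structural MIXED zero", {
  co <- classify_cohort(filter_eligible(
    simulate_cohort(sim_params(n = 20000, seed = 13)))$cohort)
  tab <- tabulate_by_nsurveys(co)
  expect_equal(tab$counts["3", "MIXED_IPV"], 0)
  sums <- colSums(tab$percent[, tab$col_n > 0])
  expect_true(all(abs(sums - 100) < 0.21))
})

test_that("all-women column percentage reflects constructed answer margins", {
  # cohort built so that 7135 of 10966 answer all six waves
  pats <- c(rep("NNNNNN", 7135), rep("NNNNN.", 1722), rep("NNNN..", 1173),
            rep("NNN...", 936))
  co <- classify_cohort(make_cohort(pats))
  tab <- tabulate_by_nsurveys(co)
  expect_equal(unname(tab$percent["6", "all_women"]), 65.1)
})

test_that("characteristics table weights and rescales correctly", {
  co <- classify_cohort(make_cohort(c("YYY", "YYY"),
                                    area = c("major_city",
                                             "remote_very_remote")))
  pr <- build_profiles(co)
  # only one class is populated, so the empty columns warn once
  expect_warning(tab <- characteristics_table(pr), "zero total weight")
  expect_equal(tab$CONSISTENT_IPV[tab$level == "major_city"], 66.7)
  expect_equal(tab$CONSISTENT_IPV[tab$level == "remote_very_remote"], 33.3)

  # equal weights match the unweighted table
  pr_eq <- pr
  pr_eq$weight <- 1
  expect_equal(suppressWarnings(characteristics_table(pr_eq)),
               suppressWarnings(characteristics_table(pr,
                                                      weighted = FALSE)))

  # global rescaling leaves percentages unchanged
  pr_scaled <- pr
  pr_scaled$weight <- pr$weight * 7.3
  expect_equal(suppressWarnings(characteristics_table(pr_scaled)),
               suppressWarnings(characteristics_table(pr)))
})

test_that("never-IPV column has the highest never-separated share", {
  co <- filter_eligible(simulate_cohort(sim_params(n = 30000, seed = 17)))
  pr <- build_profiles(classify_cohort(co$cohort))
  tab <- characteristics_table(pr)
  row <- tab[tab$variable == "trajectory" & tab$level == "NEVER_SEP_DIV",
             ipv_classes()]
  expect_equal(names(which.max(unlist(row))), "CONSISTENT_NEVER_IPV")
})
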