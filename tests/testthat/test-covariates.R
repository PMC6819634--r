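test_that("relationship trajectories follow first/last/ever separation", {
  tr <- function(...) {
    v <- c(...)
    as.character(derive_trajectory(c(v, rep(NA, 6 - length(v)))))
  }
  expect_equal(tr(rep("married", 6)), "NEVER_SEP_DIV")
  expect_equal(tr("divorced", "divorced", "separated"), "REMAINED_SEP_DIV")
  expect_equal(tr("married", "married", "divorced", "divorced"),
               "BECAME_SEP_DIV")
  expect_equal(tr("separated", "married", "married"), "BECAME_PARTNERED")
  # widowed/single are "not separated or divorced"
  expect_equal(tr("widowed", "single", "widowed"), "NEVER_SEP_DIV")
  expect_equal(tr("single", "separated", "widowed"), "BECAME_SEP_DIV")
  # multi-transition history: first and last answered status decide
  expect_equal(tr("separated", "married", "separated"), "REMAINED_SEP_DIV")
  expect_true(is.na(derive_trajectory(rep(NA_character_, 6))))
  expect_error(derive_trajectory(c("espoused", rep(NA, 5))), "invalid")
})

test_that("trajectory and stress derivations ignore MISSING positions", {
  set.seed(3)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    st <- sample(REL_LEVELS <- c("married", "defacto", "separated",
                                 "divorced", "widowed", "single"),
                 k, replace = TRUE)
    waves <- sort(sample(1:6, k))
    spread <- rep(NA_character_, 6)
    spread[waves] <- st
    expect_equal(derive_trajectory(c(st, rep(NA, 6 - k))),
                 derive_trajectory(spread))

    sv <- sample(c(TRUE, FALSE), k, replace = TRUE)
    spread_s <- rep(NA, 6)
    spread_s[waves] <- sv
    expect_equal(derive_stress_half(c(sv, rep(NA, 6 - k))),
                 derive_stress_half(spread_s))
  }
})

test_that("sustained stress uses >= half of answered items, ties inclusive", {
  expect_true(derive_stress_half(c(TRUE, TRUE, FALSE, NA, NA, NA)))
  expect_false(derive_stress_half(c(TRUE, FALSE, FALSE, FALSE, NA, NA)))
  expect_true(derive_stress_half(c(TRUE, FALSE, TRUE, FALSE, NA, NA)))
  expect_true(is.na(derive_stress_half(rep(NA, 6))))
})

test_that("design weights halve the oversampled strata and honour configs", {
  expect_equal(assign_weight("major_city"), 1)
  expect_equal(assign_weight("remote_very_remote"), 0.5)
  expect_equal(assign_weight(c("inner_regional", NA)), c(0.5, NA))
  custom <- c(default_weight_scheme()[-2], inner_regional = 1)
  expect_equal(assign_weight("inner_regional", scheme = custom), 1)
  expect_error(assign_weight("major_city", scheme = c(foo = 1)),
               "lacks area level")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("major_city: 1.0", "inner_regional: 1.0",
               "outer_regional: 0.5", "remote_very_remote: 0.5"), path)
  expect_equal(assign_weight("inner_regional", scheme = path), 1)
})

test_that("profiles carry one row per record with correct categories", {
  co <- make_cohort(c("YYYYYY", "NNNNY.", "YNY...", "NNNN.."),
                    rel = "married", istress = TRUE)
  pr <- build_profiles(classify_cohort(co))
  expect_equal(nrow(pr), 4)
  expect_equal(as.character(pr$n_surveys_cat),
               c("SIX", "FIVE", "THREE_FOUR", "THREE_FOUR"))
  expect_equal(sum(table(pr$n_surveys_cat)), nrow(pr))
  expect_true(all(pr$complete))
  expect_true(all(pr$weight == 1))
  expect_true(all(pr$istress_half))

  df <- as.data.frame(co)
  df$area[2] <- NA
  pr2 <- build_profiles(classify_cohort(as_cohort(df)))
  expect_equal(pr2$complete, c(TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(pr2$weight[2]))
})

test_that("build_profiles refuses ineligible records", {
  co <- classify_cohort(make_cohort(c("YYY", "Y.....")))
  expect_error(build_profiles(co), "ineligible")
})

test_that("injected covariate missingness is flagged at the injected rate", {
  params <- sim_params(n = 2000, seed = 5)
  co <- filter_eligible(simulate_cohort(params))$cohort
  df <- as.data.frame(co)
  set.seed(5)
  hit <- sample(nrow(df), round(0.01 * nrow(df)))
  df$area[hit] <- NA
  pr <- build_profiles(classify_cohort(as_cohort(df)))
  expect_equal(sum(!pr$complete), length(hit))
})
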