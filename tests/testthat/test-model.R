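test_that("saturated 2-outcome fit equals the closed-form odds ratio", {
  # 2x2 table of outcome (case = MAINLY_NO_IPV) by exposure
  n11 <- 75   # exposed case
  n01 <- 225  # unexposed case
  n10 <- 40   # exposed control
  n00 <- 160  # unexposed control
  df <- data.frame(
    consistency_class = factor(rep(c("CONSISTENT_IPV", "MAINLY_NO_IPV",
                                     "CONSISTENT_IPV", "MAINLY_NO_IPV"),
                                   c(n00, n01, n10, n11))),
    exposed = rep(c(FALSE, TRUE), c(n00 + n01, n10 + n11))
  )
  fit <- fit_consistency_model(consistency_class ~ exposed, data = df)
  or_closed <- (n11 * n00) / (n10 * n01)
  got <- or_table(fit)
  expect_equal(got$outcome_class, "MAINLY_NO_IPV")
  expect_equal(got$or, or_closed, tolerance = 1e-4 / or_closed)
  expect_lt(abs(got$or - or_closed), 1e-4)
})

test_that("collapsing to two outcomes reproduces binary logistic regression", {
  set.seed(31)
  n <- 1500
  x <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  z <- stats::runif(n) < 0.4
  eta <- -0.5 + 0.8 * (x == "b") - 0.4 * (x == "c") + 0.6 * z
  y <- stats::runif(n) < stats::plogis(eta)
  df <- data.frame(
    consistency_class = factor(ifelse(y, "MIXED_IPV", "CONSISTENT_IPV"),
                               levels = c("CONSISTENT_IPV", "MIXED_IPV")),
    x = x, z = z)
  fit <- fit_consistency_model(consistency_class ~ x + z, data = df)
  glm_fit <- stats::glm(y ~ x + z, family = stats::binomial())
  expect_equal(unname(coef(fit)[1, ]), unname(stats::coef(glm_fit)),
               tolerance = 1e-5)
})

test_that("null covariates give odds ratios compatible with 1", {
  set.seed(41)
  n <- 5000
  df <- data.frame(
    consistency_class = factor(sample(ipv_classes(), n, replace = TRUE,
                                      prob = c(8, 3, 77, 2, 5, 5))),
    x1 = stats::runif(n) < 0.3,
    x2 = factor(sample(c("p", "q", "r"), n, replace = TRUE))
  )
  fit <- fit_consistency_model(consistency_class ~ x1 + x2, data = df)
  tab <- or_table(fit)
  covered <- tab$ci_low <= 1 & tab$ci_high >= 1
  expect_gte(mean(covered), 0.9)
  expect_true(all(abs(tab$estimate) < 1))
})

test_that("fitted probabilities sum to one and likelihood beats uniform", {
  set.seed(51)
  df <- simulate_logit_outcomes(
    3000,
    base_probs = c(CONSISTENT_IPV = 0.075, CONSISTENT_LATER_IPV = 0.032,
                   CONSISTENT_NEVER_IPV = 0.769, MAINLY_IPV = 0.024,
                   MAINLY_NO_IPV = 0.054, MIXED_IPV = 0.047),
    beta = c(CONSISTENT_LATER_IPV = 0.2, CONSISTENT_NEVER_IPV = log(0.37),
             MAINLY_IPV = 0.1, MAINLY_NO_IPV = -0.3, MIXED_IPV = 0))
  fit <- fit_consistency_model(consistency_class ~ istress_half, data = df)
  p <- predict(fit)
  expect_true(all(abs(rowSums(p) - 1) < 1e-10))
  k <- nlevels(df$consistency_class)
  expect_gte(as.numeric(logLik(fit)), -nrow(df) * log(k))
  # class predictions are the max-probability class
  cls <- predict(fit, type = "class")
  expect_equal(as.character(cls), colnames(p)[max.col(p)])
})

test_that("reference levels, complete-case handling and errors are explicit", {
  set.seed(61)
  co <- filter_eligible(simulate_cohort(sim_params(n = 4000, seed = 3)))
  pr <- build_profiles(classify_cohort(co$cohort))
  pr$area[1:25] <- NA
  fit <- suppressWarnings(fit_consistency_model(data = pr))
  expect_equal(fit$n_used + fit$n_dropped, nrow(pr))
  expect_gte(fit$n_dropped, 25)
  tab <- or_table(fit)
  # reference covariate levels never appear as estimated rows
  expect_false(any(tab$level %in% c("major_city", "lt_year12",
                                    "NEVER_SEP_DIV", "SIX", "FALSE")))
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
  expect_true(all(tab$or > 0))

  expect_error(fit_consistency_model(data = pr, reference = "NOT_A_CLASS"),
               "absent")
  expect_error(fit_consistency_model(consistency_class ~ nope, data = pr),
               "not in data")
  one <- pr[pr$consistency_class == "CONSISTENT_NEVER_IPV", ]
  expect_error(fit_consistency_model(data = one,
                                     reference = "CONSISTENT_NEVER_IPV"),
               "at least 2 outcome classes")
})

test_that("separation is flagged, not silent", {
  df <- data.frame(
    consistency_class = factor(rep(c("CONSISTENT_IPV", "MIXED_IPV"),
                                   each = 40)),
    x = rep(c(FALSE, TRUE), each = 40)
  )
  expect_warning(fit_consistency_model(consistency_class ~ x, data = df),
                 "separation|converge")
})

test_that("sensitivity analysis restricts to six-survey responders", {
  co <- filter_eligible(simulate_cohort(sim_params(n = 6000, seed = 23)))
  pr <- build_profiles(classify_cohort(co$cohort))
  sens <- suppressWarnings(sensitivity_complete_responders(data = pr))
  expect_equal(sens$n_used + sens$n_dropped, sum(pr$answered_count == 6))
  expect_false("n_surveys_cat" %in% or_table(sens)$covariate)

  # with nobody missing a wave, it equals the full fit without the
  # survey-count term
  pr6 <- pr[pr$answered_count == 6, ]
  full6 <- suppressWarnings(
    fit_consistency_model(consistency_class ~ area + qual + trajectory +
                            pstress_half + istress_half, data = pr6))
  expect_equal(or_table(sens)$or, or_table(full6)$or, tolerance = 1e-8)

  pr_no6 <- pr[pr$answered_count < 6, ]
  expect_error(sensitivity_complete_responders(data = pr_no6),
               "no complete responders")
})
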