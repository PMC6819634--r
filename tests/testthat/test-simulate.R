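test_that("the same seed reproduces a bit-identical cohort", {
  p <- sim_params(n = 500, seed = 77)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_cohort(p, seed = 78)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("error-free generation yields no inconsistent classifications", {
  p <- sim_params(n = 4000, fp = 0, fn = 0, seed = 1)
  cls <- classify_sequences(filter_eligible(simulate_cohort(p))$cohort)
  expect_equal(sum(cls %in% c("MAINLY_IPV", "MAINLY_NO_IPV", "MIXED_IPV")),
               0)

  p0 <- sim_params(n = 2000, prev_ever = 0, fp = 0, seed = 2)
  cls0 <- classify_sequences(filter_eligible(simulate_cohort(p0))$cohort)
  expect_true(all(cls0 == "CONSISTENT_NEVER_IPV"))
})

test_that("the exact distribution is a probability vector with the right zeros", {
  d <- exact_class_distribution(sim_params(fp = 0, fn = 0))
  expect_lt(abs(sum(d) - 1), 1e-12)
  expect_equal(unname(d[c("MAINLY_IPV", "MAINLY_NO_IPV", "MIXED_IPV")]),
               c(0, 0, 0))

  # false positives alone can masquerade as later onset
  d2 <- exact_class_distribution(sim_params(prev_ever = 0, fp = 0.05,
                                            fn = 0))
  expect_gt(d2[["CONSISTENT_LATER_IPV"]], 0)
  expect_lt(abs(sum(d2) - 1), 1e-12)
})

test_that("simulated class frequencies match the enumeration oracle", {
  # property over several parameter settings, fixed seeds
  settings <- list(
    sim_params(n = 30000, seed = 101),
    sim_params(n = 30000, fp = 0.04, fn = 0.05, prev_ever = 0.3,
               seed = 102),
    sim_params(n = 30000, fp = 0.002, fn = 0.25, prev_ever = 0.1,
               monotone_mix = 0.2, seed = 103)
  )
  for (p in settings) {
    cls <- classify_sequences(filter_eligible(simulate_cohort(p))$cohort)
    emp <- table(factor(as.character(cls), levels = ipv_classes()))
    n <- sum(emp)
    ex <- exact_class_distribution(p)
    se <- sqrt(ex * (1 - ex) / n)
    z <- abs(emp / n - ex) / pmax(se, 1e-12)
    expect_true(all(z[ex > 0] < 4), info = paste(round(z, 2), collapse = " "))
    expect_true(all(emp[ex == 0] == 0))
  }
})

test_that("answered-wave margins track the requested proportions", {
  p <- sim_params(n = 40000, seed = 19)
  co <- simulate_cohort(p)
  cnt <- rowSums(!is.na(ipv_matrix(co)))
  elig <- is_eligible(co)
  got <- c(three = mean(cnt == 3 & elig), four = mean(cnt == 4 & elig),
           five = mean(cnt == 5 & elig), six = mean(cnt == 6 & elig))
  # beta_attrition_stress tilts margins for the stressed minority (~10% of
  # women), so agreement is Monte-Carlo error plus a small systematic shift
  expect_true(all(abs(got - p$answer_margins) < 0.015))
  expect_lt(abs(mean(!elig) - (1 - sum(p$answer_margins))), 0.015)
})

test_that("more false negatives mean more IPV-masking inconsistency", {
  fns <- seq(0, 0.3, by = 0.05)
  mass <- vapply(fns, function(fn) {
    d <- exact_class_distribution(sim_params(prev_ever = 1, fp = 0.01,
                                             fn = fn))
    d[["MAINLY_IPV"]] + d[["MIXED_IPV"]]
  }, 0)
  expect_true(all(diff(mass) >= -1e-12))
})

test_that("calibration recovers known parameters and reports infeasibility", {
  truth <- sim_params(fp = 0.01, fn = 0.1, prev_ever = 0.2,
                      onset_probs = c(0.6, 0, rep(0.08, 5)))
  target <- 100 * exact_class_distribution(truth)
  cal <- calibrate_error_rates(
    target, fixed = truth,
    fp_grid = c(0, 0.01, 0.02), fn_grid = c(0.05, 0.1, 0.15),
    prev_grid = c(0.15, 0.2, 0.25), onset0_grid = c(0.5, 0.6, 0.7),
    refine = FALSE)
  expect_equal(cal$params$fp, 0.01)
  expect_equal(cal$params$fn, 0.1)
  expect_equal(cal$params$prev_ever, 0.2)
  expect_equal(cal$params$onset_probs[1], 0.6)
  expect_lt(cal$distance, 1e-20)

  infeasible <- c(CONSISTENT_IPV = 10, CONSISTENT_LATER_IPV = 10,
                  CONSISTENT_NEVER_IPV = 20, MAINLY_IPV = 5,
                  MAINLY_NO_IPV = 5, MIXED_IPV = 50)
  cal2 <- calibrate_error_rates(infeasible, fixed = truth,
                                fp_grid = 0, fn_grid = 0,
                                prev_grid = 0.2, onset0_grid = 0.6,
                                refine = FALSE)
  expect_gt(cal2$distance, 100)

  expect_error(calibrate_error_rates(target, fixed = truth,
                                     fp_grid = numeric(0), fn_grid = 0,
                                     prev_grid = 0.2, onset0_grid = 0.6),
               "empty")
})

test_that("cross-sectional bias has the forced signs", {
  p0 <- sim_params(fp = 0, fn = 0)
  for (w in 1:6) expect_equal(cross_sectional_bias(p0, w), 0)

  p_fn <- sim_params(fp = 0, fn = 0.15)
  for (w in 1:6) expect_lt(cross_sectional_bias(p_fn, w), 0)

  p_fp <- sim_params(prev_ever = 0, fp = 0.05, fn = 0)
  expect_gt(cross_sectional_bias(p_fp, 3), 0)
})

test_that("presets load with overrides and bad input is rejected", {
  p <- load_preset("paper_like", n = 123, seed = 9)
  expect_s3_class(p, "ipv_sim_params")
  expect_equal(p$n, 123L)
  expect_equal(p$seed, 9L)

  p0 <- load_preset("null_model")
  expect_equal(p0$fp, 0)
  expect_equal(p0$fn, 0)

  expect_error(load_preset("no_such_preset"), "unknown preset")
  expect_error(sim_params(fp = 1.4), "must lie")
  expect_error(sim_params(onset_probs = rep(1, 3)), "onset_probs")
  expect_error(sim_params(answer_margins = c(three = 0.5, four = 0.6,
                                             five = 0, six = 0)),
               "at most 1")
})
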