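# Synthetic six-wave cohort generator and exact enumeration oracle.
#
# Generative model, per woman:
#   * latent lifetime IPV: ever ~ Bernoulli(prev_ever); conditional on ever,
#     an onset wave in 0..6 (0 = before wave 1). "Ever in a violent
#     relationship" is absorbing, so the truthful answer at wave w is YES iff
#     onset <= w; every observed inconsistency is reporting error by
#     construction.
#   * a woman-level stress propensity s (income-stress latent), more common
#     among ever-IPV women, which shifts the error and attrition rates on the
#     log-odds scale (the minimal mechanism producing group differences in
#     the characteristics table).
#   * reporting error: at an answered wave she reports YES with probability
#     1 - fn(s) if her truthful answer is YES, else with probability fp(s).
#   * attrition: the number of answered waves (3/4/5/6, or an ineligible
#     pattern) is drawn from answer_margins (tilted towards fewer waves for
#     stressed women); within a count the pattern is the monotone prefix with
#     probability monotone_mix, otherwise uniform over wave-1-answered
#     patterns — a monotone-dropout vs intermittent-skipping mixture.
#   * descriptive covariates (area, qualification, relationship trajectory,
#     per-wave stress items) are drawn conditionally on the latent state but
#     do not feed back into the response mechanism beyond s.
#
# exact_class_distribution() computes the consistency-class distribution
# implied by these parameters exactly, by summing over onset (8 states),
# stress (2), answered patterns (26 eligible) and response strings (<= 2^6),
# conditioned on eligibility. It is the oracle against which simulated
# cohorts are checked.

.ipv_env <- new.env(parent = emptyenv())

# All eligible answered-wave patterns (wave 1 answered, k = 3..6 answers),
# each with every YES/NO response string pre-classified. Parameter-free, so
# computed once and cached.
pattern_table <- function() {
  if (!is.null(.ipv_env$pattern_table)) return(.ipv_env$pattern_table)
  out <- list()
  for (k in 3:6) {
    sets <- utils::combn(2:6, k - 1)
    for (j in seq_len(ncol(sets))) {
      waves <- c(1L, sets[, j])
      yes <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
      dimnames(yes) <- NULL
      m <- matrix(NA_character_, nrow(yes), N_WAVES)
      m[, waves] <- ifelse(yes, "Y", "N")
      cls <- match(as.character(classify_sequences(m)), ipv_classes())
      out[[length(out) + 1]] <- list(waves = waves, k = k, yes = yes,
                                     cls = cls,
                                     prefix = identical(waves, seq_len(k)))
    }
  }
  .ipv_env$pattern_table <- out
  out
}

#' Default covariate parameters for the simulator
#'
#' Category probabilities for area (reflecting the two-fold rural/remote
#' oversampling) and qualification, the stress-propensity rates by latent IPV
#' status, the log-odds effects of the stress propensity on the false-negative
#' rate, false-positive rate and attrition, per-wave stress item rates, and
#' relationship-trajectory probabilities by latent IPV status.
#'
#' @return named list; see the fields in the function body.
#' @export
default_covariate_params <- function() {
  list(
    area_probs = c(major_city = 0.51, inner_regional = 0.31,
                   outer_regional = 0.15, remote_very_remote = 0.03),
    qual_probs = c(lt_year12 = 0.45, year12 = 0.17,
                   trade_cert_diploma = 0.20, university = 0.18),
    p_stress_ever = 0.22,    # P(stress propensity | ever IPV)
    p_stress_never = 0.08,
    beta_fn_stress = log(1.5),   # log-odds shift on fn when stressed
    beta_fp_stress = log(1.25),  # log-odds shift on fp when stressed
    beta_attrition_stress = 0.15,  # tilt towards fewer answered waves
    istress_item_rate = c(no = 0.05, yes = 0.85),  # per-wave item | latent
    p_pstress_active = 0.18,     # per-wave partner stress while IPV true
    p_pstress_inactive = 0.02,
    traj_probs_ever = c(NEVER_SEP_DIV = 0.45, REMAINED_SEP_DIV = 0.18,
                        BECAME_PARTNERED = 0.13, BECAME_SEP_DIV = 0.24),
    traj_probs_never = c(NEVER_SEP_DIV = 0.80, REMAINED_SEP_DIV = 0.05,
                         BECAME_PARTNERED = 0.035, BECAME_SEP_DIV = 0.115),
    baseline_partnered_probs = c(married = 0.88, defacto = 0.07,
                                 widowed = 0.02, single = 0.03)
  )
}

#' Simulation parameters
#'
#' Parameters of the synthetic-cohort generator. Defaults are the
#' "paper-like" study conditions: roughly a quarter of women ever
#' experiencing IPV with most onsets before the first survey, small
#' false-positive and moderate false-negative reporting rates calibrated so
#' the exact class distribution approximates the published one, and answered
#' -wave margins matching the published 3/4/5/6-survey proportions (the
#' remaining mass gives ineligible patterns).
#'
#' @param n cohort size.
#' @param prev_ever probability of ever experiencing IPV by the final wave.
#' @param onset_probs length-7 distribution over onset wave 0..6 given ever
#'   (0 = before wave 1); must sum to 1.
#' @param fp per-wave false-positive probability (YES with no IPV history).
#' @param fn per-wave false-negative probability (NO despite IPV history up
#'   to that wave).
#' @param answer_margins named proportions of the full cohort answering
#'   exactly three/four/five/six waves (sum <= 1; the remainder becomes
#'   ineligible patterns).
#' @param monotone_mix probability the answered pattern is the monotone
#'   prefix (dropout) rather than uniform intermittent skipping.
#' @param ineligible_split distribution of ineligible pattern shapes:
#'   wave-1-only, wave 1 plus one later wave, wave 1 missing.
#' @param covariate_params see [default_covariate_params()].
#' @param seed default RNG seed for [simulate_cohort()].
#' @return validated list of class `ipv_sim_params`.
#' @export
sim_params <- function(n = 10000,
                       prev_ever = 0.165,
                       onset_probs = c(0.887, 0, 0.0226, 0.0226, 0.0226,
                                       0.0226, 0.0226),
                       fp = 0.016,
                       fn = 0.13,
                       answer_margins = c(three = 0.0681, four = 0.0857,
                                          five = 0.1258, six = 0.5216),
                       monotone_mix = 0.7,
                       ineligible_split = c(wave1_only = 0.69,
                                            wave1_plus_one = 0.21,
                                            wave1_missing = 0.10),
                       covariate_params = default_covariate_params(),
                       seed = 20191029) {
  onset_probs <- onset_probs / sum(onset_probs)
  p <- list(n = as.integer(n), prev_ever = prev_ever,
            onset_probs = onset_probs, fp = fp, fn = fn,
            answer_margins = answer_margins, monotone_mix = monotone_mix,
            ineligible_split = ineligible_split / sum(ineligible_split),
            covariate_params = covariate_params, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "ipv_sim_params")
}

validate_sim_params <- function(p) {
  in01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (p$n < 1) stop("n must be positive", call. = FALSE)
  if (!in01(c(p$prev_ever, p$fp, p$fn, p$monotone_mix)))
    stop("prev_ever, fp, fn, monotone_mix must lie in [0, 1]", call. = FALSE)
  if (length(p$onset_probs) != 7 || !in01(p$onset_probs) ||
      abs(sum(p$onset_probs) - 1) > 1e-8)
    stop("onset_probs must be 7 probabilities summing to 1", call. = FALSE)
  if (!setequal(names(p$answer_margins), c("three", "four", "five", "six")))
    stop("answer_margins must be named three/four/five/six", call. = FALSE)
  if (!in01(p$answer_margins) || sum(p$answer_margins) > 1 + 1e-8)
    stop("answer_margins must be probabilities summing to at most 1",
         call. = FALSE)
  cp <- p$covariate_params
  if (abs(sum(cp$area_probs) - 1) > 1e-6 ||
      abs(sum(cp$qual_probs) - 1) > 1e-6)
    stop("area_probs and qual_probs must each sum to 1", call. = FALSE)
  invisible(p)
}

#' @export
print.ipv_sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  n = %d, prev_ever = %.3f, fp = %.4f, fn = %.4f\n",
              x$n, x$prev_ever, x$fp, x$fn))
  cat("  onset probs (0..6):", paste(signif(x$onset_probs, 3),
                                     collapse = " "), "\n")
  cat("  answer margins:", paste(names(x$answer_margins),
                                 signif(x$answer_margins, 3),
                                 collapse = ", "), "\n")
  cat(sprintf("  monotone_mix = %.2f, seed = %d\n", x$monotone_mix, x$seed))
  invisible(x)
}

# Shift a probability on the log-odds scale, keeping 0 and 1 fixed points.
shift_logit <- function(p, beta) {
  out <- stats::plogis(stats::qlogis(p) + beta)
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

# Answered-count margins for stress level s: stressed women are tilted
# towards fewer answered waves; the total eligible mass is preserved.
margins_for <- function(params, s) {
  m <- params$answer_margins[c("three", "four", "five", "six")]
  if (s == 0 || params$covariate_params$beta_attrition_stress == 0) return(m)
  tilt <- exp(-params$covariate_params$beta_attrition_stress * (3:6 - 3))
  w <- m * tilt
  w * sum(m) / sum(w)
}

# P(a pattern with k answers is a given wave-set): monotone prefix gets the
# mixture mass plus its share of the uniform component.
pattern_shape_prob <- function(params, k, is_prefix) {
  unif <- (1 - params$monotone_mix) / choose(5, k - 1)
  if (is_prefix) params$monotone_mix + unif else unif
}

#' Exact consistency-class distribution (enumeration oracle)
#'
#' Computes the probability of each consistency class among eligible records
#' implied by simulation parameters, exactly, by summing over latent onset,
#' stress propensity, answered-wave patterns and response strings. Runs in
#' well under a second; the simulator's empirical class frequencies converge
#' to this distribution.
#'
#' @param params an `ipv_sim_params`.
#' @return named probability vector over the six classes, summing to 1.
#' @export
exact_class_distribution <- function(params) {
  stopifnot(inherits(params, "ipv_sim_params"))
  pt <- pattern_table()
  cp <- params$covariate_params
  onset <- c(Inf, 0:6)
  p_state <- c(1 - params$prev_ever, params$prev_ever * params$onset_probs)
  acc <- stats::setNames(numeric(6), ipv_classes())
  for (s in 0:1) {
    fn_s <- shift_logit(params$fn, cp$beta_fn_stress * s)
    fp_s <- shift_logit(params$fp, cp$beta_fp_stress * s)
    marg <- margins_for(params, s)
    for (st in seq_along(onset)) {
      if (p_state[st] == 0) next
      ever <- is.finite(onset[st])
      p_s <- if (ever) cp$p_stress_ever else cp$p_stress_never
      p_joint <- p_state[st] * (if (s == 1) p_s else 1 - p_s)
      if (p_joint == 0) next
      truth <- ever & (onset[st] <= seq_len(N_WAVES))
      p_yes <- ifelse(truth, 1 - fn_s, fp_s)
      for (pat in pt) {
        p_pat <- marg[[pat$k - 2]] *
          pattern_shape_prob(params, pat$k, pat$prefix)
        if (p_pat == 0) next
        py <- p_yes[pat$waves]
        sp <- rep(p_joint * p_pat, nrow(pat$yes))
        for (j in seq_len(pat$k)) {
          sp <- sp * ifelse(pat$yes[, j], py[j], 1 - py[j])
        }
        for (c in unique(pat$cls)) {
          acc[c] <- acc[c] + sum(sp[pat$cls == c])
        }
      }
    }
  }
  acc / sum(acc)
}

#' Simulate a six-wave cohort
#'
#' Draws a cohort from the generative model described in [sim_params()].
#' Reproducible: the same seed yields a bit-identical cohort.
#'
#' @param params an `ipv_sim_params`.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return an `ipv_cohort` with an attached `truth` attribute (data frame of
#'   the latent ever/onset/stress values, for validation only).
#' @export
simulate_cohort <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "ipv_sim_params"))
  set.seed(seed)
  n <- params$n
  cp <- params$covariate_params

  ever <- stats::runif(n) < params$prev_ever
  onset <- rep(Inf, n)
  if (any(ever)) {
    onset[ever] <- sample(0:6, sum(ever), replace = TRUE,
                          prob = params$onset_probs)
  }
  s <- stats::runif(n) < ifelse(ever, cp$p_stress_ever, cp$p_stress_never)
  fn_i <- shift_logit(params$fn, cp$beta_fn_stress * as.numeric(s))
  fp_i <- shift_logit(params$fp, cp$beta_fp_stress * as.numeric(s))

  # answered-wave count: 3..6 eligible, 0 = ineligible pattern
  cnt <- integer(n)
  for (sv in 0:1) {
    idx <- which(s == (sv == 1))
    if (!length(idx)) next
    marg <- margins_for(params, sv)
    cnt[idx] <- sample(c(3:6, 0L), length(idx), replace = TRUE,
                       prob = c(marg, 1 - sum(marg)))
  }

  # answered-wave pattern
  ans <- matrix(FALSE, n, N_WAVES)
  for (k in 3:6) {
    idx <- which(cnt == k)
    if (!length(idx)) next
    mono <- stats::runif(length(idx)) < params$monotone_mix
    ans[idx[mono], seq_len(k)] <- TRUE
    rest <- idx[!mono]
    if (length(rest)) {
      sets <- utils::combn(2:6, k - 1)
      pick <- sample.int(ncol(sets), length(rest), replace = TRUE)
      ans[rest, 1] <- TRUE
      ans[cbind(rep(rest, each = k - 1), as.vector(sets[, pick]))] <- TRUE
    }
  }
  inel <- which(cnt == 0)
  if (length(inel)) {
    shape <- sample(names(params$ineligible_split), length(inel),
                    replace = TRUE, prob = params$ineligible_split)
    ans[inel[shape == "wave1_only"], 1] <- TRUE
    w1p <- inel[shape == "wave1_plus_one"]
    if (length(w1p)) {
      ans[w1p, 1] <- TRUE
      ans[cbind(w1p, sample(2:6, length(w1p), replace = TRUE))] <- TRUE
    }
    w1m <- inel[shape == "wave1_missing"]
    if (length(w1m)) {
      # uniform nonempty subset of waves 2..6
      code <- sample.int(31, length(w1m), replace = TRUE)
      for (b in 1:5) {
        hit <- bitwAnd(code, bitwShiftL(1L, b - 1L)) > 0
        ans[w1m[hit], b + 1L] <- TRUE
      }
    }
  }

  truth <- outer(onset, seq_len(N_WAVES), "<=")
  p_yes <- ifelse(truth, rep(1 - fn_i, N_WAVES), rep(fp_i, N_WAVES))
  resp <- matrix(stats::runif(n * N_WAVES), n) < p_yes
  ipv <- matrix(NA_character_, n, N_WAVES)
  ipv[ans] <- ifelse(resp[ans], "Y", "N")

  area <- sample(names(cp$area_probs), n, replace = TRUE,
                 prob = cp$area_probs)
  qual <- sample(names(cp$qual_probs), n, replace = TRUE,
                 prob = cp$qual_probs)

  # relationship histories consistent with a drawn trajectory type
  traj <- character(n)
  if (any(ever)) traj[ever] <- sample(names(cp$traj_probs_ever), sum(ever),
                                      replace = TRUE, cp$traj_probs_ever)
  if (any(!ever)) traj[!ever] <- sample(names(cp$traj_probs_never),
                                        sum(!ever), replace = TRUE,
                                        cp$traj_probs_never)
  rel <- matrix(NA_character_, n, N_WAVES)
  base_status <- sample(names(cp$baseline_partnered_probs), n,
                        replace = TRUE, cp$baseline_partnered_probs)
  sepdiv <- sample(c("separated", "divorced"), n, replace = TRUE)
  change_wave <- sample(2:6, n, replace = TRUE)
  for (w in seq_len(N_WAVES)) {
    rel[, w] <- base_status
    i <- traj == "REMAINED_SEP_DIV"
    rel[i, w] <- sepdiv[i]
    i <- traj == "BECAME_SEP_DIV" & change_wave <= w
    rel[i, w] <- sepdiv[i]
    i <- traj == "BECAME_SEP_DIV" & change_wave > w
    rel[i, w] <- "married"
    i <- traj == "BECAME_PARTNERED" & change_wave > w
    rel[i, w] <- sepdiv[i]
    i <- traj == "BECAME_PARTNERED" & change_wave <= w
    rel[i, w] <- "married"
  }
  rel[!ans] <- NA

  pstress <- matrix(stats::runif(n * N_WAVES), n) <
    ifelse(truth, cp$p_pstress_active, cp$p_pstress_inactive)
  istress <- matrix(stats::runif(n * N_WAVES), n) <
    ifelse(matrix(s, n, N_WAVES), cp$istress_item_rate[["yes"]],
           cp$istress_item_rate[["no"]])
  pstress[!ans] <- NA
  istress[!ans] <- NA

  df <- data.frame(id = sprintf("W%06d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (w in seq_len(N_WAVES)) df[[paste0("ipv_w", w)]] <- ipv[, w]
  for (w in seq_len(N_WAVES)) df[[paste0("rel_w", w)]] <- rel[, w]
  for (w in seq_len(N_WAVES)) df[[paste0("pstress_w", w)]] <- pstress[, w]
  for (w in seq_len(N_WAVES)) df[[paste0("istress_w", w)]] <- istress[, w]
  df$area <- area
  df$qual <- qual
  cohort <- as_cohort(df, provenance = sprintf(
    "simulate_cohort(n=%d, prev_ever=%.3f, fp=%.4f, fn=%.4f, seed=%d)",
    n, params$prev_ever, params$fp, params$fn, seed))
  attr(cohort, "truth") <- data.frame(id = df$id, ever = ever, onset = onset,
                                      stress_latent = s)
  cohort
}

#' Cross-sectional misreporting bias at one wave
#'
#' Difference between the apparent lifetime IPV prevalence a single-wave
#' (cross-sectional) survey would measure among that wave's responders and
#' the true lifetime-to-date prevalence among the same responders, computed
#' exactly from the parameters. Negative values mean net under-reporting.
#' With `fp = fn = 0` the bias is exactly zero at every wave.
#'
#' @param params an `ipv_sim_params`.
#' @param wave wave index 1..6.
#' @return a single number (difference of proportions).
#' @export
cross_sectional_bias <- function(params, wave) {
  stopifnot(inherits(params, "ipv_sim_params"),
            length(wave) == 1, wave %in% seq_len(N_WAVES))
  cp <- params$covariate_params
  onset <- c(Inf, 0:6)
  p_state <- c(1 - params$prev_ever, params$prev_ever * params$onset_probs)
  p_inelig <- 1 - sum(params$answer_margins)
  isplit <- params$ineligible_split

  # P(answered at `wave` | stress level s)
  p_ans_wave <- function(s) {
    marg <- margins_for(params, s)
    p <- 0
    for (k in 3:6) {
      shape <- if (wave == 1) 1
        else params$monotone_mix * (wave <= k) +
             (1 - params$monotone_mix) * (k - 1) / 5
      p <- p + marg[[k - 2]] * shape
    }
    p_in <- if (wave == 1) {
      isplit[["wave1_only"]] + isplit[["wave1_plus_one"]]
    } else {
      isplit[["wave1_plus_one"]] / 5 + isplit[["wave1_missing"]] * 16 / 31
    }
    p + p_inelig * p_in
  }

  num_yes <- num_truth <- denom <- 0
  for (s in 0:1) {
    fn_s <- shift_logit(params$fn, cp$beta_fn_stress * s)
    fp_s <- shift_logit(params$fp, cp$beta_fp_stress * s)
    pa <- p_ans_wave(s)
    for (st in seq_along(onset)) {
      ever <- is.finite(onset[st])
      p_s <- if (ever) cp$p_stress_ever else cp$p_stress_never
      pj <- p_state[st] * (if (s == 1) p_s else 1 - p_s) * pa
      if (pj == 0) next
      truth_w <- ever && onset[st] <= wave
      p_yes <- if (truth_w) 1 - fn_s else fp_s
      num_yes <- num_yes + pj * p_yes
      num_truth <- num_truth + pj * truth_w
      denom <- denom + pj
    }
  }
  as.numeric(num_yes / denom - num_truth / denom)
}

#' Calibrate misreporting and prevalence parameters to a class distribution
#'
#' Grid search over the false-positive rate, false-negative rate, lifetime
#' prevalence and the pre-study onset mass (onset distribution
#' `c(p0, 0, rep((1 - p0)/5, 5))`), minimising the squared distance between
#' the exact class distribution (in percent) and target percentages. The
#' attrition and covariate parameters are held fixed. A second, refined pass
#' runs around the best coarse cell. Infeasible targets simply return the
#' best achievable distance; no error is raised.
#'
#' @param target named numeric vector of target percentages for the six
#'   classes (names = `ipv_classes()`), summing to ~100.
#' @param fixed an `ipv_sim_params` supplying everything not searched over.
#' @param fp_grid,fn_grid,prev_grid,onset0_grid numeric search grids.
#' @param refine run a refinement pass around the best cell (default TRUE).
#' @return list of class `ipv_calibration`: `params` (calibrated
#'   `ipv_sim_params`), `distance` (achieved sum of squared percent errors),
#'   `achieved` (exact class percentages at the optimum), `target`.
#' @export
calibrate_error_rates <- function(target,
                                  fixed = sim_params(),
                                  fp_grid = seq(0, 0.03, length.out = 7),
                                  fn_grid = seq(0, 0.24, length.out = 7),
                                  prev_grid = seq(0.16, 0.32,
                                                  length.out = 5),
                                  onset0_grid = seq(0.3, 0.8,
                                                    length.out = 6),
                                  refine = TRUE) {
  stopifnot(all(ipv_classes() %in% names(target)))
  if (!length(fp_grid) || !length(fn_grid) || !length(prev_grid) ||
      !length(onset0_grid)) {
    stop("empty calibration grid", call. = FALSE)
  }
  target <- target[ipv_classes()]
  target <- 100 * target / sum(target)

  eval_point <- function(fp, fn, prev, p0) {
    p <- fixed
    p$fp <- fp; p$fn <- fn; p$prev_ever <- prev
    p$onset_probs <- c(p0, 0, rep((1 - p0) / 5, 5))
    d <- 100 * exact_class_distribution(p)
    list(params = p, dist = sum((d - target)^2), achieved = d)
  }
  search <- function(fps, fns, prevs, p0s) {
    best <- NULL
    for (fp in fps) for (fn in fns) for (pv in prevs) for (p0 in p0s) {
      r <- eval_point(fp, fn, pv, p0)
      if (is.null(best) || r$dist < best$dist) best <- r
    }
    best
  }
  best <- search(fp_grid, fn_grid, prev_grid, onset0_grid)
  if (refine) {
    local_grid <- function(x, grid, lo = 0, hi = 1) {
      step <- if (length(grid) > 1) min(diff(sort(unique(grid)))) else 0.01
      unique(pmin(hi, pmax(lo, x + step * seq(-1, 1, length.out = 5))))
    }
    b <- best$params
    best2 <- search(local_grid(b$fp, fp_grid), local_grid(b$fn, fn_grid),
                    local_grid(b$prev_ever, prev_grid),
                    local_grid(b$onset_probs[1], onset0_grid))
    if (best2$dist < best$dist) best <- best2
  }
  structure(list(params = best$params, distance = best$dist,
                 achieved = best$achieved, target = target),
            class = "ipv_calibration")
}

#' @export
print.ipv_calibration <- function(x, ...) {
  cat("Calibration of misreporting parameters\n")
  cat(sprintf("  fp = %.4f, fn = %.4f, prev_ever = %.3f, onset0 = %.3f\n",
              x$params$fp, x$params$fn, x$params$prev_ever,
              x$params$onset_probs[1]))
  cat("  achieved class %:", paste(sprintf("%.1f", x$achieved),
                                   collapse = " "), "\n")
  cat("  target class %:  ", paste(sprintf("%.1f", x$target),
                                   collapse = " "), "\n")
  cat(sprintf("  sum squared error: %.3f\n", x$distance))
  invisible(x)
}

#' Load a simulation preset
#'
#' Reads a YAML preset (shipped: `"paper_like"`, calibrated so the exact
#' class distribution approximates the published class percentages, and
#' `"null_model"`, identical but with `fp = fn = 0`) or a YAML file path.
#'
#' @param preset preset name or YAML file path.
#' @param n,seed optional overrides.
#' @return an `ipv_sim_params`.
#' @export
load_preset <- function(preset, n = NULL, seed = NULL) {
  path <- if (file.exists(preset)) preset else {
    system.file("extdata", "presets", paste0(preset, ".yaml"),
                package = "ipvconsist")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown preset: ", preset, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  cp <- default_covariate_params()
  for (f in intersect(names(y$covariate_params), names(cp))) {
    v <- unlist(y$covariate_params[[f]])
    if (!is.null(names(cp[[f]]))) names(v) <- names(cp[[f]])
    cp[[f]] <- v
  }
  sim_params(
    n = n %||% y$n %||% 10000,
    prev_ever = y$prev_ever,
    onset_probs = unlist(y$onset_probs),
    fp = y$fp, fn = y$fn,
    answer_margins = stats::setNames(unlist(y$answer_margins),
                                     names(y$answer_margins)),
    monotone_mix = y$monotone_mix,
    ineligible_split = stats::setNames(unlist(y$ineligible_split),
                                       names(y$ineligible_split)),
    covariate_params = cp,
    seed = seed %||% y$seed %||% 20191029
  )
}
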