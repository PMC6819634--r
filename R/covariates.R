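# Longitudinal covariates: relationship trajectory, sustained stress
# indicators, survey-count category, and design weights for the two-fold
# rural/remote oversampling. All derivations look only at answered waves.

#' Relationship trajectory over waves
#'
#' Classifies a per-wave relationship-status history by whether the woman was
#' separated or divorced at her first answered wave (`b`), at her last
#' answered wave (`e`), and ever:
#' `NEVER_SEP_DIV` (never separated/divorced), `REMAINED_SEP_DIV` (`b` and
#' `e`), `BECAME_PARTNERED` (`b` but not `e`), `BECAME_SEP_DIV` (not `b` but
#' ever). Widowed and single count as "not separated/divorced". All-missing
#' histories return `NA`.
#'
#' @param statuses character matrix (n x 6) or length-6 vector with entries
#'   in `c("married","defacto","separated","divorced","widowed","single")`
#'   or NA.
#' @return factor with levels
#'   `c("NEVER_SEP_DIV","REMAINED_SEP_DIV","BECAME_PARTNERED","BECAME_SEP_DIV")`.
#' @export
derive_trajectory <- function(statuses) {
  m <- if (is.matrix(statuses)) statuses else matrix(statuses, nrow = 1)
  stopifnot(ncol(m) == N_WAVES)
  bad <- !is.na(m) & !(m %in% REL_LEVELS)
  if (any(bad)) {
    stop("invalid relationship status: ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  ans <- !is.na(m)
  sep <- ans & (m == "separated" | m == "divorced")
  any_ans <- rowSums(ans) > 0
  first_i <- max.col(ans, ties.method = "first")
  last_i  <- N_WAVES + 1L - max.col(ans[, N_WAVES:1, drop = FALSE],
                                    ties.method = "first")
  b <- sep[cbind(seq_len(nrow(m)), first_i)]
  e <- sep[cbind(seq_len(nrow(m)), last_i)]
  ever <- rowSums(sep) > 0
  out <- rep(NA_character_, nrow(m))
  out[any_ans & !ever] <- "NEVER_SEP_DIV"
  out[any_ans & b & e] <- "REMAINED_SEP_DIV"
  out[any_ans & b & !e] <- "BECAME_PARTNERED"
  out[any_ans & !b & ever] <- "BECAME_SEP_DIV"
  factor(out, levels = TRAJ_LEVELS)
}

#' Sustained stress indicator ("at least half of completed surveys")
#'
#' TRUE when the item was affirmed at at least half of the waves where it was
#' answered (ties count as "at least half"); NA when never answered. The
#' denominator is the number of non-missing stress answers.
#'
#' @param indicator logical matrix (n x 6) or length-6 vector.
#' @return logical vector.
#' @export
derive_stress_half <- function(indicator) {
  m <- if (is.matrix(indicator)) indicator else matrix(indicator, nrow = 1)
  stopifnot(ncol(m) == N_WAVES)
  n_ans <- rowSums(!is.na(m))
  n_true <- rowSums(m, na.rm = TRUE)
  out <- n_true / n_ans >= 0.5
  out[n_ans == 0] <- NA
  out
}

#' Design weights for rural oversampling
#'
#' Women from rural and remote areas were sampled at twice the rate of other
#' women, so descriptive percentages weight them at half. The default scheme
#' gives `major_city` weight 1 and every other area 0.5; alternative schemes
#' can be supplied as a named vector or a YAML file mapping area level to
#' weight.
#'
#' @param area character vector of area levels (NA allowed).
#' @param scheme named numeric vector of positive weights per area level, or
#'   a YAML file path with such a mapping.
#' @return numeric weight vector (NA where area is missing).
#' @export
assign_weight <- function(area, scheme = default_weight_scheme()) {
  if (is.character(scheme) && length(scheme) == 1 && file.exists(scheme)) {
    scheme <- unlist(yaml::read_yaml(scheme))
  }
  stopifnot(is.numeric(scheme), all(scheme > 0))
  missing_lv <- setdiff(unique(area[!is.na(area)]), names(scheme))
  if (length(missing_lv)) {
    stop("weight scheme lacks area level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  unname(scheme[area])
}

#' @rdname assign_weight
#' @export
default_weight_scheme <- function() {
  c(major_city = 1, inner_regional = 0.5, outer_regional = 0.5,
    remote_very_remote = 0.5)
}

n_surveys_category <- function(answered) {
  out <- rep(NA_character_, length(answered))
  out[answered == 6] <- "SIX"
  out[answered == 5] <- "FIVE"
  out[answered %in% c(3, 4)] <- "THREE_FOUR"
  factor(out, levels = NSURV_LEVELS)
}

#' Build analysis-ready covariate profiles
#'
#' One row per record of an eligible, classified cohort: consistency class,
#' baseline area and qualification, relationship trajectory, sustained
#' partner- and income-stress indicators, the wave-1 stress and relationship
#' items, the survey-count category derived from the IPV item
#' (6 -> SIX, 5 -> FIVE, 3 or 4 -> THREE_FOUR), the design weight, and a
#' completeness flag (`complete` is FALSE when any regression covariate is
#' missing; such records are dropped, and counted, by the model fit).
#'
#' @param cohort a classified eligible `ipv_cohort` (see [classify_cohort()]);
#'   unclassified cohorts are classified on the fly.
#' @param weight_scheme see [assign_weight()].
#' @return data frame of class `ipv_profiles`.
#' @export
build_profiles <- function(cohort, weight_scheme = default_weight_scheme()) {
  if (is.null(cohort$consistency_class)) cohort <- classify_cohort(cohort)
  if (any(cohort$consistency_class == ipv_ineligible())) {
    stop("cohort contains ineligible records; run filter_eligible() first",
         call. = FALSE)
  }
  df <- as.data.frame(cohort)
  relm <- as.matrix(df[, wave_cols("rel")])
  psm <- as.matrix(df[, wave_cols("pstress")])
  ism <- as.matrix(df[, wave_cols("istress")])
  storage.mode(psm) <- "logical"
  storage.mode(ism) <- "logical"
  answered <- answered_count(ipv_matrix(cohort))
  out <- data.frame(
    id = df$id,
    consistency_class = factor(df$consistency_class, levels = ipv_classes()),
    area = factor(df$area, levels = AREA_LEVELS),
    qual = factor(df$qual, levels = QUAL_LEVELS),
    rel_baseline = factor(relm[, 1], levels = REL_LEVELS),
    trajectory = derive_trajectory(relm),
    pstress_w1 = psm[, 1],
    istress_w1 = ism[, 1],
    pstress_half = derive_stress_half(psm),
    istress_half = derive_stress_half(ism),
    answered_count = answered,
    n_surveys_cat = n_surveys_category(answered),
    weight = assign_weight(df$area, weight_scheme),
    stringsAsFactors = FALSE
  )
  model_vars <- c("area", "qual", "trajectory", "pstress_half",
                  "istress_half", "n_surveys_cat")
  out$complete <- stats::complete.cases(out[, model_vars])
  structure(out, class = c("ipv_profiles", "data.frame"))
}
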