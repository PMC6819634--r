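# Descriptive outputs: class summary with derived aggregates, class-by-
# survey-count cross-tabulation, and the weighted characteristics table.
# All printed percentages are rounded half-up (round_half_up), the
# convention of the published tables.

#' Summarise consistency classes
#'
#' Counts and one-decimal percentages per class, plus the derived aggregates
#' reported alongside: the consistent and inconsistent totals, the share who
#' ever reported IPV (everyone but the consistent-never group), the share who
#' consistently reported IPV whenever they answered (consistent IPV +
#' consistent later IPV), and the integer percentage split within the
#' inconsistent group.
#'
#' @param x a classified `ipv_cohort`, or a factor/character vector of
#'   consistency classes (no `INELIGIBLE` entries).
#' @return object of class `ipv_class_summary`: list with `counts`, `total`,
#'   `percents`, `consistent_pct`, `inconsistent_pct`, `ever_reported_pct`,
#'   `consistent_ipv_any_pct`, `within_inconsistent_pct`.
#' @export
summarize_classes <- function(x) {
  cls <- if (inherits(x, "ipv_cohort")) x$consistency_class else x
  if (is.null(cls)) stop("cohort is not classified", call. = FALSE)
  cls <- as.character(cls)
  if (!length(cls)) stop("empty cohort", call. = FALSE)
  if (any(cls == ipv_ineligible())) {
    stop("INELIGIBLE records present; run filter_eligible() first",
         call. = FALSE)
  }
  if (any(!cls %in% ipv_classes())) {
    stop("unknown class label(s)", call. = FALSE)
  }
  counts <- table(factor(cls, levels = ipv_classes()))
  counts <- stats::setNames(as.integer(counts), ipv_classes())
  total <- sum(counts)
  pct <- round_half_up(100 * counts / total, 1)
  consistent <- c("CONSISTENT_IPV", "CONSISTENT_LATER_IPV",
                  "CONSISTENT_NEVER_IPV")
  inconsistent <- c("MAINLY_IPV", "MAINLY_NO_IPV", "MIXED_IPV")
  n_inc <- sum(counts[inconsistent])
  within <- if (n_inc > 0) {
    round_half_up(100 * counts[inconsistent] / n_inc, 0)
  } else {
    stats::setNames(rep(NA_real_, 3), inconsistent)
  }
  structure(list(
    counts = counts,
    total = total,
    percents = pct,
    consistent_pct = round_half_up(100 * sum(counts[consistent]) / total, 1),
    inconsistent_pct = round_half_up(100 * n_inc / total, 1),
    ever_reported_pct = round_half_up(
      100 * (total - counts[["CONSISTENT_NEVER_IPV"]]) / total, 1),
    consistent_ipv_any_pct = round_half_up(
      100 * (counts[["CONSISTENT_IPV"]] +
             counts[["CONSISTENT_LATER_IPV"]]) / total, 1),
    within_inconsistent_pct = within
  ), class = "ipv_class_summary")
}

#' @export
print.ipv_class_summary <- function(x, ...) {
  cat("Consistency of IPV reporting (N =", format(x$total, big.mark = ","),
      ")\n")
  df <- data.frame(class = names(x$counts), n = x$counts,
                   pct = x$percents, row.names = NULL)
  print(df)
  cat(sprintf("Consistent %s%%, inconsistent %s%%, ever reported %s%%, ",
              x$consistent_pct, x$inconsistent_pct, x$ever_reported_pct))
  cat(sprintf("consistently reported IPV %s%%\n", x$consistent_ipv_any_pct))
  cat("Within inconsistent:",
      paste(sprintf("%s %s%%", names(x$within_inconsistent_pct),
                    x$within_inconsistent_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Class by number-of-answers cross-tabulation
#'
#' Column percentages of the number of times the IPV question was answered
#' (3, 4, 5, 6) within each consistency class and over all women
#' (unweighted). The MIXED column is structurally 0 in the 3-answers row:
#' a mixed sequence needs at least two YES and two NO answers.
#'
#' @param cohort a classified eligible `ipv_cohort`.
#' @return object of class `ipv_crosstab`: list with `percent` (4 x 7 matrix
#'   of one-decimal column percentages), `counts`, and `col_n`.
#' @export
tabulate_by_nsurveys <- function(cohort) {
  if (is.null(cohort$consistency_class)) cohort <- classify_cohort(cohort)
  cls <- factor(as.character(cohort$consistency_class),
                levels = ipv_classes())
  if (anyNA(cls)) {
    stop("INELIGIBLE records present; run filter_eligible() first",
         call. = FALSE)
  }
  nans <- factor(answered_count(ipv_matrix(cohort)), levels = 3:6)
  counts <- table(nans, cls)
  counts <- cbind(counts, all_women = rowSums(counts))
  col_n <- colSums(counts)
  pct <- counts
  for (j in seq_len(ncol(counts))) {
    pct[, j] <- if (col_n[j] > 0) {
      round_half_up(100 * counts[, j] / col_n[j], 1)
    } else NA_real_
  }
  structure(list(percent = pct, counts = counts, col_n = col_n),
            class = "ipv_crosstab")
}

#' @export
print.ipv_crosstab <- function(x, ...) {
  cat("Column percentages by number of times the IPV question was answered\n")
  print(x$percent)
  cat("Column N:\n")
  print(x$col_n)
  invisible(x)
}

# Weighted column percentage of each level of `values` within each class.
weighted_col_pct <- function(values, cls, w, levels) {
  out <- matrix(NA_real_, length(levels), nlevels(cls),
                dimnames = list(levels, levels(cls)))
  for (j in levels(cls)) {
    in_col <- cls == j & !is.na(values) & !is.na(w)
    tw <- sum(w[in_col])
    if (tw <= 0) next
    for (lv in levels) {
      out[lv, j] <- round_half_up(
        100 * sum(w[in_col & values == lv]) / tw, 1)
    }
  }
  out
}

#' Characteristics of women by consistency class
#'
#' Weighted column percentages (design weights correcting the rural/remote
#' oversampling) of baseline and longitudinal characteristics within each
#' consistency class: area of residence, highest qualification, baseline
#' relationship status (collapsed to married/de facto, divorced/separated,
#' widowed/single), relationship trajectory, partner stress (at wave 1 and
#' sustained) and income stress (at wave 1 and sustained). With equal weights
#' the table equals the unweighted one; percentages are invariant to global
#' rescaling of the weights.
#'
#' @param profiles an `ipv_profiles` table (see [build_profiles()]).
#' @param weighted use the design weights (default TRUE); FALSE gives
#'   unweighted percentages.
#' @return data frame with columns `variable`, `level`, then one column of
#'   percentages per consistency class.
#' @export
characteristics_table <- function(profiles, weighted = TRUE) {
  cls <- factor(as.character(profiles$consistency_class),
                levels = ipv_classes())
  w <- if (weighted) profiles$weight else rep(1, nrow(profiles))
  col_w <- vapply(levels(cls),
                  function(j) sum(w[cls == j], na.rm = TRUE), 0)
  if (any(col_w <= 0)) {
    warning("zero total weight in column(s) ",
            paste(names(col_w)[col_w <= 0], collapse = ", "),
            "; emitted empty", call. = FALSE)
  }
  rel3 <- as.character(profiles$rel_baseline)
  rel3[rel3 %in% c("married", "defacto")] <- "married_defacto"
  rel3[rel3 %in% c("divorced", "separated")] <- "divorced_separated"
  rel3[rel3 %in% c("widowed", "single")] <- "widowed_single"
  blocks <- list(
    area = list(v = profiles$area, lv = AREA_LEVELS),
    qual = list(v = profiles$qual, lv = QUAL_LEVELS),
    rel_baseline = list(v = rel3, lv = c("married_defacto",
                                         "divorced_separated",
                                         "widowed_single")),
    trajectory = list(v = profiles$trajectory, lv = TRAJ_LEVELS),
    pstress_w1 = list(v = profiles$pstress_w1, lv = c(TRUE, FALSE)),
    pstress_half = list(v = profiles$pstress_half, lv = c(TRUE, FALSE)),
    istress_w1 = list(v = profiles$istress_w1, lv = c(TRUE, FALSE)),
    istress_half = list(v = profiles$istress_half, lv = c(TRUE, FALSE))
  )
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    pct <- weighted_col_pct(as.character(b$v), cls, w, as.character(b$lv))
    data.frame(variable = nm, level = rownames(pct), pct,
               row.names = NULL, check.names = FALSE)
  })
  do.call(rbind, rows)
}
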