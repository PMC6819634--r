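# Baseline-category multinomial logistic regression of consistency class on
# covariates, with the consistently-IPV group as the reference outcome.
# The likelihood is maximised by nnet::multinom; this file owns the
# reference-level handling, complete-case accounting, Wald odds-ratio table,
# convergence/separation diagnostics and the S3 interface.

#' Fit the consistency-class regression
#'
#' Baseline-category (multinomial) logistic regression of consistency class
#' on categorical covariates. Each non-reference class is contrasted against
#' the reference outcome (default `CONSISTENT_IPV`); odds ratios are
#' exponentiated coefficients with Wald 95% confidence intervals
#' (z = 1.959964). Records with a missing model covariate are dropped and
#' counted (complete-case analysis), never silently.
#'
#' @param formula model formula; the left-hand side must be the consistency
#'   class. Default: class on area, qualification, relationship trajectory,
#'   sustained partner and income stress, and survey-count category.
#' @param data an `ipv_profiles` table (or any data frame with the model
#'   variables).
#' @param reference reference outcome class (default `"CONSISTENT_IPV"`).
#' @param weights optional non-negative case weights (descriptive design
#'   weights are *not* applied by default; the published fit is unweighted).
#' @param maxit,reltol optimiser control (BFGS via `nnet`); defaults 200
#'   iterations and relative tolerance 1e-10.
#' @return object of class `ipv_class_fit` with components `fit` (the
#'   underlying `multinom` object), `or_table` (data frame: `outcome_class`,
#'   `covariate`, `level`, `estimate` = log odds, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `significant` at the 0.05 level — annotation only),
#'   `n_used`, `n_dropped`, `converged`, `separation_suspect`,
#'   `reference`, `formula`.
#' @seealso [sensitivity_complete_responders()], [or_table()]
#' @export
fit_consistency_model <- function(formula = consistency_class ~ area + qual +
                                    trajectory + pstress_half +
                                    istress_half + n_surveys_cat,
                                  data,
                                  reference = "CONSISTENT_IPV",
                                  weights = NULL,
                                  maxit = 200, reltol = 1e-10) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("model variables not in data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data), all(weights >= 0, na.rm = TRUE))
  keep <- stats::complete.cases(data[, vars, drop = FALSE]) & !is.na(weights)
  dat <- data[keep, , drop = FALSE]
  dat$.wts <- weights[keep]
  n_dropped <- sum(!keep)

  yname <- all.vars(formula[[2]])
  y <- droplevels(factor(dat[[yname]]))
  if (!reference %in% levels(y)) {
    stop("reference outcome '", reference, "' absent from the data",
         call. = FALSE)
  }
  if (nlevels(y) < 2) {
    stop("need at least 2 outcome classes, got ", nlevels(y), call. = FALSE)
  }
  dat[[yname]] <- stats::relevel(y, ref = reference)
  # drop empty factor levels in covariates but report them
  dropped_levels <- list()
  for (v in setdiff(vars, yname)) {
    if (is.factor(dat[[v]])) {
      empty <- setdiff(levels(dat[[v]]), unique(as.character(dat[[v]])))
      if (length(empty)) dropped_levels[[v]] <- empty
      dat[[v]] <- droplevels(dat[[v]])
    } else if (is.logical(dat[[v]])) {
      dat[[v]] <- factor(dat[[v]], levels = c(FALSE, TRUE))
    }
  }
  if (length(dropped_levels)) {
    warning("covariate level(s) with zero cells dropped: ",
            paste(names(dropped_levels), vapply(dropped_levels, paste,
                  "", collapse = "/"), sep = "=", collapse = "; "),
            call. = FALSE)
  }

  fit <- tryCatch(
    nnet::multinom(formula, data = dat, weights = .wts, trace = FALSE,
                   maxit = maxit, reltol = reltol, abstol = 1e-12,
                   Hess = TRUE),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- structure(list(fit = NULL, or_table = NULL,
                          n_used = nrow(dat), n_dropped = n_dropped,
                          converged = FALSE, separation_suspect = NA,
                          failure = conditionMessage(fit),
                          reference = reference, formula = formula,
                          dropped_levels = dropped_levels),
                     class = "ipv_class_fit")
    warning("multinomial fit failed: ", conditionMessage(fit),
            call. = FALSE)
    return(out)
  }
  converged <- isTRUE(fit$convergence == 0)
  if (!converged) {
    warning("multinomial fit did not converge within ", maxit,
            " iterations", call. = FALSE)
  }
  tab <- build_or_table(fit, formula, dat, reference)
  separation <- any(abs(tab$estimate[tab$covariate != "(Intercept)"]) > 15,
                    na.rm = TRUE)
  if (isTRUE(separation)) {
    warning("very large coefficient magnitude; (quasi-)separation suspected",
            call. = FALSE)
  }
  structure(list(fit = fit, or_table = tab, n_used = nrow(dat),
                 n_dropped = n_dropped, converged = converged,
                 separation_suspect = separation, failure = NULL,
                 reference = reference, formula = formula,
                 dropped_levels = dropped_levels),
            class = "ipv_class_fit")
}

# Map model-matrix column names to (covariate, level) pairs and assemble the
# Wald odds-ratio table.
build_or_table <- function(fit, formula, dat, reference, z = 1.959964) {
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) {
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(setdiff(fit$lev, reference), names(cf)))
  }
  V <- stats::vcov(fit)
  se <- matrix(NA_real_, nrow(cf), ncol(cf), dimnames = dimnames(cf))
  vn <- rownames(V)
  for (i in rownames(cf)) {
    for (j in colnames(cf)) {
      key <- if (nrow(cf) == 1) j else paste(i, j, sep = ":")
      if (key %in% vn) {
        vv <- V[key, key]
        # near-singular Hessians under (quasi-)separation can produce
        # negative variance estimates; report NA rather than NaN
        se[i, j] <- if (is.finite(vv) && vv >= 0) sqrt(vv) else NA_real_
      }
    }
  }
  tt <- stats::terms(formula)
  mm <- stats::model.matrix(tt, dat)
  assign <- attr(mm, "assign")
  labels <- c("(Intercept)", attr(tt, "term.labels"))
  covariate <- labels[assign + 1][match(colnames(cf), colnames(mm))]
  level <- mapply(function(cn, cov) {
    if (cov == "(Intercept)") "" else sub(cov, "", cn, fixed = TRUE)
  }, colnames(cf), covariate)
  long <- expand.grid(term = colnames(cf), outcome_class = rownames(cf),
                      stringsAsFactors = FALSE)
  idx <- cbind(match(long$outcome_class, rownames(cf)),
               match(long$term, colnames(cf)))
  est <- cf[idx]
  ses <- se[idx]
  pz <- 2 * stats::pnorm(-abs(est / ses))
  data.frame(
    outcome_class = long$outcome_class,
    covariate = covariate[match(long$term, colnames(cf))],
    level = unname(level[match(long$term, colnames(cf))]),
    estimate = est,
    se = ses,
    or = exp(est),
    ci_low = exp(est - z * ses),
    ci_high = exp(est + z * ses),
    p = pz,
    significant = !is.na(pz) & pz < 0.05,
    stringsAsFactors = FALSE
  )
}

#' Extract the odds-ratio table
#'
#' @param object an `ipv_class_fit`.
#' @param include_intercepts keep intercept rows (default FALSE).
#' @return data frame; see [fit_consistency_model()].
#' @export
or_table <- function(object, include_intercepts = FALSE) {
  stopifnot(inherits(object, "ipv_class_fit"))
  tab <- object$or_table
  if (is.null(tab)) stop("fit failed: ", object$failure, call. = FALSE)
  if (!include_intercepts) tab <- tab[tab$covariate != "(Intercept)", ]
  rownames(tab) <- NULL
  tab
}

#' Sensitivity analysis on complete responders
#'
#' Refits the consistency-class model on the subset of women who answered the
#' IPV item at all six waves, removing the survey-count covariate (constant
#' in that subset).
#'
#' @inheritParams fit_consistency_model
#' @param data an `ipv_profiles` table (must carry `answered_count`).
#' @return an `ipv_class_fit`.
#' @export
sensitivity_complete_responders <- function(formula = consistency_class ~
                                              area + qual + trajectory +
                                              pstress_half + istress_half +
                                              n_surveys_cat,
                                            data,
                                            reference = "CONSISTENT_IPV",
                                            weights = NULL, ...) {
  if (is.null(data$answered_count)) {
    stop("data must carry an answered_count column (see build_profiles)",
         call. = FALSE)
  }
  keep <- data$answered_count == 6
  if (!any(keep)) {
    stop("no complete responders: nobody answered the IPV item at all six ",
         "waves", call. = FALSE)
  }
  if ("n_surveys_cat" %in% all.vars(formula)) {
    formula <- stats::update(formula, . ~ . - n_surveys_cat)
  }
  if (!is.null(weights)) weights <- weights[keep]
  fit_consistency_model(formula, data[keep, , drop = FALSE],
                        reference = reference, weights = weights, ...)
}

#' @export
print.ipv_class_fit <- function(x, digits = 2, ...) {
  cat("Baseline-category multinomial logit of consistency class\n")
  cat("Reference outcome:", x$reference, "\n")
  cat("Records used:", x$n_used, "(", x$n_dropped,
      "dropped for missing covariates )\n")
  if (is.null(x$fit)) {
    cat("FIT FAILED:", x$failure, "\n")
    return(invisible(x))
  }
  if (!x$converged) cat("WARNING: optimiser did not converge\n")
  if (isTRUE(x$separation_suspect)) cat("WARNING: separation suspected\n")
  tab <- or_table(x)
  tab$or <- round(tab$or, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  print(tab[, c("outcome_class", "covariate", "level", "or", "ci_low",
                "ci_high", "significant")])
  invisible(x)
}

#' @export
summary.ipv_class_fit <- function(object, ...) {
  structure(list(or_table = object$or_table, n_used = object$n_used,
                 n_dropped = object$n_dropped, converged = object$converged,
                 separation_suspect = object$separation_suspect,
                 reference = object$reference,
                 logLik = if (!is.null(object$fit))
                   as.numeric(stats::logLik(object$fit)) else NA_real_,
                 formula = object$formula),
            class = "summary.ipv_class_fit")
}

#' @export
print.summary.ipv_class_fit <- function(x, ...) {
  cat("Consistency-class multinomial fit\n")
  cat("Formula:", deparse(x$formula), "\n")
  cat("Reference:", x$reference, "| n used:", x$n_used, "| dropped:",
      x$n_dropped, "| logLik:", format(x$logLik), "\n")
  print(x$or_table)
  invisible(x)
}

#' @export
coef.ipv_class_fit <- function(object, ...) {
  if (is.null(object$fit)) stop("fit failed: ", object$failure)
  cf <- stats::coef(object$fit)
  if (is.null(dim(cf))) {
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(setdiff(object$fit$lev, object$reference),
                                 names(cf)))
  }
  cf
}

#' @export
logLik.ipv_class_fit <- function(object, ...) {
  if (is.null(object$fit)) stop("fit failed: ", object$failure)
  stats::logLik(object$fit)
}

#' @export
confint.ipv_class_fit <- function(object, parm, level = 0.95, ...) {
  tab <- or_table(object, include_intercepts = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab$ci_low <- exp(tab$estimate - z * tab$se)
  tab$ci_high <- exp(tab$estimate + z * tab$se)
  tab
}

#' @export
predict.ipv_class_fit <- function(object, newdata = NULL,
                                  type = c("probs", "class"), ...) {
  if (is.null(object$fit)) stop("fit failed: ", object$failure)
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- stats::fitted(object$fit)
    if (type == "probs") return(p)
    return(factor(colnames(p)[max.col(p)], levels = object$fit$lev))
  }
  stats::predict(object$fit, newdata = newdata, type = type)
}

#' Forest-style plot of odds ratios
#'
#' Dot-and-whisker display of the odds ratios and 95% confidence intervals,
#' one panel row per covariate level, points grouped by outcome class, on a
#' log scale with a reference line at OR = 1.
#'
#' @param x an `ipv_class_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ipv_class_fit <- function(x, ...) {
  tab <- or_table(x)
  tab$label <- paste(tab$outcome_class, paste(tab$covariate, tab$level),
                     sep = " : ")
  k <- nrow(tab)
  old <- graphics::par(mar = c(4, 16, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(tab$or, seq_len(k), log = "x",
                 xlim = range(c(tab$ci_low, tab$ci_high, 1), finite = TRUE),
                 yaxt = "n", xlab = "Odds ratio (log scale)", ylab = "",
                 pch = 19, ...)
  graphics::segments(tab$ci_low, seq_len(k), tab$ci_high, seq_len(k))
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = tab$label, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}
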