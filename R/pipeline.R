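# End-to-end orchestration: read or simulate -> filter -> classify ->
# profiles -> descriptive tables -> regression, with every stage output
# written as plain CSV/JSON plus a run manifest sufficient to reproduce the
# bundle exactly.

#' Run configuration
#'
#' Validated settings for [run_pipeline()]. Exactly one of `input` (wide
#' cohort CSV) or `preset` (simulation preset name/YAML, see [load_preset()])
#' must be given.
#'
#' @param input path to a wide cohort CSV, or NULL.
#' @param preset simulation preset name or YAML path, or NULL.
#' @param n cohort size when simulating (overrides the preset).
#' @param seed RNG seed for simulation.
#' @param weighted use design weights in the characteristics table.
#' @param model `"full"`, `"sensitivity"`, `"both"`, or `"none"` (descriptive
#'   outputs only — useful for small classification runs).
#' @param out_dir output directory (created if absent); NULL disables file
#'   output.
#' @return list of class `ipv_run_config`.
#' @export
run_config <- function(input = NULL, preset = NULL, n = 10000, seed = 1,
                       weighted = TRUE, model = c("both", "full",
                                                  "sensitivity", "none"),
                       out_dir = NULL) {
  model <- match.arg(model)
  if (is.null(input) == is.null(preset)) {
    stop("give exactly one of input= (CSV) or preset= (simulation)",
         call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  structure(list(input = input, preset = preset, n = as.integer(n),
                 seed = as.integer(seed), weighted = isTRUE(weighted),
                 model = model, out_dir = out_dir),
            class = "ipv_run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes read/simulate, eligibility filtering, classification, covariate
#' profiles, descriptive tables and the multinomial regression (full model
#' and/or the complete-responder sensitivity model), logging record counts
#' per stage to `message()`. When `out_dir` is set, writes:
#' `class_summary.json`, `exclusions.json`, `crosstab_nsurveys.csv`,
#' `characteristics.csv`, `profiles.csv`, `or_table_full.csv`,
#' `or_table_sensitivity.csv` and `manifest.json`. Reruns with the same
#' configuration produce byte-identical numeric outputs.
#'
#' @param config an `ipv_run_config` (see [run_config()]).
#' @return list of class `ipv_report_bundle` with components `cohort`,
#'   `exclusions`, `profiles`, `class_summary`, `crosstab`,
#'   `characteristics`, `fit_full`, `fit_sensitivity`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ipv_run_config"))
  cohort <- run_stage("ingest", {
    if (!is.null(config$input)) {
      read_cohort(config$input)
    } else {
      simulate_cohort(load_preset(config$preset, n = config$n,
                                  seed = config$seed))
    }
  })
  message("ingest: ", nrow(cohort), " records")

  flt <- run_stage("filter_eligible", filter_eligible(cohort))
  stopifnot(flt$exclusions$n_eligible + flt$exclusions$n_excluded ==
              nrow(cohort))
  message("filter_eligible: ", flt$exclusions$n_eligible, " eligible, ",
          flt$exclusions$n_excluded, " excluded")

  classified <- run_stage("classify", classify_cohort(flt$cohort))
  profiles <- run_stage("build_profiles", build_profiles(classified))
  message("build_profiles: ", sum(profiles$complete), " complete of ",
          nrow(profiles))

  class_summary <- run_stage("summarize", summarize_classes(classified))
  crosstab <- run_stage("tabulate", tabulate_by_nsurveys(classified))
  characteristics <- run_stage("characteristics",
                               characteristics_table(profiles,
                                 weighted = config$weighted))

  fit_full <- fit_sens <- NULL
  if (config$model %in% c("full", "both")) {
    fit_full <- run_stage("fit_full",
                          fit_consistency_model(data = profiles))
    message("fit_full: ", fit_full$n_used, " used, ", fit_full$n_dropped,
            " dropped")
  }
  if (config$model %in% c("sensitivity", "both")) {
    fit_sens <- run_stage("fit_sensitivity",
                          sensitivity_complete_responders(data = profiles))
    message("fit_sensitivity: ", fit_sens$n_used, " used")
  }

  manifest <- list(
    package = "ipvconsist",
    version = as.character(utils::packageVersion("ipvconsist")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config)[c("input", "preset", "n", "seed", "weighted",
                               "model")],
    n_input = nrow(cohort),
    n_eligible = flt$exclusions$n_eligible,
    n_excluded = flt$exclusions$n_excluded
  )

  bundle <- structure(list(cohort = classified,
                           exclusions = flt$exclusions,
                           profiles = profiles,
                           class_summary = class_summary,
                           crosstab = crosstab,
                           characteristics = characteristics,
                           fit_full = fit_full,
                           fit_sensitivity = fit_sens,
                           manifest = manifest),
                      class = "ipv_report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cs <- bundle$class_summary
  jsonlite::write_json(list(counts = as.list(cs$counts), total = cs$total,
                            percents = as.list(cs$percents),
                            consistent_pct = cs$consistent_pct,
                            inconsistent_pct = cs$inconsistent_pct,
                            ever_reported_pct = cs$ever_reported_pct,
                            consistent_ipv_any_pct = cs$consistent_ipv_any_pct,
                            within_inconsistent_pct =
                              as.list(cs$within_inconsistent_pct)),
                       p("class_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(bundle$exclusions), p("exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  ct <- as.data.frame(bundle$crosstab$percent)
  ct <- cbind(n_answered = rownames(bundle$crosstab$percent), ct)
  utils::write.csv(ct, p("crosstab_nsurveys.csv"), row.names = FALSE)
  utils::write.csv(bundle$characteristics, p("characteristics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$profiles), p("profiles.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(bundle$fit_full)) {
    utils::write.csv(or_table(bundle$fit_full), p("or_table_full.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$fit_sensitivity)) {
    utils::write.csv(or_table(bundle$fit_sensitivity),
                     p("or_table_sensitivity.csv"), row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ipv_report_bundle <- function(x, ...) {
  cat("IPV consistency analysis bundle\n")
  cat("Input:", x$manifest$config$input %||% paste("preset",
      x$manifest$config$preset), "\n")
  cat("Records:", x$manifest$n_input, "in;", x$manifest$n_eligible,
      "eligible\n")
  print(x$class_summary)
  invisible(x)
}
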