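# Six-wave cohort container, CSV input/output, eligibility filtering.
#
# A cohort is a plain data frame (class "ipv_cohort") in the wide layout:
# one row per woman, columns
#   id, ipv_w1..ipv_w6 ("Y"/"N"/NA),
#   rel_w1..rel_w6 (relationship status), pstress_w1..pstress_w6 (logical),
#   istress_w1..istress_w6 (logical), area, qual.
# MISSING is NA in memory and an empty cell on disk.

wave_cols <- function(prefix) paste0(prefix, "_w", seq_len(N_WAVES))

cohort_schema <- function() {
  c("id", wave_cols("ipv"), wave_cols("rel"), wave_cols("pstress"),
    wave_cols("istress"), "area", "qual")
}

#' Wave index/label map
#'
#' The six analysis waves with their calendar survey labels. Wave indices are
#' contiguous 1..6 internally; the labels carry the calendar years
#' (1996, 2004, 2007, 2010, 2013, 2016).
#'
#' @param labels optional character vector of 6 replacement labels.
#' @return data frame with columns `index` and `label`.
#' @export
waves <- function(labels = WAVE_LABELS) {
  stopifnot(length(labels) == N_WAVES)
  data.frame(index = seq_len(N_WAVES), label = as.character(labels))
}

#' Construct a cohort from a wide data frame
#'
#' Validates the wide schema and category codes and returns an `ipv_cohort`.
#'
#' @param df data frame with the documented wide columns.
#' @param provenance free-text origin (file path or simulation call).
#' @return an `ipv_cohort` (a validated data frame).
#' @export
as_cohort <- function(df, provenance = "in-memory") {
  missing_cols <- setdiff(cohort_schema(), names(df))
  if (length(missing_cols)) {
    stop("cohort schema error; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, cohort_schema()]
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  check_codes <- function(cols, allowed, what) {
    for (cl in cols) {
      v <- df[[cl]]
      v[v %in% ""] <- NA
      bad <- !is.na(v) & !(v %in% allowed)
      if (any(bad)) {
        stop("invalid ", what, " code(s) in column ", cl, ": ",
             paste(unique(v[bad]), collapse = ", "), call. = FALSE)
      }
      df[[cl]] <<- as.character(v)
    }
  }
  check_codes(wave_cols("ipv"), c("Y", "N"), "IPV response")
  check_codes(wave_cols("rel"), REL_LEVELS, "relationship status")
  check_codes("area", AREA_LEVELS, "area of residence")
  check_codes("qual", QUAL_LEVELS, "qualification")
  for (cl in c(wave_cols("pstress"), wave_cols("istress"))) {
    v <- df[[cl]]
    if (is.character(v)) v[v %in% ""] <- NA
    lv <- as.logical(v)
    if (any(!is.na(v) & is.na(lv))) {
      stop("invalid logical code(s) in column ", cl, call. = FALSE)
    }
    df[[cl]] <- lv
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("ipv_cohort", "data.frame"))
}

#' Read a cohort from a wide CSV file
#'
#' One row per woman; empty cells are missing values. Unknown category codes
#' and duplicate ids are rejected with informative errors.
#'
#' @param path CSV file path.
#' @param dialect code map as returned by [cohort_dialect()]; a YAML file
#'   path is also accepted.
#' @return an `ipv_cohort`.
#' @export
read_cohort <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect)) dialect <- cohort_dialect(yaml_file = dialect)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = dialect$na_string,
                        check.names = FALSE)
  recode <- function(cols, map) {
    for (cl in intersect(cols, names(df))) {
      v <- df[[cl]]
      hit <- !is.na(v) & v %in% names(map)
      v[hit] <- unname(map[v[hit]])
      df[[cl]] <<- v
    }
  }
  recode(wave_cols("ipv"), dialect$ipv_codes)
  recode(c(wave_cols("pstress"), wave_cols("istress")), dialect$logical_codes)
  as_cohort(df, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] under the default dialect: missing values become
#' empty cells and the round trip is lossless cell-for-cell.
#'
#' @param cohort an `ipv_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' CSV dialect (category code maps)
#'
#' Maps on-disk codes to the internal codes. The default reads "Y"/"N" IPV
#' answers and "TRUE"/"FALSE" stress flags directly; alternative exports
#' (e.g. "yes"/"no", "1"/"0") can be declared here or loaded from YAML with
#' fields `na_string`, `ipv_codes`, `logical_codes`.
#'
#' @param na_string string representing missing cells (default empty).
#' @param ipv_codes named character vector, names = disk codes, values in
#'   `c("Y","N")`.
#' @param logical_codes named character vector, values in
#'   `c("TRUE","FALSE")`.
#' @param yaml_file optional YAML file overriding the above.
#' @return a list of class `ipv_dialect`.
#' @export
cohort_dialect <- function(na_string = "",
                           ipv_codes = c(Y = "Y", N = "N"),
                           logical_codes = c(`TRUE` = "TRUE",
                                             `FALSE` = "FALSE"),
                           yaml_file = NULL) {
  d <- list(na_string = na_string,
            ipv_codes = ipv_codes,
            logical_codes = logical_codes)
  if (!is.null(yaml_file)) {
    y <- yaml::read_yaml(yaml_file)
    for (f in intersect(names(y), names(d))) d[[f]] <- unlist(y[[f]])
  }
  structure(d, class = "ipv_dialect")
}

#' Build a cohort skeleton from compact response patterns
#'
#' Convenience constructor for worked examples and simulations: takes compact
#' IPV pattern strings (see [parse_pattern()]) and fills the covariate
#' columns with constant defaults (overridable, recycled across records).
#'
#' @param patterns character vector of compact patterns, e.g. `"YNY..."`.
#' @param rel,pstress,istress per-record covariate values recycled across
#'   the six waves.
#' @param area,qual baseline covariates, recycled across records.
#' @param ids record identifiers (default `p0001`, `p0002`, ...).
#' @return an `ipv_cohort`.
#' @export
cohort_from_patterns <- function(patterns, rel = "married",
                                 pstress = FALSE, istress = FALSE,
                                 area = "major_city", qual = "university",
                                 ids = NULL) {
  m <- parse_pattern(patterns)
  n <- length(patterns)
  df <- data.frame(id = ids %||% sprintf("p%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  rel_m <- matrix(rel, n, N_WAVES)
  ps_m <- matrix(pstress, n, N_WAVES)
  is_m <- matrix(istress, n, N_WAVES)
  for (w in seq_len(N_WAVES)) df[[paste0("ipv_w", w)]] <- m[, w]
  for (w in seq_len(N_WAVES)) df[[paste0("rel_w", w)]] <- rel_m[, w]
  for (w in seq_len(N_WAVES)) df[[paste0("pstress_w", w)]] <- ps_m[, w]
  for (w in seq_len(N_WAVES)) df[[paste0("istress_w", w)]] <- is_m[, w]
  df$area <- rep_len(area, n)
  df$qual <- rep_len(qual, n)
  as_cohort(df, provenance = "cohort_from_patterns")
}

#' Extract the 6-column IPV response matrix
#'
#' @param cohort an `ipv_cohort`.
#' @return character matrix, n rows x 6 waves, entries "Y"/"N"/NA.
#' @export
ipv_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[, wave_cols("ipv")])
  dimnames(m) <- list(cohort$id, wave_cols("ipv"))
  m
}

answered_count <- function(m) rowSums(!is.na(m))

#' Eligibility of IPV response sequences
#'
#' A record is eligible when the IPV item was answered at wave 1 and at at
#' least two of waves 2..6 (hence at least three answers in total).
#'
#' @param x an `ipv_cohort`, a character matrix of responses (n x 6), or a
#'   single length-6 character vector with entries "Y"/"N"/NA.
#' @return logical vector, one element per record.
#' @export
is_eligible <- function(x) {
  m <- if (inherits(x, "ipv_cohort")) ipv_matrix(x)
       else if (is.matrix(x)) x
       else matrix(x, nrow = 1)
  stopifnot(ncol(m) == N_WAVES)
  !is.na(m[, 1]) & rowSums(!is.na(m[, -1, drop = FALSE])) >= 2
}

#' Filter a cohort to eligible records
#'
#' Splits a cohort into the eligible subset (input order preserved) and an
#' exclusion summary reporting how many records were dropped and the wave-1
#' IPV prevalence among excluded versus included women (among those who
#' answered at wave 1).
#'
#' @param cohort an `ipv_cohort`.
#' @return list with elements `cohort` (eligible `ipv_cohort`) and
#'   `exclusions` (class `ipv_exclusions`).
#' @export
filter_eligible <- function(cohort) {
  m <- ipv_matrix(cohort)
  keep <- is_eligible(m)
  w1_prev <- function(sub) {
    v <- m[sub, 1]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    round_half_up(100 * mean(v == "Y"), 1)
  }
  excl <- structure(list(
    n_input = nrow(cohort),
    n_eligible = sum(keep),
    n_excluded = sum(!keep),
    wave1_ipv_pct_excluded = w1_prev(!keep),
    wave1_ipv_pct_included = w1_prev(keep)
  ), class = "ipv_exclusions")
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- c("ipv_cohort", "data.frame")
  list(cohort = out, exclusions = excl)
}

#' @export
print.ipv_exclusions <- function(x, ...) {
  cat("Eligibility filter:", x$n_eligible, "eligible of", x$n_input,
      "records (", x$n_excluded, "excluded)\n")
  cat("Wave-1 IPV prevalence: excluded", x$wave1_ipv_pct_excluded,
      "% vs included", x$wave1_ipv_pct_included, "%\n")
  invisible(x)
}

#' @export
print.ipv_cohort <- function(x, ...) {
  cat("Six-wave IPV cohort:", nrow(x), "women",
      "(", sum(is_eligible(x)), "eligible )\n")
  cat("Provenance:", attr(x, "provenance") %||% "unknown", "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}
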