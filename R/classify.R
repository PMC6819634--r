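# Consistency classification of six-wave yes/no response sequences.
#
# The survey item asks about *lifetime* experience ("Have you ever been in a
# violent relationship with a partner/spouse?"), so once a truthful answer is
# YES it can never truthfully revert to NO. A NO given at a wave later than a
# YES is therefore an internal inconsistency. Classification looks only at
# the answered (non-missing) subsequence:
#
#   eligible sequences (wave 1 answered, >= 3 answers), with
#   y = number of YES among the n answered entries and a "drop" meaning some
#   YES occurs before a later NO:
#     no drop:  y == n -> CONSISTENT_IPV;  y == 0 -> CONSISTENT_NEVER_IPV;
#               otherwise (a NO-block then a YES-block) -> CONSISTENT_LATER_IPV
#     drop:     y == n - 1 -> MAINLY_IPV (IPV at all but one survey)
#               y == 1     -> MAINLY_NO_IPV (IPV at exactly one survey)
#               otherwise  -> MIXED_IPV
#
# Monotone sequences are always "consistent", so NYY is CONSISTENT_LATER_IPV
# even though it has exactly one NO; and YYN (one NO, but after a YES) is
# MAINLY_IPV. Inconsistent sequences with >= 2 YES and >= 2 NO are MIXED
# even when one-directional (YYNN).

class_levels <- function() c(ipv_classes(), ipv_ineligible())

#' Classify response sequences into consistency classes
#'
#' Classifies each row of a response matrix (entries "Y", "N", NA over the
#' six waves) into one of the six consistency classes, or `INELIGIBLE` when
#' wave 1 is missing or fewer than three answers are present. Classification
#' depends only on the answered subsequence.
#'
#' @param m character matrix with 6 columns ("Y"/"N"/NA), or a single
#'   length-6 character vector, or an `ipv_cohort`.
#' @return factor of length `nrow(m)` with levels
#'   `c(ipv_classes(), "INELIGIBLE")`.
#' @seealso [classify_pattern()] for compact pattern strings,
#'   [enumerate_class_counts()] for the exhaustive enumeration oracle.
#' @export
classify_sequences <- function(m) {
  if (inherits(m, "ipv_cohort")) m <- ipv_matrix(m)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  stopifnot(ncol(m) == N_WAVES)
  bad <- !is.na(m) & !(m %in% c("Y", "N"))
  if (any(bad)) {
    stop("invalid response code(s): ", paste(unique(m[bad]), collapse = ", "),
         call. = FALSE)
  }
  yes <- !is.na(m) & m == "Y"
  no  <- !is.na(m) & m == "N"
  n <- rowSums(yes) + rowSums(no)
  y <- rowSums(yes)
  nn <- rowSums(no)
  # first YES / last NO positions; only meaningful when the row has any
  first_yes <- max.col(yes, ties.method = "first")
  last_no   <- N_WAVES + 1L - max.col(no[, N_WAVES:1, drop = FALSE],
                                      ties.method = "first")
  drop <- y > 0 & nn > 0 & first_yes < last_no

  cls <- rep(ipv_ineligible(), nrow(m))
  elig <- !is.na(m[, 1]) & n >= 3
  cls[elig & !drop & y == n] <- "CONSISTENT_IPV"
  cls[elig & !drop & y == 0] <- "CONSISTENT_NEVER_IPV"
  cls[elig & !drop & y > 0 & y < n] <- "CONSISTENT_LATER_IPV"
  cls[elig & drop & y == n - 1] <- "MAINLY_IPV"
  cls[elig & drop & y == 1] <- "MAINLY_NO_IPV"
  cls[elig & drop & y > 1 & y < n - 1] <- "MIXED_IPV"
  factor(cls, levels = class_levels())
}

#' Parse compact pattern strings
#'
#' Turns strings like `"YNY"` or `"Y.N..Y"` into length-6 response vectors:
#' `Y`/`N` are answers, `.` (or `-`) a missing wave. Patterns shorter than 6
#' characters occupy the leading waves; the remaining waves are missing.
#'
#' @param pattern character vector of patterns, each of length at most 6.
#' @return character matrix, one row per pattern, 6 columns.
#' @export
parse_pattern <- function(pattern) {
  stopifnot(is.character(pattern), all(nchar(pattern) <= N_WAVES))
  m <- matrix(NA_character_, length(pattern), N_WAVES)
  for (i in seq_along(pattern)) {
    ch <- toupper(strsplit(pattern[i], "")[[1]])
    ch[ch %in% c(".", "-", "?")] <- NA
    if (any(!is.na(ch) & !(ch %in% c("Y", "N")))) {
      stop("invalid pattern character in '", pattern[i], "'", call. = FALSE)
    }
    if (length(ch)) m[i, seq_along(ch)] <- ch
  }
  m
}

#' Classify compact pattern strings
#'
#' @param pattern character vector of patterns, see [parse_pattern()].
#' @return factor of consistency classes, one per pattern.
#' @examples
#' classify_pattern(c("YYY", "NNY", "YNY", "NYN", "YNYN"))
#' @export
classify_pattern <- function(pattern) {
  classify_sequences(parse_pattern(pattern))
}

#' Annotate a cohort with consistency classes
#'
#' Adds a `consistency_class` factor column to the cohort.
#'
#' @param cohort an `ipv_cohort`.
#' @return the cohort with an added `consistency_class` column.
#' @export
classify_cohort <- function(cohort) {
  cls <- classify_sequences(ipv_matrix(cohort))
  cohort$consistency_class <- cls
  cohort
}

#' Exhaustive enumeration of class counts (oracle)
#'
#' Classifies every one of the `2^n` fully-answered YES/NO sequences of a
#' given length and tabulates the classes. Because the classification rule is
#' a partition, the counts always sum to `2^n`; and because MIXED requires at
#' least two YES and two NO answers after an inconsistency, the MIXED count
#' is 0 for `n = 3`. Used as a brute-force oracle for the classifier.
#'
#' @param n_answered integer number of answered waves, between 3 and 6.
#' @return named integer vector over the six classes, summing to
#'   `2^n_answered`.
#' @export
enumerate_class_counts <- function(n_answered) {
  if (length(n_answered) != 1 || !(n_answered %in% 3:6)) {
    stop("n_answered must be a single integer in 3..6", call. = FALSE)
  }
  g <- as.matrix(expand.grid(rep(list(c("Y", "N")), n_answered),
                             stringsAsFactors = FALSE))
  m <- matrix(NA_character_, nrow(g), N_WAVES)
  m[, seq_len(n_answered)] <- g
  cls <- classify_sequences(m)
  tab <- table(factor(cls, levels = ipv_classes()))
  out <- as.integer(tab)
  names(out) <- ipv_classes()
  out
}
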