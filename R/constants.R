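# Shared category levels and small numeric helpers.

#' Consistency class labels
#'
#' The six analysis classes for an eligible six-wave IPV response sequence,
#' in canonical order, plus the marker used for records that cannot be
#' classified (wave-1 answer missing or fewer than three answers overall).
#'
#' @format `ipv_classes()` returns a character vector of length 6;
#'   `ipv_ineligible()` the single marker string.
#' @export
ipv_classes <- function() {
  c("CONSISTENT_IPV", "CONSISTENT_LATER_IPV", "CONSISTENT_NEVER_IPV",
    "MAINLY_IPV", "MAINLY_NO_IPV", "MIXED_IPV")
}

#' @rdname ipv_classes
#' @export
ipv_ineligible <- function() "INELIGIBLE"

N_WAVES <- 6L

# Calendar labels for the six analysis waves (study surveys 1, 4, 5, 6, 7, 8).
WAVE_LABELS <- c("1996", "2004", "2007", "2010", "2013", "2016")

AREA_LEVELS <- c("major_city", "inner_regional", "outer_regional",
                 "remote_very_remote")
QUAL_LEVELS <- c("lt_year12", "year12", "trade_cert_diploma", "university")
REL_LEVELS  <- c("married", "defacto", "separated", "divorced", "widowed",
                 "single")
TRAJ_LEVELS <- c("NEVER_SEP_DIV", "REMAINED_SEP_DIV", "BECAME_PARTNERED",
                 "BECAME_SEP_DIV")
NSURV_LEVELS <- c("SIX", "FIVE", "THREE_FOUR")

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' all printed table percentages. Base [round()] rounds ties to even, which
#' turns 587/10966 into 5.3 rather than the printed 5.4.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
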