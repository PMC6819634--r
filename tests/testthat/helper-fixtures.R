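# Fixture builders shared across test files. Everything is generated in
# code; only the exported package API is used.

`%or%` <- function(a, b) if (is.null(a)) b else a

# Build a cohort from compact IPV pattern strings with constant, complete
# covariates unless overridden.
make_cohort <- function(patterns, ..., ids = NULL) {
  cohort_from_patterns(patterns, ...,
                       ids = ids %or% sprintf("w%03d", seq_along(patterns)))
}

# Random fully/partially answered pattern strings (wave-1 answered, >= 3
# answers) for property-style tests.
random_eligible_patterns <- function(n) {
  vapply(seq_len(n), function(i) {
    k <- sample(3:6, 1)
    waves <- sort(c(1, sample(2:6, k - 1)))
    ch <- rep(".", 6)
    ch[waves] <- sample(c("Y", "N"), k, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
}

# Independent oracle for "inconsistent": literal quantifier over answered
# entries — some YES strictly before some later NO.
has_yes_before_no <- function(seq6) {
  idx <- which(!is.na(seq6))
  r <- seq6[idx]
  for (i in seq_along(r)) {
    for (j in seq_along(r)) {
      if (i < j && r[i] == "Y" && r[j] == "N") return(TRUE)
    }
  }
  FALSE
}

# Draw profiles + classes from an explicit baseline-category logit so that
# regression recovery is checked against known coefficients. `beta` is a
# named vector of log odds (one per non-reference class) for a binary
# covariate; intercepts are log(p_k / p_ref) from `base_probs`.
simulate_logit_outcomes <- function(n, base_probs, beta, p_covariate = 0.15) {
  stopifnot(names(base_probs)[1] == "CONSISTENT_IPV")
  x <- stats::runif(n) < p_covariate
  alpha <- log(base_probs[-1] / base_probs[1])
  eta <- rbind(0, alpha + outer(beta, as.numeric(x)))  # (K x n)
  pr <- apply(eta, 2, function(e) exp(e) / sum(exp(e)))
  cls <- apply(pr, 2, function(p) sample(names(base_probs), 1, prob = p))
  data.frame(consistency_class = factor(cls, levels = names(base_probs)),
             istress_half = x)
}

reference_class_counts <- function() {
  c(CONSISTENT_IPV = 827, CONSISTENT_LATER_IPV = 347,
    CONSISTENT_NEVER_IPV = 8436, MAINLY_IPV = 258, MAINLY_NO_IPV = 587,
    MIXED_IPV = 511)
}
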