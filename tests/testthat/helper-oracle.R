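# Independent oracles, deliberately written as second implementations that
# share no code with the package internals.

# Mass oracle: regex-parse a formula string and sum tabulated isotope
# masses / atomic weights.
.ORACLE_MONO <- c(C = 12.0, H = 1.007825, N = 14.003074, O = 15.994915,
                  P = 30.973762, S = 31.972071, F = 18.998403)
.ORACLE_AVG <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                 P = 30.973762, S = 32.06, F = 18.998403)

oracle_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, list(m))[[1]]
  counts <- integer(0)
  for (p in pieces) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Za-z]", "", p)
    n <- if (n == "") 1L else as.integer(n)
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + n
  }
  counts
}

oracle_mono <- function(formula) {
  cn <- oracle_counts(formula)
  sum(.ORACLE_MONO[names(cn)] * cn)
}

oracle_avg <- function(formula) {
  cn <- oracle_counts(formula)
  sum(.ORACLE_AVG[names(cn)] * cn)
}

# Oligo mass oracle: neutral mass of a 5'-OH/3'-OH chain from nucleoside
# formulas, joined by (n-1) phosphodiester condensations (+HPO3 - H2O each).
oracle_oligo_mono <- function(nucleoside_formulas) {
  n <- length(nucleoside_formulas)
  sum(vapply(nucleoside_formulas, oracle_mono, numeric(1))) +
    (n - 1) * (oracle_mono("HPO3") - oracle_mono("H2O"))
}

# Ladder oracle: brute-force enumeration over all 2^r conversion patterns of
# r reactive positions with per-position mass deltas; returns the sorted
# distinct total deltas (and, optionally, their probabilities under
# per-position conversion probability p).
oracle_ladder <- function(deltas, p = NULL) {
  r <- length(deltas)
  if (r == 0) {
    return(data.frame(delta = 0, prob = if (is.null(p)) NA_real_ else 1))
  }
  patterns <- expand.grid(rep(list(c(0, 1)), r))
  total <- as.numeric(as.matrix(patterns) %*% deltas)
  prob <- if (is.null(p)) rep(NA_real_, nrow(patterns)) else
    apply(patterns, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  agg <- aggregate(prob, by = list(delta = round(total, 6)), FUN = sum)
  names(agg) <- c("delta", "prob")
  agg[order(agg$delta), ]
}

# Random modified-RNA sequence generator for property tests.
random_tokens <- function(n, include_modified = TRUE) {
  pool <- c("A", "C", "G", "U")
  if (include_modified) {
    pool <- c(pool, "Psi", "m5C", "m1A", "Gm", "m7G", "D", "s4U", "ac4C")
  }
  sample(pool, n, replace = TRUE)
}
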