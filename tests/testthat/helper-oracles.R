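# Independent oracles and shared fixtures for the test suite.

# Brute-force two-tailed Fisher p by hypergeometric enumeration over all
# tables with the observed margins: sum of probabilities <= observed
# (relative tolerance 1e-7). Independent of stats::fisher.test().
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Apply a single variant to a linear representation of a circular sequence;
# returns the edited string rotated so comparisons are rotation-invariant.
# Used as the sequence-equality oracle for indel normalization.
apply_variant_oracle <- function(seq, position, ref, alt) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  wrap <- function(i) ((i - 1L) %% L) + 1L
  if (ref != "" && alt == "") {            # deletion
    idx <- wrap(position + 0:(nchar(ref) - 1L))
    stopifnot(paste(chars[idx], collapse = "") == ref)
    out <- chars[-idx]
  } else if (ref == "" && alt != "") {     # insertion after `position`
    p <- wrap(position)
    out <- append(chars, strsplit(alt, "")[[1]], after = p)
  } else {                                 # substitution
    p <- wrap(position)
    stopifnot(chars[p] == ref)
    chars[p] <- alt
    out <- chars
  }
  s <- paste(out, collapse = "")
  # canonical rotation: the lexicographically smallest rotation
  n <- nchar(s)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(s, i, n), substr(s, 1, i - 1L))
  }, character(1))
  min(rots)
}

# Is an observed success count consistent with Binomial(n, p)? Uses the
# central 99.8% exact binomial interval, the conventional band for
# deterministic-seed checks of stochastic generators.
binom_consistent <- function(x, n, p) {
  x >= stats::qbinom(0.001, n, p) && x <= stats::qbinom(0.999, n, p)
}

# Cached default simulated cohort so several test files can share one run.
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cohort(simulation_config(seed = 101L))
  }
  .fixture_env$sim
}

synthetic_ref <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- rcrs_synthetic()
  .fixture_env$ref
}
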