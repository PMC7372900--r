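# Independent oracles, kept deliberately naive and separate from the
# package's computation paths.

# Closed-form outputs of the 16 two-input PC logic functions, one formula
# per index, written directly from the algebra of each function.
pc_two_input_formulas <- list(
  function(a, b) 0 * a,
  function(a, b) (1 - a) * (1 - b),
  function(a, b) b - a * b,
  function(a, b) 1 - a,
  function(a, b) a - a * b,
  function(a, b) 1 - b,
  function(a, b) a + b - 2 * a * b,
  function(a, b) 1 - a * b,
  function(a, b) a * b,
  function(a, b) 1 - a - b + 2 * a * b,
  function(a, b) b + 0 * a,
  function(a, b) 1 - a + a * b,
  function(a, b) a + 0 * b,
  function(a, b) 1 - b + a * b,
  function(a, b) a + b - a * b,
  function(a, b) 1 + 0 * a
)

# Textbook beta log-density, written out in lgamma terms (the package path
# goes through stats::dbeta).
beta_logpdf_oracle <- function(t, alpha, beta) {
  lgamma(alpha + beta) - lgamma(alpha) - lgamma(beta) +
    (alpha - 1) * log(t) + (beta - 1) * log(1 - t)
}

# Naive sum over samples of the oracle beta log-density under the
# mean-matched parameterisation.
loglik_oracle <- function(target, f, c, eps, delta = 1e-4) {
  t <- pmin(pmax(target, delta), 1 - delta)
  sum(beta_logpdf_oracle(t, c * f + eps, c * (1 - f) + eps))
}

# Brute-force PC evaluation from the mask definition: sum over active
# partitions of the product of literal probabilities, all in explicit
# loops.
pc_eval_bruteforce <- function(mask, x) {
  k <- length(x)
  total <- 0
  for (p in seq_along(mask) - 1L) {
    if (mask[p + 1L] == 0L) next
    term <- 1
    for (j in seq_len(k)) {
      bit <- (p %/% 2^(k - j)) %% 2
      term <- term * if (bit == 1) x[j] else 1 - x[j]
    }
    total <- total + term
  }
  total
}

# Reduce a logic to its essential inputs by fixing every non-essential bit
# to zero (legal because the truth table does not depend on them).
reduce_to_essential <- function(f) {
  ess <- essential_inputs(f)
  k <- f$arity
  m <- length(ess)
  mask <- integer(2^m)
  for (q in seq_len(2^m) - 1L) {
    p <- 0L
    for (jj in seq_len(m)) {
      bit <- (q %/% 2^(m - jj)) %% 2
      if (bit == 1) p <- p + 2^(k - ess[jj])
    }
    mask[q + 1L] <- f$mask[p + 1L]
  }
  list(inputs = ess, logic = logic_function(m, mask = mask))
}

# A tiny hand-assembled ground truth: G5 = AND(G1, G2) among five genes,
# the others left as uniform roots.
and_target_network <- function() {
  logical_network(
    genes = paste0("G", 1:5),
    targets = list(
      G5 = list(regulators = c("G1", "G2"), signs = c(1L, 1L),
                logic = gate_logic("AND", c(1, 1)), gate = "AND")
    )
  )
}
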