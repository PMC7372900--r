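#' Bayesian information criterion for a k-regulator logic model
#'
#' \code{BIC = -2 * loglik + 2^k * log(n)}: a k-input logic function carries
#' one on/off parameter per Venn partition, hence 2^k parameters. Natural
#' logarithm, as in the standard BIC.
#'
#' @param loglik model log-likelihood.
#' @param k number of regulator inputs (>= 0).
#' @param n number of expression samples (>= 1).
#' @return the BIC value (smaller is better).
#' @examples
#' bic(-10, k = 2, n = 10)  # 20 + 4 * log(10)
#' @export
bic <- function(loglik, k, n) {
  if (n < 1) stop("`n` must be >= 1")
  if (k < 0) stop("`k` must be >= 0")
  -2 * loglik + 2^k * log(n)
}

#' Log-likelihood of the non-informative null logic
#'
#' The null is a logic without biological meaning, used as the Bayes-factor
#' reference. Two readings are provided: \code{"constant_half"} (default)
#' fixes the logic output at 0.5 in every sample — the expected output of a
#' uniformly random logic at random inputs, deterministic and independent of
#' the regulator data; \code{"random_sample"} averages the log-likelihood
#' over \code{n_draws} logic functions drawn uniformly without replacement
#' from the arity's full enumeration (all of them when \code{n_draws}
#' reaches the enumeration size), evaluated on the supplied regulator data.
#'
#' @param target_samples target expression levels in [0, 1].
#' @param c,eps,delta as in \code{\link{log_likelihood}}.
#' @param mode \code{"constant_half"} or \code{"random_sample"}.
#' @param regulator_data matrix (one row per regulator, one column per
#'   sample); required for \code{"random_sample"}.
#' @param n_draws number of random logics to average over (default 100).
#' @param seed integer seed for the random draws.
#' @param logic_family \code{"pc"} or \code{"fuzzy"} semantics for the
#'   random draws.
#' @return the null log-likelihood.
#' @export
null_model_loglik <- function(target_samples, c = 1000, eps = 1e-4,
                              delta = 1e-4,
                              mode = c("constant_half", "random_sample"),
                              regulator_data = NULL, n_draws = 100,
                              seed = 1L,
                              logic_family = c("pc", "fuzzy")) {
  mode <- match.arg(mode)
  logic_family <- match.arg(logic_family)
  if (mode == "constant_half") {
    return(log_likelihood(target_samples,
                          rep(0.5, length(target_samples)),
                          c = c, eps = eps, delta = delta))
  }
  if (is.null(regulator_data)) {
    stop("`regulator_data` is required for mode = \"random_sample\"")
  }
  if (is.null(dim(regulator_data))) {
    regulator_data <- matrix(regulator_data, nrow = 1L)
  }
  k <- nrow(regulator_data)
  n_fun <- 2^(2^k)
  eval_fun <- if (logic_family == "pc") evaluate_pc else evaluate_fuzzy
  draws <- if (n_draws >= n_fun) {
    seq_len(n_fun) - 1L
  } else {
    withr::with_seed(seed, sample.int(n_fun, n_draws)) - 1L
  }
  lls <- vapply(draws, function(i) {
    f <- logic_function(k, index = i)
    log_likelihood(target_samples, eval_fun(f, regulator_data),
                   c = c, eps = eps, delta = delta)
  }, numeric(1))
  mean(lls)
}

#' Bayes factor of a selected model against the null
#'
#' \code{BF = exp(loglik_m1 - loglik_m0)}, the likelihood ratio of the
#' minimum-BIC logic model to the non-informative null. Decisive support
#' requires \code{BF > 100} (strict); overflow returns \code{Inf}, which
#' passes the threshold.
#'
#' @param loglik_m1 log-likelihood of the selected model.
#' @param loglik_m0 log-likelihood of the null
#'   (\code{\link{null_model_loglik}}).
#' @return nonnegative numeric (possibly \code{Inf}).
#' @export
bayes_factor <- function(loglik_m1, loglik_m0) {
  exp(loglik_m1 - loglik_m0)
}

#' Decisive-support predicate for a Bayes factor
#'
#' Strict comparison: \code{bf > threshold}; a Bayes factor exactly at the
#' threshold is not decisive.
#'
#' @param bf a Bayes factor.
#' @param threshold cutoff (default 100).
#' @return logical.
#' @export
is_decisive <- function(bf, threshold = 100) {
  bf > threshold
}
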