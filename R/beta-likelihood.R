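#' Beta shape parameters implied by a logic output
#'
#' A target's expression level in [0, 1] is modelled as a beta draw whose
#' mean equals the logic-function output f for that sample: with total
#' concentration \code{c = alpha + beta}, \code{alpha = c * f} and
#' \code{beta = c * (1 - f)}, so that \code{E(T) = alpha / (alpha + beta)
#' = f}. A small \code{eps} is added to both shapes so they stay strictly
#' positive when f hits 0 or 1.
#'
#' @param f_value logic output(s) in [0, 1].
#' @param c total concentration alpha + beta (> 0); larger values mean less
#'   dispersion of the target around the logic output. Default 1000.
#' @param eps nonnegative shift added to both shapes (default 1e-4).
#' @return list with numeric fields \code{alpha} and \code{beta}, the same
#'   length as \code{f_value}.
#' @examples
#' beta_params_from_logic(0.5, c = 1000, eps = 0)  # alpha = beta = 500
#' @export
beta_params_from_logic <- function(f_value, c = 1000, eps = 1e-4) {
  check_unit_values(f_value)
  if (c <= 0) stop("`c` must be positive")
  if (eps < 0) stop("`eps` must be nonnegative")
  list(alpha = c * f_value + eps, beta = c * (1 - f_value) + eps)
}

#' Clamp values into the open unit interval
#'
#' Min-max scaling leaves at least one exact 0 and one exact 1 per gene,
#' which would send the log terms of the beta density to -Inf; values are
#' pulled into \code{[delta, 1 - delta]}. Interior values are unchanged and
#' the map is idempotent.
#'
#' @param values numeric vector.
#' @param delta half-width of the excluded boundary, in (0, 0.5);
#'   default 1e-4.
#' @return clamped numeric vector.
#' @export
clamp_unit_interval <- function(values, delta = 1e-4) {
  if (delta <= 0 || delta >= 0.5) stop("`delta` must lie in (0, 0.5)")
  pmin(pmax(values, delta), 1 - delta)
}

#' Beta log-likelihood of target samples given logic outputs
#'
#' Sums, over samples s, the log beta density of the target level
#' \code{T_s} under shapes \code{alpha_s = c * f_s + eps},
#' \code{beta_s = c * (1 - f_s) + eps}, where \code{f_s} is the logic
#' output computed from the regulators in sample s. Target samples are
#' clamped into \code{[delta, 1 - delta]} first so the result is always
#' finite.
#'
#' @param target_samples target expression levels in [0, 1], length n.
#' @param logic_outputs logic-function outputs in [0, 1], length n.
#' @param c total beta concentration (default 1000).
#' @param eps shape shift (default 1e-4).
#' @param delta boundary clamp applied to \code{target_samples}
#'   (default 1e-4).
#' @return the log-likelihood (a single finite number).
#' @export
log_likelihood <- function(target_samples, logic_outputs, c = 1000,
                           eps = 1e-4, delta = 1e-4) {
  if (length(target_samples) != length(logic_outputs)) {
    stop("`target_samples` and `logic_outputs` must have equal length")
  }
  if (length(target_samples) < 1L) stop("need at least one sample")
  check_unit_values(target_samples)
  par <- beta_params_from_logic(logic_outputs, c = c, eps = eps)
  tt <- clamp_unit_interval(target_samples, delta)
  sum(stats::dbeta(tt, par$alpha, par$beta, log = TRUE))
}
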