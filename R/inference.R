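#' Inference configuration
#'
#' Bundles the tunable parameters of the network-reconstruction workflow.
#'
#' @param c beta concentration alpha + beta (default 1000; results are
#'   insensitive over roughly 500-1250).
#' @param eps shift keeping the beta shapes positive (default 1e-4).
#' @param delta boundary clamp on target samples (default 1e-4).
#' @param k_max deepest regulator-subset size searched, 1 to 4 (default 3;
#'   4 is supported but the candidate count grows as
#'   \code{2^(2^k) * choose(N-1, k)}).
#' @param bf_threshold Bayes-factor cutoff for decisive support
#'   (default 100, strict inequality).
#' @param logic_family \code{"pc"} (probabilistic-continuous, the default)
#'   or \code{"fuzzy"} evaluation semantics.
#' @param null_mode null model for the Bayes factor; see
#'   \code{\link{null_model_loglik}}.
#' @param n_null_draws draws for the \code{"random_sample"} null.
#' @param seed integer seed for any stochastic step (only the
#'   \code{"random_sample"} null uses randomness).
#' @return a list of class \code{inference_config}.
#' @export
inference_config <- function(c = 1000, eps = 1e-4, delta = 1e-4, k_max = 3,
                             bf_threshold = 100,
                             logic_family = c("pc", "fuzzy"),
                             null_mode = c("constant_half", "random_sample"),
                             n_null_draws = 100, seed = 1L) {
  logic_family <- match.arg(logic_family)
  null_mode <- match.arg(null_mode)
  if (k_max < 1 || k_max > MAX_ARITY) {
    stop("`k_max` must be between 1 and ", MAX_ARITY)
  }
  if (bf_threshold <= 0) stop("`bf_threshold` must be positive")
  if (c <= 0) stop("`c` must be positive")
  structure(
    list(c = c, eps = eps, delta = delta, k_max = as.integer(k_max),
         bf_threshold = bf_threshold, logic_family = logic_family,
         null_mode = null_mode, n_null_draws = as.integer(n_null_draws),
         seed = as.integer(seed)),
    class = "inference_config"
  )
}

check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr))) stop("`expr` must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in `expr`")
  check_unit_values(expr)
  invisible(expr)
}

null_loglik_for <- function(target_samples, regulator_data, config) {
  null_model_loglik(
    target_samples,
    c = config$c, eps = config$eps, delta = config$delta,
    mode = config$null_mode, regulator_data = regulator_data,
    n_draws = config$n_null_draws, seed = config$seed,
    logic_family = config$logic_family
  )
}

#' Score one (target, regulator subset, logic) candidate
#'
#' Evaluates the logic on the regulators sample by sample, computes the beta
#' log-likelihood of the target, the BIC with 2^k parameters, and the Bayes
#' factor against the configured null.
#'
#' @param target target gene id.
#' @param regulators character vector of regulator gene ids (the logic's
#'   inputs, in order); must not contain the target.
#' @param logic a \code{\link{logic_function}} whose arity equals
#'   \code{length(regulators)}.
#' @param expr numeric genes-x-samples matrix with values in [0, 1] and
#'   gene ids as rownames.
#' @param config an \code{\link{inference_config}}.
#' @return a list of class \code{scored_model} with fields \code{target},
#'   \code{regulators}, \code{logic}, \code{loglik}, \code{bic},
#'   \code{bayes_factor}.
#' @export
score_candidate <- function(target, regulators, logic, expr,
                            config = inference_config()) {
  check_expression_matrix(expr)
  if (target %in% regulators) {
    stop("target '", target, "' cannot be one of its own regulators")
  }
  missing <- setdiff(c(target, regulators), rownames(expr))
  if (length(missing)) {
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  }
  if (length(regulators) != logic$arity) {
    stop("logic arity ", logic$arity, " does not match ",
         length(regulators), " regulators")
  }
  x <- expr[regulators, , drop = FALSE]
  eval_fun <- if (config$logic_family == "pc") evaluate_pc else evaluate_fuzzy
  f_s <- eval_fun(logic, x)
  ll <- log_likelihood(expr[target, ], f_s, c = config$c, eps = config$eps,
                       delta = config$delta)
  ll0 <- null_loglik_for(expr[target, ], x, config)
  new_scored_model(target, regulators, logic, ll,
                   bic(ll, logic$arity, ncol(expr)),
                   bayes_factor(ll, ll0))
}

new_scored_model <- function(target, regulators, logic, loglik, bic_value,
                             bf) {
  structure(
    list(target = target, regulators = regulators, logic = logic,
         loglik = loglik, bic = bic_value, bayes_factor = bf),
    class = "scored_model"
  )
}

#' @export
print.scored_model <- function(x, ...) {
  cat(sprintf(
    "<scored_model> %s = %s  (loglik %.3f, BIC %.3f, BF %.4g)\n",
    x$target, logic_to_string(x$logic, x$regulators, ascii = TRUE),
    x$loglik, x$bic, x$bayes_factor
  ))
  invisible(x)
}

# Log-likelihood of every logic of arity k on one regulator subset, in one
# pass: the 2^k partition terms are shared by all 2^(2^k) masks, so logic
# outputs are a single mask-matrix product.
score_all_logics <- function(target_samples, x, config) {
  k <- nrow(x)
  n <- ncol(x)
  mm <- logic_mask_matrix(k)
  if (config$logic_family == "pc") {
    fmat <- mm %*% partition_probs(x, k)
  } else {
    fmat <- pmin(mm %*% partition_terms_fuzzy(x, k), 1)
  }
  alpha <- config$c * fmat + config$eps
  beta <- config$c * (1 - fmat) + config$eps
  tmat <- matrix(clamp_unit_interval(target_samples, config$delta),
                 nrow = nrow(fmat), ncol = n, byrow = TRUE)
  ll <- rowSums(stats::dbeta(tmat, alpha, beta, log = TRUE))
  list(loglik = ll, bic = -2 * ll + 2^k * log(n))
}

#' Infer the best-supported logic model for one target gene
#'
#' Exhaustively scores every subset of the other genes of size 1 to
#' \code{k_max} (or exactly the supplied \code{fixed_regulators}) crossed
#' with every logic function of matching arity; keeps the minimum-BIC
#' candidate (ties: fewer regulators, then the lexicographically earlier
#' subset, then the smaller logic index); accepts it only when its Bayes
#' factor against the null exceeds \code{bf_threshold}.
#'
#' @inheritParams score_candidate
#' @param fixed_regulators optional character vector: restrict the search to
#'   logics over exactly this regulator set (logic-detection mode for a
#'   known structure).
#' @return a \code{scored_model}, or \code{NULL} when no candidate reaches
#'   decisive support.
#' @export
infer_target <- function(target, expr, config = inference_config(),
                         fixed_regulators = NULL) {
  check_expression_matrix(expr)
  genes <- rownames(expr)
  if (length(genes) < 2L) stop("`expr` must contain at least 2 genes")
  if (!target %in% genes) stop("unknown target gene '", target, "'")
  n <- ncol(expr)
  target_samples <- expr[target, ]

  if (is.null(fixed_regulators)) {
    others <- setdiff(genes, target)  # preserves matrix row order
    subsets <- unlist(lapply(seq_len(min(config$k_max, length(others))),
                             function(k) {
                               utils::combn(others, k, simplify = FALSE)
                             }),
                      recursive = FALSE)
  } else {
    if (target %in% fixed_regulators) {
      stop("target '", target, "' cannot be one of its own regulators")
    }
    if (!all(fixed_regulators %in% genes)) stop("unknown fixed regulator(s)")
    if (length(fixed_regulators) > MAX_ARITY) {
      stop("at most ", MAX_ARITY, " fixed regulators are supported")
    }
    subsets <- list(fixed_regulators)
  }

  best <- NULL
  for (subset in subsets) {
    x <- expr[subset, , drop = FALSE]
    sc <- score_all_logics(target_samples, x, config)
    i <- which.min(sc$bic)  # first minimum = smallest logic index
    if (is.null(best) || sc$bic[i] < best$bic) {
      best <- list(bic = sc$bic[i], loglik = sc$loglik[i],
                   subset = subset, logic_index = i - 1L)
    }
  }
  logic <- logic_function(length(best$subset), index = best$logic_index)
  ll0 <- null_loglik_for(target_samples,
                         expr[best$subset, , drop = FALSE], config)
  bf <- bayes_factor(best$loglik, ll0)
  if (!is_decisive(bf, config$bf_threshold)) return(NULL)
  new_scored_model(target, best$subset, logic, best$loglik, best$bic, bf)
}

#' Reconstruct the directed logical network for all genes
#'
#' Runs \code{\link{infer_target}} with every gene as the target and
#' assembles the accepted models into a signed directed edge list. Only
#' essential inputs of each accepted logic become edges; the edge sign is
#' +1 for an activator, -1 for an inhibitor and 0 for a mixed (e.g. XOR)
#' effect.
#'
#' @inheritParams score_candidate
#' @return a list of class \code{grn_prediction} with \code{models} (named
#'   list of \code{scored_model}, one entry per gene, \code{NULL} where no
#'   model reached decisive support) and \code{edges} (data.frame with
#'   columns \code{regulator}, \code{target}, \code{sign}, \code{bf}).
#' @export
infer_network <- function(expr, config = inference_config()) {
  check_expression_matrix(expr)
  genes <- rownames(expr)
  models <- lapply(genes, infer_target, expr = expr, config = config)
  names(models) <- genes
  edges <- prediction_edges(models)
  structure(list(models = models, edges = edges, genes = genes),
            class = "grn_prediction")
}

prediction_edges <- function(models) {
  rows <- list()
  for (m in models) {
    if (is.null(m)) next
    ess <- essential_inputs(m$logic)
    if (length(ess) == 0L) next
    signs <- regulator_signs(m$logic)[ess]
    rows[[length(rows) + 1L]] <- data.frame(
      regulator = m$regulators[ess],
      target = m$target,
      sign = ifelse(signs == "activator", 1L,
                    ifelse(signs == "inhibitor", -1L, 0L)),
      bf = m$bayes_factor,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(regulator = character(0), target = character(0),
                      sign = integer(0), bf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.grn_prediction <- function(x, ...) {
  n_mod <- sum(!vapply(x$models, is.null, logical(1)))
  cat(sprintf("<grn_prediction> %d genes, %d accepted models, %d edges\n",
              length(x$genes), n_mod, nrow(x$edges)))
  invisible(x)
}

#' Exact number of candidate models per target
#'
#' For N genes and subset sizes 1 .. k_max, each target is scored against
#' \code{sum_j 2^(2^j) * choose(N-1, j)} (subset, logic) candidates; the
#' search over all N targets therefore costs
#' \code{O(n * 2^(2^k) * N^(k+1))} likelihood evaluations for n samples.
#'
#' @param N number of genes in the network (>= 2).
#' @param k_max deepest subset size (1 to 4).
#' @return the candidate count for a single target.
#' @examples
#' count_candidate_models(10, 3)  # 22116
#' @export
count_candidate_models <- function(N, k_max) {
  if (N < 2) stop("`N` must be >= 2")
  if (k_max < 1 || k_max > MAX_ARITY) {
    stop("`k_max` must be between 1 and ", MAX_ARITY)
  }
  sum(vapply(seq_len(k_max),
             function(j) 2^(2^j) * choose(N - 1, j),
             numeric(1)))
}
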