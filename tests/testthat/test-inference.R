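sim_expr <- function(net, n, seed, c = 1000) {
  simulate_expression(net, simulation_config(n_samples = n, c = c,
                                             seed = seed))
}

test_that("score_candidate prefers the generating logic and checks inputs", {
  net <- and_target_network()
  expr <- sim_expr(net, 50, seed = 21)
  cfg <- inference_config()
  and2 <- logic_function(2, 8)
  xor2 <- logic_function(2, 6)
  m_and <- score_candidate("G5", c("G1", "G2"), and2, expr, cfg)
  m_xor <- score_candidate("G5", c("G1", "G2"), xor2, expr, cfg)
  expect_gt(m_and$loglik, m_xor$loglik)
  expect_equal(m_and$bic, -2 * m_and$loglik + 4 * log(50))
  expect_true(m_and$bayes_factor > 100)
  # density ordering for constant logics
  hi <- expr
  hi["G5", ] <- 0.999
  c1 <- score_candidate("G5", c("G1", "G2"), logic_function(2, 15), hi, cfg)
  c0 <- score_candidate("G5", c("G1", "G2"), logic_function(2, 0), hi, cfg)
  expect_gt(c1$loglik, c0$loglik)
  expect_error(score_candidate("G5", c("G5", "G1"), and2, expr, cfg),
               "own regulators")
  expect_error(score_candidate("G5", c("G1", "GX"), and2, expr, cfg),
               "unknown")
  expect_error(score_candidate("G5", c("G1"), and2, expr, cfg), "arity")
})

test_that("infer_target matches a naive exhaustive re-scoring", {
  # independent brute force: loops over subsets and enumerated logics,
  # oracle likelihood, no shared code with the fast path
  net <- and_target_network()
  # N = 4 genes including the regulated one
  expr <- sim_expr(net, 15, seed = 33)[c("G1", "G2", "G3", "G5"), ]
  cfg <- inference_config(k_max = 2)
  naive_best <- function(target) {
    genes <- rownames(expr)
    others <- setdiff(genes, target)
    best <- NULL
    for (k in 1:2) {
      subs <- utils::combn(others, k, simplify = FALSE)
      for (s in subs) {
        for (f in enumerate_logic_functions(k)) {
          fs <- vapply(seq_len(ncol(expr)), function(j) {
            pc_eval_bruteforce(f$mask, expr[s, j])
          }, numeric(1))
          ll <- loglik_oracle(expr[target, ], fs, 1000, 1e-4)
          b <- -2 * ll + 2^k * log(ncol(expr))
          if (is.null(best) || b < best$bic) {
            best <- list(bic = b, subset = s, index = f$index)
          }
        }
      }
    }
    best
  }
  checked <- 0L
  for (target in c("G5", "G3")) {
    got <- infer_target(target, expr, cfg)
    want <- naive_best(target)
    if (is.null(got)) next  # below the BF cutoff; nothing to compare
    checked <- checked + 1L
    expect_identical(got$regulators, want$subset)
    expect_identical(got$logic$index, want$index)
    expect_equal(got$bic, want$bic, tolerance = 1e-6)
  }
  expect_gte(checked, 1L)  # the regulated target must be comparable
})

test_that("the generating AND model is recovered with decisive support", {
  net <- and_target_network()
  expr <- sim_expr(net, 50, seed = 7)
  m <- infer_target("G5", expr, inference_config())
  expect_false(is.null(m))
  expect_setequal(m$regulators, c("G1", "G2"))
  expect_identical(m$logic$index, 8L)
  expect_true(m$bayes_factor > 100)
})

test_that("the BF filter rejects when the null already explains the target", {
  # a target sitting at 0.5 is exactly what the non-informative null
  # predicts; no logic model can beat it decisively
  set.seed(55)
  rejected <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    expr <- matrix(runif(5 * 10), nrow = 5,
                   dimnames = list(paste0("G", 1:5), NULL))
    expr["G1", ] <- rbeta(10, 500, 500)  # concentrated at the null mean
    m <- infer_target("G1", expr, inference_config(k_max = 2))
    if (is.null(m)) rejected <- rejected + 1L
  }
  expect_gte(rejected, 8L)
})

test_that("fixed-regulator mode restricts the search to that subset", {
  net <- and_target_network()
  expr <- sim_expr(net, 30, seed = 9)
  m <- infer_target("G5", expr, inference_config(),
                    fixed_regulators = c("G1", "G2"))
  expect_identical(m$regulators, c("G1", "G2"))
  expect_identical(m$logic$arity, 2L)
  # single known regulator: selection lands in the four 1-input logics
  m1 <- infer_target("G5", expr, inference_config(bf_threshold = 1e-12),
                     fixed_regulators = "G1")
  expect_true(m1$logic$index %in% 0:3)
  expect_error(infer_target("G5", expr, inference_config(),
                            fixed_regulators = c("G5")), "own regulators")
})

test_that("accepted models never carry a non-essential regulator", {
  net <- and_target_network()
  expr <- sim_expr(net, 20, seed = 77)
  pred <- infer_network(expr, inference_config(k_max = 3))
  for (m in pred$models) {
    if (is.null(m)) next
    expect_identical(essential_inputs(m$logic),
                     seq_along(m$regulators))
  }
  # and no self-edges in the assembled edge list
  expect_false(any(pred$edges$regulator == pred$edges$target))
})

test_that("network inference is deterministic given config and data", {
  net <- and_target_network()
  expr <- sim_expr(net, 10, seed = 2)
  p1 <- infer_network(expr, inference_config())
  p2 <- infer_network(expr, inference_config())
  expect_identical(p1$edges, p2$edges)
  expect_identical(lapply(p1$models, function(m) m$bic),
                   lapply(p2$models, function(m) m$bic))
})

test_that("a three-gene chain is recovered with signs", {
  net <- logical_network(
    genes = c("G1", "G2", "G3"),
    targets = list(
      G2 = list(regulators = "G1", signs = 1L,
                logic = gate_logic("LITERAL", 1L), gate = "LITERAL"),
      G3 = list(regulators = "G2", signs = -1L,
                logic = gate_logic("LITERAL", -1L), gate = "LITERAL")
    )
  )
  expr <- sim_expr(net, 50, seed = 19)
  pred <- infer_network(expr, inference_config(k_max = 2))
  edges <- pred$edges[order(pred$edges$target), c("regulator", "target",
                                                  "sign")]
  rownames(edges) <- NULL
  expect_true(all(c("G2", "G3") %in% edges$target))
  expect_identical(edges[edges$target == "G2", "regulator"], "G1")
  expect_identical(edges[edges$target == "G2", "sign"], 1L)
  expect_identical(edges[edges$target == "G3", "regulator"], "G2")
  expect_identical(edges[edges$target == "G3", "sign"], -1L)
})

test_that("candidate counts follow the per-target enumeration formula", {
  expect_identical(count_candidate_models(10, 1), 36)
  expect_identical(count_candidate_models(10, 3), 22116)
  expect_identical(count_candidate_models(2, 1), 4)
  # independent summation
  for (N in c(5, 8)) {
    for (kmax in 1:3) {
      want <- 0
      for (j in 1:kmax) want <- want + 2^(2^j) * choose(N - 1, j)
      expect_identical(count_candidate_models(N, kmax), want)
    }
  }
  expect_error(count_candidate_models(1, 1), "N")
  expect_error(count_candidate_models(10, 5), "k_max")
})
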