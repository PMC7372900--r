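test_that("enumeration is complete, ordered, and bounded by the constants", {
  for (k in 0:3) {
    fns <- enumerate_logic_functions(k)
    expect_length(fns, 2^(2^k))
    expect_equal(vapply(fns, `[[`, integer(1), "index"),
                 0:(2^(2^k) - 1L))
    expect_true(all(fns[[1]]$mask == 0L))          # constant 0
    expect_true(all(fns[[length(fns)]]$mask == 1L))  # constant 1
  }
  expect_error(enumerate_logic_functions(-1), "arity")
  expect_error(enumerate_logic_functions(5), "arity")
})

test_that("index and mask encodings agree and cross-validate", {
  for (i in c(0, 3, 8, 9, 14, 15)) {
    f <- logic_function(2, index = i)
    expect_equal(sum(f$mask * 2^(0:3)), i)
    expect_equal(logic_function(2, mask = f$mask)$index, i)
  }
  expect_error(logic_function(2, index = 16), "index")
  expect_error(logic_function(2, index = 8, mask = c(1, 0, 0, 0)),
               "disagree")
})

test_that("PC evaluation matches worked examples", {
  expect_equal(evaluate_pc(logic_function(2, 8), c(0.5, 0.5)), 0.25)
  expect_equal(evaluate_pc(logic_function(2, 14), c(0.3, 0.4)), 0.58)
  expect_equal(evaluate_pc(logic_function(2, 6), c(0.5, 0.5)), 0.5)
  x <- c(0.123, 0.876)
  expect_equal(evaluate_pc(logic_function(2, 0), x), 0)
  expect_equal(evaluate_pc(logic_function(2, 15), x), 1)
  # k = 1: the four functions are 0, NOT, identity, 1
  expect_equal(evaluate_pc(logic_function(1, 1), 0.2), 0.8)
  expect_equal(evaluate_pc(logic_function(1, 2), 0.2), 0.2)
})

test_that("PC evaluation matches the 16 two-input closed forms on a grid", {
  grid <- expand.grid(a = seq(0, 1, by = 0.1), b = seq(0, 1, by = 0.1))
  for (i in 0:15) {
    f <- logic_function(2, index = i)
    got <- apply(grid, 1, function(r) evaluate_pc(f, c(r[["a"]], r[["b"]])))
    want <- pc_two_input_formulas[[i + 1]](grid$a, grid$b)
    expect_equal(got, unname(want), tolerance = 1e-12,
                 label = paste("logic index", i))
  }
})

test_that("PC evaluation equals the brute-force mask definition at k = 3", {
  set.seed(7)
  for (rep in 1:20) {
    f <- logic_function(3, index = sample(0:255, 1))
    x <- runif(3)
    expect_equal(evaluate_pc(f, x), pc_eval_bruteforce(f$mask, x),
                 tolerance = 1e-12)
  }
})

test_that("fuzzy evaluation follows min/bounded-sum semantics", {
  expect_equal(evaluate_fuzzy(logic_function(2, 8), c(0.3, 0.7)), 0.3)
  # OR as the bounded sum over the three active partition terms
  expect_equal(evaluate_fuzzy(logic_function(2, 14), c(0.8, 0.5)), 1.0)
  expect_equal(evaluate_fuzzy(logic_function(1, 1), 0.2), 0.8)
  # partition-wise check: terms are minima over literals
  f <- logic_function(2, 9)  # XNOR: G1G2 and ~G1~G2
  x <- c(0.6, 0.3)
  expect_equal(evaluate_fuzzy(f, x),
               min(1, min(0.6, 0.3) + min(0.4, 0.7)))
})

test_that("PC and fuzzy agree with the Boolean truth table on corners", {
  corners <- expand.grid(a = c(0, 1), b = c(0, 1))
  for (i in 0:15) {
    f <- logic_function(2, index = i)
    for (r in seq_len(nrow(corners))) {
      x <- c(corners$a[r], corners$b[r])
      p <- x[1] * 2 + x[2]  # partition index of this corner
      expect_identical(evaluate_pc(f, x), as.numeric(f$mask[p + 1]))
      expect_identical(evaluate_fuzzy(f, x), as.numeric(f$mask[p + 1]))
    }
  }
})

test_that("complement identity holds: f(x) + (1-f)(x) = 1", {
  set.seed(11)
  for (k in 1:3) {
    for (rep in 1:10) {
      f <- logic_function(k, index = sample(0:(2^(2^k) - 1), 1))
      x <- runif(k)
      expect_equal(evaluate_pc(f, x) + evaluate_pc(complement_logic(f), x),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("monotone masks give evaluation monotone in each input", {
  # masks closed upward under the bitwise partial order of partitions
  upward_closed <- function(mask, k) {
    for (p in seq_along(mask) - 1L) {
      if (mask[p + 1L] == 0L) next
      for (j in seq_len(k)) {
        q <- bitwOr(p, 2L^(k - j))
        if (mask[q + 1L] == 0L) return(FALSE)
      }
    }
    TRUE
  }
  set.seed(3)
  k <- 2
  for (i in 0:15) {
    f <- logic_function(k, index = i)
    if (!upward_closed(f$mask, k)) next
    for (rep in 1:5) {
      x <- runif(k)
      for (j in 1:k) {
        hi <- x; hi[j] <- min(1, x[j] + 0.2)
        expect_gte(evaluate_pc(f, hi), evaluate_pc(f, x) - 1e-12)
      }
    }
  }
})

test_that("dimension and domain errors are raised", {
  f <- logic_function(2, 8)
  expect_error(evaluate_pc(f, c(0.5)), "arity|length")
  expect_error(evaluate_pc(f, c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(evaluate_fuzzy(f, c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("essential inputs are read off the mask", {
  expect_identical(essential_inputs(logic_function(2, 12)), 1L)  # = G1
  expect_identical(essential_inputs(logic_function(2, 10)), 2L)  # = G2
  expect_identical(essential_inputs(logic_function(2, 8)), c(1L, 2L))
  expect_identical(essential_inputs(logic_function(2, 15)), integer(0))
  # every essential set agrees with a numeric dependence probe
  set.seed(5)
  for (i in 0:255) {
    f <- logic_function(3, index = i)
    ess <- essential_inputs(f)
    for (j in 1:3) {
      x <- runif(3)
      lo <- x; lo[j] <- 0
      hi <- x; hi[j] <- 1
      depends <- abs(evaluate_pc(f, hi) - evaluate_pc(f, lo)) > 1e-12
      if (j %in% ess) next  # dependence may vanish at special x; skip
      expect_false(depends)
    }
  }
})

test_that("logic strings render and round-trip", {
  expect_equal(logic_to_string(logic_function(2, 9)), "G1G2 V ~G1~G2")
  expect_equal(logic_to_string(logic_function(2, 9), ascii = FALSE),
               "G1G2 ∨ ¬G1¬G2")
  expect_equal(logic_to_string(logic_function(2, 0)), "0")
  expect_equal(logic_to_string(logic_function(2, 15)), "1")
  expect_equal(logic_to_string(logic_function(2, 13), c("A", "B")),
               "AB V A~B V ~A~B")
  for (i in 0:15) {
    f <- logic_function(2, index = i)
    for (ascii in c(TRUE, FALSE)) {
      s <- logic_to_string(f, ascii = ascii)
      expect_equal(parse_logic_string(s, c("G1", "G2"))$index, i)
    }
  }
  expect_error(logic_to_string(logic_function(2, 9), c("A")), "length")
})

test_that("regulator signs classify activators, inhibitors and XOR", {
  expect_identical(regulator_signs(logic_function(1, 2)), "activator")
  expect_identical(regulator_signs(logic_function(1, 1)), "inhibitor")
  expect_identical(regulator_signs(logic_function(2, 6)),
                   c("mixed", "mixed"))
  expect_identical(regulator_signs(logic_function(2, 8)),
                   c("activator", "activator"))
  expect_identical(regulator_signs(logic_function(2, 13)),
                   c("activator", "inhibitor"))
  expect_identical(regulator_signs(logic_function(2, 15)),
                   c("none", "none"))
})

test_that("input permutation preserves the function under reordering", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(2:3, 1)
    f <- logic_function(k, index = sample(0:(2^(2^k) - 1), 1))
    perm <- sample(k)
    g <- permute_logic_inputs(f, perm)
    x <- runif(k)
    expect_equal(evaluate_pc(g, x), evaluate_pc(f, x[order(perm)]),
                 tolerance = 1e-12)
  }
})
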