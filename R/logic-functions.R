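#' k-input logic functions over Venn partitions
#'
#' A k-input logic function is encoded by which of the 2^k disjoint
#' activatory/inhibitory combinations (Venn partitions, i.e. minterms) of its
#' k inputs are active. Partition \code{p} (numbered 0 .. 2^k - 1) contains
#' input \code{j} non-negated when bit \code{k - j} of \code{p} is set, so
#' input 1 occupies the most significant bit: for k = 2, partition 3 is
#' \code{G1 G2}, partition 2 is \code{G1 ~G2}, partition 1 is \code{~G1 G2}
#' and partition 0 is \code{~G1 ~G2}. The function index \code{i} is the
#' integer whose binary digit \code{p} is the activity bit of partition
#' \code{p}; there are 2^(2^k) functions of k inputs. Arity 0 is allowed and
#' encodes the two constants.
#'
#' @param arity integer number of inputs, 0 to 4.
#' @param index integer in \code{[0, 2^(2^arity))}; alternative to
#'   \code{mask}.
#' @param mask 0/1 vector of length \code{2^arity}, element \code{p + 1}
#'   being the activity bit of partition \code{p}; alternative to
#'   \code{index}.
#' @return An object of class \code{logic_function} with fields
#'   \code{arity}, \code{index} and \code{mask}.
#' @examples
#' logic_function(2, index = 8)    # AND
#' logic_function(2, index = 14)   # OR
#' logic_function(1, mask = c(1, 0))  # NOT
#' @export
logic_function <- function(arity, index = NULL, mask = NULL) {
  check_arity(arity)
  n_part <- 2L^arity
  if (is.null(index) && is.null(mask)) {
    stop("supply either `index` or `mask`")
  }
  if (!is.null(mask)) {
    if (length(mask) != n_part || !all(mask %in% c(0, 1))) {
      stop("`mask` must be a 0/1 vector of length 2^arity = ", n_part)
    }
    mask <- as.integer(mask)
    idx_from_mask <- sum(mask * 2^(seq_len(n_part) - 1L))
    if (!is.null(index) && index != idx_from_mask) {
      stop("`index` and `mask` disagree")
    }
    index <- idx_from_mask
  } else {
    if (index < 0 || index >= 2^n_part) {
      stop("`index` must lie in [0, 2^(2^arity)) = [0, ", 2^n_part, ")")
    }
    mask <- as.integer(bitwAnd(index %/% 2^(seq_len(n_part) - 1L), 1L))
  }
  structure(
    list(arity = as.integer(arity), index = as.integer(index), mask = mask),
    class = "logic_function"
  )
}

MAX_ARITY <- 4L

check_arity <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 0 ||
      k > MAX_ARITY) {
    stop("arity must be an integer between 0 and ", MAX_ARITY)
  }
  invisible(as.integer(k))
}

#' @export
print.logic_function <- function(x, ...) {
  cat(sprintf(
    "<logic_function> k = %d, index = %d: %s\n",
    x$arity, x$index, logic_to_string(x, ascii = TRUE)
  ))
  invisible(x)
}

#' @export
format.logic_function <- function(x, ...) logic_to_string(x, ascii = TRUE)

#' Enumerate all logic functions of a given arity
#'
#' @param k arity (0 to 4; the search never goes deeper than 4 inputs).
#' @return List of the \code{2^(2^k)} \code{\link{logic_function}} objects in
#'   index order; index 0 is the constant-0 function and the last index the
#'   constant-1 function.
#' @examples
#' length(enumerate_logic_functions(2))  # 16
#' @export
enumerate_logic_functions <- function(k) {
  check_arity(k)
  lapply(0:(2^(2^k) - 1L), function(i) logic_function(k, index = i))
}

#' All masks of arity k as a matrix
#'
#' Row \code{i + 1} is the partition mask of the index-\code{i} function;
#' used to score every logic of a subset in one matrix product.
#' @noRd
logic_mask_matrix <- function(k) {
  check_arity(k)
  n_part <- 2L^k
  n_fun <- 2L^n_part
  idx <- 0:(n_fun - 1L)
  m <- vapply(seq_len(n_part) - 1L,
              function(p) bitwAnd(idx %/% 2L^p, 1L),
              integer(n_fun))
  matrix(as.numeric(m), nrow = n_fun, ncol = n_part)
}

check_unit_values <- function(x) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("expression values must lie in [0, 1]")
  }
  invisible(x)
}

#' Per-sample Venn partition probabilities (PC semantics)
#'
#' @param x numeric matrix, one row per input gene, one column per sample
#'   (a plain vector is treated as a single sample).
#' @return matrix of 2^k rows (partition p in row p + 1) and one column per
#'   sample; each column sums to 1.
#' @noRd
partition_probs <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, nrow = k)
  out <- matrix(1, nrow = 2L^k, ncol = ncol(x))
  if (k == 0L) return(out)
  p <- 0:(2L^k - 1L)
  for (j in seq_len(k)) {
    on <- bitwAnd(p %/% 2L^(k - j), 1L) == 1L
    out[on, ] <- out[on, , drop = FALSE] *
      rep(x[j, ], each = sum(on))
    out[!on, ] <- out[!on, , drop = FALSE] *
      rep(1 - x[j, ], each = sum(!on))
  }
  out
}

#' Per-sample Venn partition terms under fuzzy semantics
#'
#' Each partition term is the minimum over its literals (x_j or 1 - x_j).
#' @noRd
partition_terms_fuzzy <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, nrow = k)
  out <- matrix(1, nrow = 2L^k, ncol = ncol(x))
  if (k == 0L) return(out)
  p <- 0:(2L^k - 1L)
  for (j in seq_len(k)) {
    on <- bitwAnd(p %/% 2L^(k - j), 1L) == 1L
    out[on, ] <- pmin(out[on, , drop = FALSE],
                      rep(x[j, ], each = sum(on)))
    out[!on, ] <- pmin(out[!on, , drop = FALSE],
                       rep(1 - x[j, ], each = sum(!on)))
  }
  out
}

#' Evaluate a logic function on expression levels
#'
#' Under probabilistic-continuous (PC) semantics the value is the probability
#' of the union of the active partitions: the sum over active partitions of
#' the product of literal probabilities (\code{x_j} for an activatory
#' literal, \code{1 - x_j} for an inhibitory one). Under fuzzy semantics each
#' partition term is the minimum over its literals and the union is the
#' bounded sum \code{min(1, sum of terms)}. Both return values in [0, 1];
#' on Boolean inputs (every coordinate 0 or 1) the two semantics agree with
#' the Boolean truth table of the mask.
#'
#' @param f a \code{\link{logic_function}}.
#' @param x numeric vector of length \code{arity(f)} with entries in [0, 1]
#'   (one expression level per input), or a matrix with one row per input
#'   and one column per sample.
#' @return numeric value in [0, 1], or a vector of one value per sample when
#'   \code{x} is a matrix.
#' @examples
#' AND <- logic_function(2, index = 8)
#' evaluate_pc(AND, c(0.5, 0.5))     # 0.25
#' evaluate_fuzzy(AND, c(0.3, 0.7))  # 0.3
#' @export
evaluate_pc <- function(f, x) {
  stopifnot(inherits(f, "logic_function"))
  x <- check_logic_input(f, x)
  check_unit_values(x)
  drop(crossprod(partition_probs(x, f$arity), f$mask))
}

#' @rdname evaluate_pc
#' @export
evaluate_fuzzy <- function(f, x) {
  stopifnot(inherits(f, "logic_function"))
  x <- check_logic_input(f, x)
  check_unit_values(x)
  pmin(1, drop(crossprod(partition_terms_fuzzy(x, f$arity), f$mask)))
}

check_logic_input <- function(f, x) {
  if (is.null(dim(x))) {
    if (length(x) != f$arity) {
      stop("input length ", length(x), " does not match arity ", f$arity)
    }
    x <- matrix(x, nrow = max(f$arity, 1L))
  } else if (nrow(x) != f$arity) {
    stop("input has ", nrow(x), " rows but arity is ", f$arity)
  }
  x
}

#' Inputs a logic function actually depends on
#'
#' Input \code{j} is essential when flipping its bit in at least one
#' partition changes membership in the active set, i.e. the Boolean truth
#' table depends on it. Non-essential inputs can be dropped without changing
#' the function (e.g. the index-12 function of two inputs is just its first
#' input).
#'
#' @param f a \code{\link{logic_function}}.
#' @return integer vector of essential input positions (possibly empty).
#' @export
essential_inputs <- function(f) {
  stopifnot(inherits(f, "logic_function"))
  k <- f$arity
  if (k == 0L) return(integer(0))
  p <- 0:(2L^k - 1L)
  ess <- vapply(seq_len(k), function(j) {
    flip <- bitwXor(p, 2L^(k - j))
    any(f$mask != f$mask[flip + 1L])
  }, logical(1))
  which(ess)
}

#' Flip every partition bit of a logic function
#'
#' The complement satisfies \code{evaluate_pc(f, x) +
#' evaluate_pc(complement_logic(f), x) == 1} for every x, because the
#' partitions are disjoint and exhaustive.
#' @param f a \code{\link{logic_function}}.
#' @return the complementary \code{logic_function}.
#' @export
complement_logic <- function(f) {
  stopifnot(inherits(f, "logic_function"))
  logic_function(f$arity, mask = 1L - f$mask)
}

#' Permute the inputs of a logic function
#'
#' Returns the function of the reordered inputs: position \code{j} of the
#' result reads the input that sat at position \code{perm[j]} of \code{f}.
#' Used to align masks whose regulator lists are the same set in a
#' different order.
#' @param f a \code{\link{logic_function}}.
#' @param perm permutation of \code{1:arity(f)}.
#' @return a \code{logic_function} of the same arity.
#' @export
permute_logic_inputs <- function(f, perm) {
  stopifnot(inherits(f, "logic_function"))
  k <- f$arity
  if (length(perm) != k || !setequal(perm, seq_len(k))) {
    stop("`perm` must be a permutation of 1:", k)
  }
  if (k == 0L) return(f)
  p <- 0:(2L^k - 1L)
  bits <- vapply(seq_len(k), function(j) bitwAnd(p %/% 2L^(k - j), 1L),
                 integer(2L^k))
  # new partition q: bit j of q equals bit perm[j] of the source partition
  newp <- as.integer(bits[, perm, drop = FALSE] %*% 2L^(k - seq_len(k)))
  mask <- integer(2L^k)
  mask[newp + 1L] <- f$mask
  logic_function(k, mask = mask)
}

#' Render a logic function as text
#'
#' Active partitions are written as juxtaposed literals (negation marked
#' with an overbar-free prefix), joined by the OR symbol, most-activatory
#' partition first. The constants render as "0" and "1". The output parses
#' back to the identical mask with \code{\link{parse_logic_string}}.
#'
#' @param f a \code{\link{logic_function}}.
#' @param names character vector of input names, length \code{arity(f)};
#'   defaults to G1, G2, ...
#' @param ascii use ASCII "V" and "~" instead of \code{"∨"} and
#'   \code{"¬"} (default TRUE, the machine-readable form).
#' @return a single string.
#' @examples
#' logic_to_string(logic_function(2, index = 9))  # "G1G2 V ~G1~G2"
#' @export
logic_to_string <- function(f, names = NULL, ascii = TRUE) {
  stopifnot(inherits(f, "logic_function"))
  k <- f$arity
  if (is.null(names)) names <- paste0("G", seq_len(k))
  if (length(names) != k) {
    stop("`names` must have length ", k)
  }
  if (all(f$mask == 0L)) return("0")
  if (all(f$mask == 1L)) return("1")
  or_sym <- if (ascii) " V " else " ∨ "
  not_sym <- if (ascii) "~" else "¬"
  active <- rev(which(f$mask == 1L) - 1L)  # descending partition index
  terms <- vapply(active, function(p) {
    lits <- vapply(seq_len(k), function(j) {
      if (bitwAnd(p %/% 2L^(k - j), 1L) == 1L) names[j]
      else paste0(not_sym, names[j])
    }, character(1))
    paste0(lits, collapse = "")
  }, character(1))
  paste(terms, collapse = or_sym)
}

#' Parse the text rendering of a logic function back to the object
#'
#' Accepts the ASCII dialect ("V", "~") and the symbol dialect
#' (\code{"∨"}, \code{"¬"}), as produced by
#' \code{\link{logic_to_string}}.
#'
#' @param s a logic string.
#' @param names input gene names, in input order (defines bit positions).
#' @return a \code{\link{logic_function}} of arity \code{length(names)}.
#' @export
parse_logic_string <- function(s, names = NULL) {
  s <- trimws(s)
  if (is.null(names)) {
    if (s %in% c("0", "1")) {
      return(logic_function(0L, index = as.integer(s)))
    }
    stop("`names` is required for non-constant logic strings")
  }
  k <- length(names)
  mask <- integer(2L^k)
  if (s == "0") return(logic_function(k, mask = mask))
  if (s == "1") return(logic_function(k, mask = mask + 1L))
  terms <- strsplit(gsub("∨", "V", s, fixed = TRUE), "V", fixed = TRUE)[[1]]
  for (term in trimws(terms)) {
    term <- gsub("¬", "~", term, fixed = TRUE)
    p <- 0L
    rest <- term
    for (j in seq_len(k)) {
      neg <- startsWith(rest, "~")
      if (neg) rest <- substring(rest, 2L)
      if (!startsWith(rest, names[j])) {
        stop("cannot parse term '", term, "': expected literal for ", names[j])
      }
      rest <- substring(rest, nchar(names[j]) + 1L)
      if (!neg) p <- p + 2L^(k - j)
    }
    if (nchar(rest) > 0) stop("trailing text in term '", term, "'")
    mask[p + 1L] <- 1L
  }
  logic_function(k, mask = mask)
}

#' Regulatory sign of each input of a logic function
#'
#' The effect of input \code{j} is read off the Boolean corners: for every
#' setting of the other inputs, compare the function with \code{x_j = 1}
#' against \code{x_j = 0}. An input whose nonzero differences are all
#' positive is an activator, all negative an inhibitor, and both signs mixed
#' (as for XOR). Non-essential inputs are reported as \code{"none"}.
#'
#' @param f a \code{\link{logic_function}}.
#' @return character vector of length \code{arity(f)} with values in
#'   \code{c("activator", "inhibitor", "mixed", "none")}.
#' @examples
#' regulator_signs(logic_function(1, index = 2))  # "activator"
#' regulator_signs(logic_function(2, index = 6))  # XOR: "mixed" "mixed"
#' @export
regulator_signs <- function(f) {
  stopifnot(inherits(f, "logic_function"))
  k <- f$arity
  if (k == 0L) return(character(0))
  p <- 0:(2L^k - 1L)
  vapply(seq_len(k), function(j) {
    bit <- 2L^(k - j)
    on <- bitwAnd(p %/% bit, 1L) == 1L
    d <- f$mask[p[on] + 1L] - f$mask[bitwXor(p[on], bit) + 1L]
    d <- d[d != 0L]
    if (length(d) == 0L) "none"
    else if (all(d > 0L)) "activator"
    else if (all(d < 0L)) "inhibitor"
    else "mixed"
  }, character(1))
}
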