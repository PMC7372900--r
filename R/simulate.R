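#' Random signed regulatory-network topology
#'
#' Draws a uniform simple directed graph without self-loops, subject to a
#' maximum in-degree, and assigns each edge an inhibitory sign with
#' probability \code{inhibitor_fraction}. A stand-in for curated benchmark
#' topologies at the same scale (10 genes, 15 edges matches the scale of
#' the in-silico E. coli benchmark).
#'
#' @param n_genes number of genes (named G1 .. Gn).
#' @param n_edges number of directed edges.
#' @param inhibitor_fraction probability an edge is inhibitory
#'   (default 0.3).
#' @param max_in_degree cap on regulators per target, at most 4
#'   (default 3, the default search depth of the inference step).
#' @param seed integer seed.
#' @return data.frame with columns \code{regulator}, \code{target},
#'   \code{sign} (+1/-1).
#' @export
make_random_signed_network <- function(n_genes, n_edges,
                                       inhibitor_fraction = 0.3,
                                       max_in_degree = 3, seed = 1L) {
  if (n_genes < 2) stop("`n_genes` must be >= 2")
  if (max_in_degree > MAX_ARITY) {
    stop("`max_in_degree` must be at most ", MAX_ARITY)
  }
  if (n_edges > n_genes * min(n_genes - 1, max_in_degree)) {
    stop("`n_edges` infeasible under the in-degree constraint")
  }
  genes <- paste0("G", seq_len(n_genes))
  withr::with_seed(seed, {
    pairs <- expand.grid(regulator = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    pairs <- pairs[sample.int(nrow(pairs)), ]  # uniform order
    indeg <- stats::setNames(integer(n_genes), genes)
    keep <- logical(nrow(pairs))
    taken <- 0L
    for (i in seq_len(nrow(pairs))) {
      if (taken == n_edges) break
      tgt <- pairs$target[i]
      if (indeg[[tgt]] < max_in_degree) {
        keep[i] <- TRUE
        indeg[[tgt]] <- indeg[[tgt]] + 1L
        taken <- taken + 1L
      }
    }
    if (taken < n_edges) stop("could not place all edges; relax constraints")
    kept <- pairs[keep, ]
    data.frame(regulator = kept$regulator, target = kept$target,
               sign = ifelse(stats::runif(n_edges) < inhibitor_fraction,
                             -1L, 1L),
               stringsAsFactors = FALSE)
  })
}

#' Construct a ground-truth logical network
#'
#' @param genes character vector of all gene ids.
#' @param targets named list (one entry per regulated target) of lists with
#'   \code{regulators} (character), \code{signs} (+1/-1) and \code{logic}
#'   (a \code{\link{logic_function}} whose literal polarities match the
#'   signs); an optional \code{gate} label is kept as-is.
#' @return a \code{logical_network}.
#' @export
logical_network <- function(genes, targets) {
  rows <- lapply(names(targets), function(tgt) {
    spec <- targets[[tgt]]
    if (length(spec$regulators) != spec$logic$arity) {
      stop("target '", tgt, "': regulator count does not match logic arity")
    }
    data.frame(regulator = spec$regulators, target = tgt,
               sign = as.integer(spec$signs), stringsAsFactors = FALSE)
  })
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regulator = character(0), target = character(0),
               sign = integer(0), stringsAsFactors = FALSE)
  check_edge_frame(edges)
  missing <- setdiff(unique(c(edges$regulator, edges$target)), genes)
  if (length(missing)) {
    stop("edge gene(s) not in `genes`: ", paste(missing, collapse = ", "))
  }
  structure(list(genes = genes, targets = targets, edges = edges),
            class = "logical_network")
}

#' Assign random AND/OR/XOR logics to a signed network
#'
#' Builds the ground-truth logical network: every target with m >= 2
#' regulators receives a logic drawn uniformly from AND, OR, XOR applied to
#' its sign-adjusted literals (an activatory edge contributes the regulator
#' itself, an inhibitory edge its negation); a single-regulator target gets
#' the plain literal. XOR of m >= 3 literals is the parity function and is
#' never drawn for m = 1 (it has no distinct meaning there).
#'
#' @param network signed edge data.frame (\code{regulator}, \code{target},
#'   \code{sign} in +1/-1), at most 4 regulators per target.
#' @param seed integer seed for the logic draws.
#' @return a list of class \code{logical_network}: \code{genes} (all gene
#'   ids), \code{targets} (per regulated target: \code{regulators} in gene
#'   order, \code{signs}, \code{logic} (a \code{\link{logic_function}}),
#'   \code{gate} label), and \code{edges} (the input edge list).
#' @export
assign_random_logics <- function(network, seed = 1L) {
  check_edge_frame(network)
  genes <- sort_genes(unique(c(network$regulator, network$target)))
  tgt_list <- split(network, network$target)
  withr::with_seed(seed, {
    targets <- lapply(tgt_list, function(ed) {
      ord <- order(match(ed$regulator, genes))
      ed <- ed[ord, ]
      m <- nrow(ed)
      if (m > MAX_ARITY) {
        stop("target '", ed$target[1], "' has ", m,
             " regulators; at most ", MAX_ARITY, " supported")
      }
      gate <- if (m == 1L) "LITERAL" else sample(c("AND", "OR", "XOR"), 1L)
      list(regulators = ed$regulator, signs = ed$sign,
           logic = gate_logic(gate, ed$sign), gate = gate)
    })
  })
  names(targets) <- names(tgt_list)
  structure(list(genes = genes, targets = targets, edges = network),
            class = "logical_network")
}

# Order gene ids numerically when they look like G<number>, else lexically;
# keeps simulator output aligned with the inference's subset enumeration.
sort_genes <- function(genes) {
  num <- suppressWarnings(as.integer(sub("^G", "", genes)))
  if (!any(is.na(num))) genes[order(num)] else sort(genes)
}

#' Logic-function mask for a named gate over signed literals
#'
#' @param gate "AND", "OR", "XOR" or (for one regulator) "LITERAL".
#' @param signs vector of +1/-1, one per regulator in input order.
#' @return a \code{\link{logic_function}} whose literal polarities follow
#'   \code{signs}: partition truth uses the regulator itself for +1 and its
#'   negation for -1.
#' @export
gate_logic <- function(gate, signs) {
  m <- length(signs)
  if (m < 1 || m > MAX_ARITY) stop("1 to ", MAX_ARITY, " signs required")
  p <- 0:(2L^m - 1L)
  # literal j true in partition p iff presence bit matches the edge sign
  lit_true <- vapply(seq_len(m), function(j) {
    bit <- bitwAnd(p %/% 2L^(m - j), 1L) == 1L
    if (signs[j] > 0) bit else !bit
  }, logical(2L^m))
  lit_true <- matrix(lit_true, nrow = 2L^m)
  n_true <- rowSums(lit_true)
  mask <- switch(gate,
    LITERAL = {
      if (m != 1L) stop("LITERAL requires exactly one regulator")
      as.integer(n_true == 1L)
    },
    AND = as.integer(n_true == m),
    OR = as.integer(n_true >= 1L),
    XOR = {
      if (m < 2L) stop("XOR requires at least two regulators")
      as.integer(n_true %% 2L == 1L)
    },
    stop("unknown gate '", gate, "'")
  )
  logic_function(m, mask = mask)
}

#' Simulation configuration
#'
#' @param n_samples number of expression samples (the benchmark uses 10
#'   and 50).
#' @param c beta concentration of the expression noise (default 1000).
#' @param eps shape shift (default 1e-4).
#' @param seed integer seed.
#' @param cyclic_sweeps synchronous relaxation rounds used when the network
#'   has cycles (default 5).
#' @return a list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 10, c = 1000, eps = 1e-4,
                              seed = 1L, cyclic_sweeps = 5) {
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (cyclic_sweeps < 1) stop("`cyclic_sweeps` must be >= 1")
  structure(
    list(n_samples = as.integer(n_samples), c = c, eps = eps,
         seed = as.integer(seed), cyclic_sweeps = as.integer(cyclic_sweeps)),
    class = "simulation_config"
  )
}

#' Simulate expression samples from a logical network
#'
#' Per sample, root genes (no regulators) are drawn Uniform(0, 1);
#' regulated genes take a single beta draw with mean equal to their logic
#' output f on the current regulator values,
#' \code{Beta(c f + eps, c (1 - f) + eps)}. Acyclic networks are evaluated
#' in topological order; cyclic ones by \code{cyclic_sweeps} rounds of
#' synchronous deterministic updating from Uniform(0, 1) initial values,
#' with the beta draw taken once after the last sweep. Fully determined by
#' the seed.
#'
#' @param network a \code{\link{logical_network}}
#'   (\code{\link{assign_random_logics}}).
#' @param config a \code{\link{simulation_config}}.
#' @return numeric genes-x-samples matrix with values in [0, 1], gene ids
#'   as rownames and samples S1 .. Sn as colnames.
#' @export
simulate_expression <- function(network, config = simulation_config()) {
  stopifnot(inherits(network, "logical_network"))
  genes <- network$genes
  n <- config$n_samples
  g <- igraph::graph_from_data_frame(
    network$edges[, c("regulator", "target")],
    directed = TRUE, vertices = genes
  )
  acyclic <- igraph::is_dag(g)
  order_genes <- if (acyclic) {
    names(igraph::topo_sort(g, mode = "out"))
  } else {
    genes
  }
  regulated <- names(network$targets)

  withr::with_seed(config$seed, {
    expr <- matrix(stats::runif(length(genes) * n),
                   nrow = length(genes), ncol = n,
                   dimnames = list(genes, paste0("S", seq_len(n))))
    logic_out <- function(gene) {
      spec <- network$targets[[gene]]
      evaluate_pc(spec$logic,
                  expr[spec$regulators, , drop = FALSE])
    }
    if (acyclic) {
      for (gene in order_genes) {
        if (!gene %in% regulated) next
        f <- logic_out(gene)
        expr[gene, ] <- stats::rbeta(n, config$c * f + config$eps,
                                     config$c * (1 - f) + config$eps)
      }
    } else {
      for (sweep in seq_len(config$cyclic_sweeps)) {
        new_vals <- vapply(regulated, logic_out, numeric(n))
        expr[regulated, ] <- t(matrix(new_vals, nrow = n))
      }
      for (gene in regulated) {
        f <- evaluate_pc(network$targets[[gene]]$logic,
                         expr[network$targets[[gene]]$regulators, ,
                              drop = FALSE])
        expr[gene, ] <- stats::rbeta(n, config$c * f + config$eps,
                                     config$c * (1 - f) + config$eps)
      }
    }
    expr
  })
}

#' @export
print.logical_network <- function(x, ...) {
  cat(sprintf("<logical_network> %d genes, %d edges, %d regulated targets\n",
              length(x$genes), nrow(x$edges), length(x$targets)))
  for (tgt in names(x$targets)) {
    spec <- x$targets[[tgt]]
    cat(sprintf("  %s = %s  [%s]\n", tgt,
                logic_to_string(spec$logic, spec$regulators, ascii = TRUE),
                spec$gate))
  }
  invisible(x)
}
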