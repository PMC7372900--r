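#' Simulation benchmark of network and logic recovery
#'
#' Replays the simulation protocol end to end: draw a random signed
#' topology, assign random AND/OR/XOR logics, simulate beta-noise
#' expression samples, min-max rescale, reconstruct the network, and score
#' the prediction at the undirected, directed and directed-logical levels.
#' Counts are accumulated over replicates and converted to metrics once at
#' the end, matching how benchmark totals are usually tabulated.
#'
#' @param n_replicates number of independent simulated networks.
#' @param n_genes,n_edges,inhibitor_fraction,max_in_degree topology
#'   parameters (see \code{\link{make_random_signed_network}}); defaults
#'   10 genes / 15 edges, the scale of the in-silico E. coli benchmark.
#' @param n_samples expression samples per replicate (default 10).
#' @param sim_c beta concentration used by the simulator (default 1000).
#' @param config an \code{\link{inference_config}} for the reconstruction
#'   step.
#' @param rescale apply \code{\link{minmax_scale}} to the simulated matrix
#'   before inference (default FALSE: simulated values already live on
#'   [0, 1] and per-row stretching would distort the exact logic relation
#'   the likelihood looks for; scaling is the path for real data on
#'   arbitrary scales).
#' @param seed master seed; replicate r uses seed + r for each stage.
#' @return list with \code{counts} (per level, summed
#'   \code{\link{confusion_counts}}), \code{metrics} (per level,
#'   \code{\link{confusion_to_metrics}} of the summed counts) and
#'   \code{per_replicate} (data.frame of per-replicate directed-logical
#'   F-measures).
#' @export
benchmark_recovery <- function(n_replicates = 20, n_genes = 10,
                               n_edges = 15, inhibitor_fraction = 0.3,
                               max_in_degree = 3, n_samples = 10,
                               sim_c = 1000,
                               config = inference_config(),
                               rescale = FALSE, seed = 1L) {
  tot <- list(
    undirected = c(tp = 0, fp = 0, tn = 0, fn = 0),
    directed = c(tp = 0, fp = 0, tn = 0, fn = 0),
    logical = c(tp = 0, fp = 0, fn = 0)
  )
  rep_f <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- seed + r
    topo <- make_random_signed_network(n_genes, n_edges,
                                       inhibitor_fraction, max_in_degree,
                                       seed = s)
    net <- assign_random_logics(topo, seed = s)
    expr <- simulate_expression(net, simulation_config(
      n_samples = n_samples, c = sim_c, seed = s))
    if (rescale) expr <- minmax_scale(expr)
    pred <- infer_network(expr, config)
    und <- compare_edges(pred, net, net$genes, mode = "undirected")
    dir <- compare_edges(pred, net, net$genes, mode = "directed")
    lgl <- compare_logical(pred, net)
    tot$undirected <- tot$undirected +
      c(und$tp, und$fp, und$tn, und$fn)
    tot$directed <- tot$directed + c(dir$tp, dir$fp, dir$tn, dir$fn)
    tot$logical <- tot$logical + c(lgl$tp, lgl$fp, lgl$fn)
    f <- confusion_to_metrics(lgl)$f_measure
    rep_f[r] <- if (is.na(f)) 0 else f
  }
  counts <- list(
    undirected = confusion_counts(tot$undirected[1], tot$undirected[2],
                                  tot$undirected[3], tot$undirected[4]),
    directed = confusion_counts(tot$directed[1], tot$directed[2],
                                tot$directed[3], tot$directed[4]),
    logical = confusion_counts(tot$logical[1], tot$logical[2], NA,
                               tot$logical[3])
  )
  list(
    counts = counts,
    metrics = lapply(counts, confusion_to_metrics),
    per_replicate = data.frame(replicate = seq_len(n_replicates),
                               logical_f = rep_f)
  )
}
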