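#' Confusion counts
#'
#' @param tp,fp,tn,fn nonnegative counts; \code{tn} may be \code{NA} for
#'   the directed-logical level, where no meaningful universe of true
#'   negatives exists.
#' @return a list of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  vals <- c(tp = tp, fp = fp, fn = fn)
  if (any(vals < 0) || (!is.na(tn) && tn < 0)) {
    stop("counts must be nonnegative")
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %s  FP %s  TN %s  FN %s\n",
              x$tp, x$fp, ifelse(is.na(x$tn), "-", x$tn), x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den

#' Performance metrics from confusion counts
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP),
#' ACC = (TP+TN)/(TP+FP+TN+FN), MCC = (TP*TN - FP*FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and the F-measure, the harmonic
#' mean of TPR and PPV. Any metric whose denominator is zero — or that
#' needs a TN count where none is defined — is reported as \code{NA}
#' (absent), never as 0.
#'
#' @param counts a \code{\link{confusion_counts}}.
#' @return a list of class \code{metrics_report} with fields \code{tpr},
#'   \code{fpr}, \code{ppv}, \code{acc}, \code{mcc}, \code{f_measure}.
#' @examples
#' confusion_to_metrics(confusion_counts(724, 157, 2843, 776))
#' @export
confusion_to_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  tpr <- safe_ratio(tp, tp + fn)
  fpr <- safe_ratio(fp, fp + tn)
  ppv <- safe_ratio(tp, tp + fp)
  acc <- safe_ratio(tp + tn, tp + fp + tn + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_ratio(tp * tn - fp * fn, mcc_den)
  f <- if (is.na(tpr) || is.na(ppv) || tpr + ppv == 0) NA_real_
       else 2 * tpr * ppv / (tpr + ppv)
  structure(list(tpr = tpr, fpr = fpr, ppv = ppv, acc = acc, mcc = mcc,
                 f_measure = f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  cat(sprintf("<metrics_report> TPR %s  FPR %s  PPV %s  ACC %s  MCC %s  F %s\n",
              fmt(x$tpr), fmt(x$fpr), fmt(x$ppv), fmt(x$acc), fmt(x$mcc),
              fmt(x$f_measure)))
  invisible(x)
}

edge_frame_of <- function(x) {
  if (inherits(x, "grn_prediction")) return(x$edges)
  if (inherits(x, "logical_network")) return(x$edges)
  if (is.data.frame(x)) return(x)
  stop("expected an edge data.frame, grn_prediction or logical_network")
}

#' Compare predicted and true edge sets
#'
#' Counts true/false positives and negatives over the full pair universe of
#' the gene set: all ordered non-self pairs (\code{N(N-1)}) in directed
#' mode, or all unordered pairs (\code{N(N-1)/2}) in undirected mode, where
#' reciprocal edges collapse to one pair before counting.
#'
#' @param pred predicted edges: a data.frame with \code{regulator} and
#'   \code{target} columns, or a \code{grn_prediction}.
#' @param truth reference edges in the same forms, or a
#'   \code{logical_network}.
#' @param genes the gene universe: a character vector of ids, or an integer
#'   N meaning genes G1 .. GN.
#' @param mode \code{"directed"} or \code{"undirected"}.
#' @return a \code{\link{confusion_counts}}; the four counts always sum to
#'   the pair-universe size.
#' @export
compare_edges <- function(pred, truth, genes,
                          mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  pred <- edge_frame_of(pred)
  truth <- edge_frame_of(truth)
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- paste0("G", seq_len(genes))
  }
  for (ed in list(pred, truth)) {
    bad <- setdiff(c(ed$regulator, ed$target), genes)
    if (length(bad)) {
      stop("edges reference unknown gene(s): ", paste(bad, collapse = ", "))
    }
  }
  n <- length(genes)
  key <- function(ed) {
    if (nrow(ed) == 0L) return(character(0))
    if (mode == "directed") {
      unique(paste(ed$regulator, ed$target, sep = "\r"))
    } else {
      a <- pmin(ed$regulator, ed$target)
      b <- pmax(ed$regulator, ed$target)
      unique(paste(a, b, sep = "\r"))
    }
  }
  p <- key(pred); t <- key(truth)
  universe <- as.integer(if (mode == "directed") n * (n - 1)
                         else n * (n - 1) / 2)
  tp <- length(intersect(p, t))
  fp <- length(setdiff(p, t))
  fn <- length(setdiff(t, p))
  confusion_counts(tp, fp, universe - tp - fp - fn, fn)
}

#' Directed-logical comparison of predicted models against the truth
#'
#' The integrative level scores, per target, both the regulator set and the
#' active Venn partitions of the logic. When the predicted regulator set
#' equals the true one, each active partition present in both masks is a
#' TP, each predicted-only partition an FP and each true-only partition an
#' FN (masks are aligned to a common regulator order first). When the sets
#' differ, every predicted active partition counts as FP and every true
#' active partition as FN; a regulated target with no prediction
#' contributes its true active partitions as FN. No TN is defined at this
#' level (\code{tn = NA}).
#'
#' @param pred a \code{grn_prediction}, or a named list of
#'   \code{scored_model} objects (NULL entries allowed).
#' @param truth a \code{\link{logical_network}}.
#' @return a \code{\link{confusion_counts}} with \code{tn = NA}.
#' @export
compare_logical <- function(pred, truth) {
  stopifnot(inherits(truth, "logical_network"))
  models <- if (inherits(pred, "grn_prediction")) pred$models else pred
  tp <- fp <- fn <- 0L
  all_targets <- union(names(truth$targets),
                       names(models)[!vapply(models, is.null, logical(1))])
  for (tgt in all_targets) {
    true_spec <- truth$targets[[tgt]]
    m <- models[[tgt]]
    true_active <- if (is.null(true_spec)) 0L else sum(true_spec$logic$mask)
    if (is.null(m)) {
      fn <- fn + true_active
      next
    }
    pred_active <- sum(m$logic$mask)
    if (!is.null(true_spec) &&
        setequal(m$regulators, true_spec$regulators) &&
        length(m$regulators) == length(true_spec$regulators)) {
      # align the predicted mask to the true regulator order
      perm <- match(true_spec$regulators, m$regulators)
      pmask <- permute_logic_inputs(m$logic, perm)$mask
      tmask <- true_spec$logic$mask
      tp <- tp + sum(pmask == 1L & tmask == 1L)
      fp <- fp + sum(pmask == 1L & tmask == 0L)
      fn <- fn + sum(pmask == 0L & tmask == 1L)
    } else {
      fp <- fp + pred_active
      fn <- fn + true_active
    }
  }
  confusion_counts(tp, fp, NA, fn)
}
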