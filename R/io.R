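#' Min-max scale each gene row into [0, 1]
#'
#' Per-gene feature scaling \code{(x - min) / (max - min)}: every row of the
#' result has minimum 0 and maximum 1, the scale the beta-likelihood model
#' expects. A constant row carries no usable signal and is rejected by name.
#'
#' @param expr numeric genes-x-samples matrix with gene ids as rownames.
#' @return the scaled matrix.
#' @export
minmax_scale <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix")
  }
  rmin <- apply(expr, 1, min)
  rmax <- apply(expr, 1, max)
  flat <- rmax - rmin <= 0
  if (any(flat)) {
    stop("constant expression row(s), cannot min-max scale: ",
         paste(rownames(expr)[flat], collapse = ", "))
  }
  (expr - rmin) / (rmax - rmin)
}

#' Convenience log transform for count data
#'
#' \code{log2(count + 1)} applied elementwise; a simple variance-compressing
#' step before \code{\link{minmax_scale}} for sequencing counts. It is not a
#' mean-variance modelling transform.
#'
#' @param counts nonnegative numeric matrix.
#' @return transformed matrix.
#' @export
log2p1_transform <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  log2(counts + 1)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expected layout: header row of sample ids; first column gene ids; the
#' rest numeric. The delimiter (tab or comma) is sniffed from the first
#' line.
#'
#' @param path file path.
#' @return numeric genes-x-samples matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr genes-x-samples matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

check_edge_frame <- function(edges) {
  need <- c("regulator", "target", "sign")
  if (!is.data.frame(edges) || !all(need %in% colnames(edges))) {
    stop("edge list must have columns ", paste(need, collapse = ", "))
  }
  if (any(edges$regulator == edges$target)) stop("self-edges are not allowed")
  if (anyDuplicated(edges[, c("regulator", "target")])) {
    stop("duplicate (regulator, target) edges")
  }
  if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
  invisible(edges)
}

#' Read a signed directed edge list
#'
#' Tab- (or comma-) separated rows \code{regulator, target, value}, with or
#' without a header. A value column in \{1, -1\} is read as the sign; a
#' gold-standard presence column in \{0, 1\} keeps rows with 1 as
#' activatory edges and drops rows with 0.
#'
#' @param path file path.
#' @return data.frame with columns \code{regulator}, \code{target},
#'   \code{sign}.
#' @export
read_signed_edges_tsv <- function(path) {
  sep <- sniff_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 3) stop("edge file ", path, " needs 3 columns")
  df <- df[, 1:3]
  colnames(df) <- c("regulator", "target", "value")
  bad <- which(!df$value %in% c(-1, 0, 1))
  if (length(bad)) {
    stop("invalid edge value at data line(s) ",
         paste(bad, collapse = ", "), " of ", path)
  }
  df <- df[df$value != 0, , drop = FALSE]
  out <- data.frame(regulator = as.character(df$regulator),
                    target = as.character(df$target),
                    sign = as.integer(df$value),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  check_edge_frame(out)
  out
}

#' Write a signed edge list (or prediction edges) to TSV
#'
#' @param edges data.frame with \code{regulator}, \code{target},
#'   \code{sign} (and optionally \code{bf}), or a \code{grn_prediction}.
#' @param path output path.
#' @export
write_edges_tsv <- function(edges, path) {
  edges <- edge_frame_of(edges)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write the per-target logic table of a prediction or truth network
#'
#' Columns: target, comma-joined regulators, logic index, ASCII logic
#' string, and (for predictions) loglik, bic, bf.
#'
#' @param x a \code{grn_prediction} or \code{logical_network}.
#' @param path output path.
#' @export
write_logic_tsv <- function(x, path) {
  rows <- list()
  if (inherits(x, "grn_prediction")) {
    for (m in x$models) {
      if (is.null(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        target = m$target,
        regulators = paste(m$regulators, collapse = ","),
        logic_index = m$logic$index,
        logic_string = logic_to_string(m$logic, m$regulators, ascii = TRUE),
        loglik = m$loglik, bic = m$bic, bf = m$bayes_factor,
        stringsAsFactors = FALSE
      )
    }
  } else if (inherits(x, "logical_network")) {
    for (tgt in names(x$targets)) {
      spec <- x$targets[[tgt]]
      rows[[length(rows) + 1L]] <- data.frame(
        target = tgt,
        regulators = paste(spec$regulators, collapse = ","),
        logic_index = spec$logic$index,
        logic_string = logic_to_string(spec$logic, spec$regulators,
                                       ascii = TRUE),
        stringsAsFactors = FALSE
      )
    }
  } else {
    stop("expected a grn_prediction or logical_network")
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(0), regulators = character(0),
               logic_index = integer(0), logic_string = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-target logic table into a named model list
#'
#' Inverse of \code{\link{write_logic_tsv}}: reconstructs the regulator
#' lists and logic functions (and scores, when present).
#'
#' @param path file path.
#' @return named list of \code{scored_model}-like entries.
#' @export
read_logic_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  models <- lapply(seq_len(nrow(df)), function(i) {
    regs <- strsplit(df$regulators[i], ",", fixed = TRUE)[[1]]
    f <- logic_function(length(regs), index = df$logic_index[i])
    new_scored_model(df$target[i], regs, f,
                     if ("loglik" %in% names(df)) df$loglik[i] else NA_real_,
                     if ("bic" %in% names(df)) df$bic[i] else NA_real_,
                     if ("bf" %in% names(df)) df$bf[i] else NA_real_)
  })
  names(models) <- df$target
  models
}
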