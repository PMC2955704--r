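#' Bootstrap resampling of a dataset
#'
#' Draws `n` rows i.i.d. with replacement from the original dataset
#' (the "re-shuffled" dataset of the bootstrap scheme).  Deterministic for
#' a fixed seed.
#'
#' @param data a data frame.
#' @param seed integer seed.
#' @return A data frame with the same shape and columns.
#' @export
bootstrap_resample <- function(data, seed) {
  if (!is.data.frame(data)) data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 1) stop_input("cannot resample an empty dataset")
  rows <- with_seed(seed, sample.int(n, n, replace = TRUE))
  out <- data[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Directional edge confidences across bootstrap replicates
#'
#' Counts, for every ordered node pair, how many replicate PDAGs support an
#' edge in that direction: a directed edge `x -> y` contributes to `(x, y)`
#' only, an undirected edge to both `(x, y)` and `(y, x)`.  Confidence is
#' the support count divided by the number of replicates.
#'
#' @param pdags non-empty list of `"pdag"` objects over the same node set.
#' @return An object of class `"edge_confidence"`: list with `counts`
#'   (square integer matrix, rows = from, cols = to), `n_replicates`, and
#'   `nodes`.
#' @export
edge_confidences <- function(pdags) {
  if (!length(pdags)) stop_input("need at least one PDAG")
  nodes <- sort(pdags[[1]]$nodes)
  counts <- matrix(0L, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
  for (p in pdags) {
    if (!setequal(p$nodes, nodes)) stop_input("PDAGs have mismatched node sets")
    if (nrow(p$directed))
      counts[p$directed] <- counts[p$directed] + 1L
    if (nrow(p$undirected)) {
      counts[p$undirected] <- counts[p$undirected] + 1L
      counts[p$undirected[, 2:1, drop = FALSE]] <-
        counts[p$undirected[, 2:1, drop = FALSE]] + 1L
    }
  }
  structure(list(counts = counts, n_replicates = length(pdags),
                 nodes = nodes),
            class = "edge_confidence")
}

#' @export
print.edge_confidence <- function(x, ...) {
  cat("edge confidences over", x$n_replicates, "replicates;",
      sum(x$counts > 0), "supported ordered pairs\n")
  invisible(x)
}

#' @rdname edge_confidences
#' @param conf an `"edge_confidence"` table.
#' @param x,y node names.
#' @export
edge_confidence <- function(conf, x, y) {
  conf$counts[x, y] / conf$n_replicates
}

#' @rdname edge_confidences
#' @param path CSV output path (columns `from,to,confidence`; only pairs
#'   with positive support are written).
#' @export
confidences_to_csv <- function(conf, path) {
  idx <- which(conf$counts > 0, arr.ind = TRUE)
  df <- data.frame(from = conf$nodes[idx[, 1]], to = conf$nodes[idx[, 2]],
                   confidence = conf$counts[idx] / conf$n_replicates)
  df <- df[order(df$from, df$to), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Threshold a confidence table into a consensus PDAG
#'
#' An ordered pair whose confidence strictly exceeds the threshold
#' contributes an edge; when both directions exceed it, the edge is
#' undirected, otherwise it keeps its majority direction.
#'
#' @param conf an `"edge_confidence"` table.
#' @param threshold inclusion threshold in `[0, 1]` (strict `>`); the
#'   benchmark-tuned default is 0.25.
#' @return A `"pdag"`.
#' @export
consensus_pdag <- function(conf, threshold = 0.25) {
  if (threshold < 0 || threshold > 1) stop_input("threshold must be in [0, 1]")
  cf <- conf$counts / conf$n_replicates
  over <- cf > threshold
  directed <- NULL
  undirected <- NULL
  nodes <- conf$nodes
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      x <- nodes[i]; y <- nodes[j]
      if (over[x, y] && over[y, x]) undirected <- rbind(undirected, c(x, y))
      else if (over[x, y]) directed <- rbind(directed, c(x, y))
      else if (over[y, x]) directed <- rbind(directed, c(y, x))
    }
  }
  safe_pdag(nodes, directed, undirected)
}

#' Bootstrap consensus structure learning
#'
#' Runs [rhpc()] on `n_replicates` bootstrap resamples of the data,
#' accumulates directional edge confidences, and thresholds them into a
#' consensus PDAG.  Replicate seeds derive from the master seed by a fixed
#' counter scheme, so the whole procedure is reproducible.
#'
#' @inheritParams rhpc
#' @param data a data frame of fully observed variables.
#' @param n_replicates number of bootstrap replicates (the paper-scale
#'   default is 200).
#' @param threshold consensus inclusion threshold (strict `>`).
#' @param seed master integer seed.
#' @return `list(consensus = <pdag>, confidences = <edge_confidence>,
#'   replicates = <list of pdags>)`.
#' @export
bootstrap_learn <- function(data, n_replicates = 200, threshold = 0.25,
                            alpha = 0.05, test = "g2", seed = 1,
                            rule = c("or", "and")) {
  if (n_replicates < 1) stop_input("need at least one replicate")
  if (is.function(test))
    stop_input("bootstrap_learn needs a test method name, not a closure ",
               "(each replicate binds the test to its own resample)")
  rule <- match.arg(rule)
  if (!is.data.frame(data)) data <- as.data.frame(data)
  pdags <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    d <- bootstrap_resample(data, derive_seed(seed, i))
    pdags[[i]] <- rhpc(d, test = test, alpha = alpha, rule = rule)
  }
  conf <- edge_confidences(pdags)
  list(consensus = consensus_pdag(conf, threshold), confidences = conf,
       replicates = pdags)
}
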