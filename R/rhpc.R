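#' Learn the skeleton by running HPC on every node
#'
#' Runs [hpc()] on each column and places an undirected edge between `x`
#' and `y` when either endpoint reports the other in its PC set (the OR
#' rule, which rescues false negatives; `rule = "and"` requires both).  All
#' separating sets found along the way are merged into a single cache.
#'
#' @inheritParams de_pcs
#' @param rule `"or"` (default) or `"and"` skeleton combination.
#' @return `list(skeleton = <pdag with undirected edges only>,
#'   cache = <sepset_cache>, pc = <named list of per-node PC sets>)`.
#' @export
learn_skeleton <- function(data = NULL, test = "g2", alpha = 0.05,
                           rule = c("or", "and")) {
  rule <- match.arg(rule)
  test <- as_tester(test, data, alpha)
  cols <- tester_columns(data, test)
  if (is.null(cols)) stop_input("data with named columns is required")
  cols <- sort(cols)
  cache <- sepset_cache()
  pc <- list()
  for (t in cols) {
    pc[[t]] <- hpc(t, data, test, alpha,
                   candidates = setdiff(cols, t), cache = cache)$pc
  }
  edges <- NULL
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (i >= j) next
      x <- cols[i]; y <- cols[j]
      claimed <- c(y %in% pc[[x]], x %in% pc[[y]])
      keep <- if (rule == "or") any(claimed) else all(claimed)
      if (keep) edges <- rbind(edges, c(x, y))
    }
  }
  list(skeleton = pdag(cols, undirected = edges), cache = cache, pc = pc)
}

#' Orient v-structures from cached separating sets
#'
#' For every unshielded triple `x - z - y` (with `x`, `y` non-adjacent),
#' orients `x -> z <- y` when `z` does not belong to the cached separating
#' set of `x` and `y`.  If a pair has no cached set, a separating set of
#' size at most 2 is searched among subsets of either endpoint's
#' neighbourhood (when a tester is supplied); an unresolvable pair leaves
#' the triple unoriented.  An edge that different triples orient in both
#' directions reverts to undirected.
#'
#' @param skeleton an undirected `"pdag"` from [learn_skeleton()].
#' @param cache a [sepset_cache()].
#' @param test optional tester closure used for the fallback search.
#' @return A `"pdag"` with the v-structure edges directed.
#' @export
orient_v_structures <- function(skeleton, cache, test = NULL) {
  p <- skeleton
  nodes <- p$nodes
  adj <- setNames(lapply(nodes, function(v) pdag_adjacent(p, v)), nodes)
  get_sepset <- function(x, y) {
    if (sepset_has(cache, x, y)) return(sepset_get(cache, x, y))
    if (is.null(test))
      stop("no cached separating set for non-adjacent pair ", x, ", ", y,
           call. = FALSE)
    ct <- cached_test(test, cache)
    for (pool in list(setdiff(adj[[x]], y), setdiff(adj[[y]], x))) {
      if (find_separator(ct, x, y, pool, max_subset = 2))
        return(sepset_get(cache, x, y))
    }
    NULL
  }
  votes <- new.env(parent = emptyenv())  # "x\ry" -> TRUE for each x -> y vote
  for (z in nodes) {
    nb <- adj[[z]]
    if (length(nb) < 2) next
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (i >= j) next
        x <- nb[i]; y <- nb[j]
        if (y %in% adj[[x]]) next  # shielded
        ds <- get_sepset(x, y)
        if (is.null(ds)) next      # unresolved pair: leave unoriented
        if (!(z %in% ds)) {
          votes[[paste(x, z, sep = "\r")]] <- TRUE
          votes[[paste(y, z, sep = "\r")]] <- TRUE
        }
      }
    }
  }
  keys <- ls(votes)
  if (!length(keys)) return(p)
  vm <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  both <- row_pair_keys(vm)[duplicated(row_pair_keys(vm)) |
                            duplicated(row_pair_keys(vm), fromLast = TRUE)]
  vm <- vm[!(row_pair_keys(vm) %in% both), , drop = FALSE]  # conflicts revert
  if (!nrow(vm)) return(p)
  um <- p$undirected
  um <- um[!(row_pair_keys(um) %in% row_pair_keys(vm)), , drop = FALSE]
  safe_pdag(nodes, vm, um)
}

#' RHPC: recursive whole-network structure learning
#'
#' The full constraint-based pipeline: learn the skeleton with [hpc()] run
#' on every node, orient the v-structures from the cached separating sets,
#' then propagate compelled-edge orientations with the Meek rules to a
#' fixpoint.  Under reliable tests on data faithful to a DAG the output
#' equals [essential_graph()] of that DAG.
#'
#' @inheritParams learn_skeleton
#' @return A `"pdag"`: the estimated essential graph.
#' @examples
#' bn <- load_insulin_like_fixture()
#' d <- forward_sample(bn, 300, seed = 7)
#' rhpc(d, test = "g2", alpha = 0.05)
#' @export
rhpc <- function(data = NULL, test = "g2", alpha = 0.05,
                 rule = c("or", "and")) {
  tester <- as_tester(test, data, alpha)
  cols <- tester_columns(data, tester)
  if (!is.null(cols) && length(cols) == 1)
    return(pdag(cols))
  sk <- learn_skeleton(data, tester, alpha, rule = rule)
  vp <- orient_v_structures(sk$skeleton, sk$cache, test = tester)
  m <- pdag_to_matrices(vp)
  m <- meek_closure(m$D, m$U)
  di <- which(m$D, arr.ind = TRUE)
  ui <- which(m$U & upper.tri(m$U), arr.ind = TRUE)
  safe_pdag(vp$nodes,
            cbind(vp$nodes[di[, 1]], vp$nodes[di[, 2]]),
            cbind(vp$nodes[ui[, 1]], vp$nodes[ui[, 2]]))
}
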